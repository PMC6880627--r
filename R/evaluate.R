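#' Normalised mean-squared error between parameter maps
#'
#' `NMSE = mean((estimate - truth)^2) / mean(truth^2)` over the masked
#' voxels. The normalisation makes the error scale-invariant, so values are
#' comparable across kinetic parameters of very different magnitudes.
#'
#' @param estimates Numeric matrix of estimated values.
#' @param truth Numeric matrix of ground-truth values (non-zero on the
#'   mask).
#' @param mask Logical matrix; defaults to all voxels.
#' @return Non-negative scalar; 0 iff the maps agree exactly on the mask.
#' @examples
#' nmse(matrix(3, 2, 2), matrix(2, 2, 2))  # 0.25
#' @export
nmse <- function(estimates, truth, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(truth))
  if (!all(dim(estimates) == dim(truth)))
    stop("`estimates` and `truth` shapes differ", call. = FALSE)
  e <- estimates[mask]; t <- truth[mask]
  if (any(t == 0)) stop("zero truth voxel: NMSE undefined", call. = FALSE)
  mean((e - t)^2) / mean(t^2)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples (exact for small
#' tie-free samples, normal approximation with tie correction otherwise).
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with the `U` statistic (for `a`) and the two-sided
#'   `p.value`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  exact <- length(a) + length(b) <= 20L && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Outlier and failed-fit accounting for a parameter map
#'
#' Reports the fraction of masked voxels with a blood-flow estimate above
#' the physiological outlier threshold (5 mL/min/mL) and, when per-voxel
#' fit results are supplied, the fraction of voxels whose fit failed.
#'
#' @param fb_map Matrix of blood-flow estimates.
#' @param mask Logical matrix.
#' @param fit_results Optional matrix-shaped list of `fit_result` objects
#'   (as returned in `fit_slice_nlls()$results`).
#' @param threshold Outlier threshold, mL/min/mL.
#' @return List with `outlier_fraction` and `failure_fraction` (`NA` when
#'   no fit results are given).
#' @export
outlier_stats <- function(fb_map, mask, fit_results = NULL, threshold = 5) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  outlier <- sum(fb_map[mask] > threshold, na.rm = TRUE) / sum(mask)
  failure <- NA_real_
  if (!is.null(fit_results)) {
    ok <- vapply(fit_results[mask], function(r) isTRUE(r$success), logical(1L))
    failure <- mean(!ok)
  }
  list(outlier_fraction = outlier, failure_fraction = failure)
}

# per-parameter NMSE of an estimate-map list against a phantom's truth
nmse_by_param <- function(maps, phantom) {
  vapply(c("fb", "vp", "ve", "ps"),
         function(p) nmse(maps[[p]], phantom$maps[[p]], phantom$mask),
         numeric(1L))
}

# one realisation of one condition fitted with one method; returns the
# per-parameter NMSE vector plus bookkeeping fractions
fit_one <- function(method, series, n_steps, burn_in, seed) {
  if (method %in% c("bayes", "bayes_nonhier")) {
    spec <- if (method == "bayes") prior_spec()
            else prior_spec(hierarchical = FALSE, fb_var = 0.2, ps_var = 0.2,
                            alpha_b_fixed = 3.5, alpha_ps_fixed = 1.0)
    chain <- run_mcmc(series, spec = spec, n_steps = n_steps,
                      burn_in = burn_in, seed = seed)
    summ <- summarize_posterior(chain)
    list(nmse = nmse_by_param(summ$median, series$truth),
         maps = summ$median, failure = 0,
         acceptance = chain$acceptance_fraction)
  } else if (method %in% c("nlls1", "nlls100")) {
    cfg <- fit_config(n_starts = if (method == "nlls1") 1L else 100L,
                      seed = seed)
    fit <- fit_slice_nlls(series, cfg)
    list(nmse = nmse_by_param(fit$maps, series$truth), maps = fit$maps,
         failure = fit$failure_fraction, acceptance = NA_real_)
  } else stop("unknown method: ", method, call. = FALSE)
}

#' Monte-Carlo comparison of fitting methods on simulation phantoms
#'
#' For each condition and noise realisation, simulates a phantom series,
#' fits it with every requested method, and scores each fit by the
#' per-parameter NMSE against the ground truth. Aggregates NMSE means and
#' standard deviations across realisations (pooled over conditions and per
#' condition), compares methods by Mann-Whitney U tests on the
#' per-realisation overall NMSE values, and accounts outliers
#' (`Fb > 5 mL/min/mL`) and failed fits. Fully reproducible from
#' `master_seed`.
#'
#' @param conditions Character vector of phantom conditions.
#' @param n_realisations Noise realisations per condition (>= 2).
#' @param methods Subset of `"bayes"`, `"bayes_nonhier"`, `"nlls1"`,
#'   `"nlls100"`.
#' @param master_seed Integer master seed.
#' @param n_steps,burn_in Chain settings for the Bayesian methods.
#' @param snr Signal-to-noise ratio of the simulations.
#' @param u_test_pairs List of 2-vectors of method names to compare;
#'   defaults to Bayesian vs every other fitted method.
#' @return Object of class `eval_report`: `per_realisation` data frame
#'   (condition, realisation, method, per-parameter and overall NMSE,
#'   failure/outlier fractions, sampler acceptance), `summary` data frame
#'   of NMSE mean (sd) per method and parameter in a Table-1-style layout,
#'   `u_tests`, `n_realisations`, `seeds`.
#' @export
monte_carlo_study <- function(conditions = c("rest", "stress", "stress_defect"),
                              n_realisations = 20L,
                              methods = c("bayes", "nlls1", "nlls100"),
                              master_seed = 1L, n_steps = 4000L,
                              burn_in = 1000L, snr = 15,
                              u_test_pairs = NULL) {
  if (n_realisations < 2L) stop("`n_realisations` must be >= 2", call. = FALSE)
  rows <- list()
  seeds <- integer(0)
  param_names <- c("fb", "vp", "ve", "ps")
  idx <- 0L
  for (cond in conditions) {
    phantom <- build_phantom(cond)
    for (r in seq_len(n_realisations)) {
      idx <- idx + 1L
      seed_r <- voxel_seed(master_seed, 131L * idx)
      seeds <- c(seeds, seed_r)
      series <- simulate_series(phantom, snr = snr, seed = seed_r)
      for (m in methods) {
        res <- tryCatch(
          fit_one(m, series, n_steps, burn_in, seed = seed_r + 1L),
          error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, realisation = r, method = m, fb = NA_real_,
            vp = NA_real_, ve = NA_real_, ps = NA_real_, all = NA_real_,
            failure_fraction = NA_real_, outlier_fraction = NA_real_,
            acceptance = NA_real_, error = conditionMessage(res))
          next
        }
        out <- outlier_stats(res$maps$fb, phantom$mask)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, realisation = r, method = m,
          fb = res$nmse[["fb"]], vp = res$nmse[["vp"]],
          ve = res$nmse[["ve"]], ps = res$nmse[["ps"]],
          all = mean(res$nmse), failure_fraction = res$failure,
          outlier_fraction = out$outlier_fraction,
          acceptance = res$acceptance, error = NA_character_)
      }
    }
  }
  per_real <- do.call(rbind, rows)

  agg <- function(d) {
    do.call(rbind, lapply(split(d, d$method), function(g) {
      vals <- vapply(c("all", param_names), function(p)
        c(mean(g[[p]], na.rm = TRUE), sd(g[[p]], na.rm = TRUE)),
        numeric(2L))
      data.frame(method = g$method[1L],
                 parameter = c("all", param_names),
                 mean = vals[1L, ], sd = vals[2L, ], row.names = NULL)
    }))
  }
  summary_df <- agg(per_real)
  by_condition <- lapply(split(per_real, per_real$condition), agg)

  if (is.null(u_test_pairs) && "bayes" %in% methods)
    u_test_pairs <- lapply(setdiff(methods, "bayes"),
                           function(m) c("bayes", m))
  # one U test per parameter row (and overall), comparing the
  # per-realisation NMSE distributions of the two methods
  u_tests <- lapply(u_test_pairs, function(pair) {
    per_param <- lapply(c("all", param_names), function(p) {
      a <- per_real[[p]][per_real$method == pair[1L]]
      b <- per_real[[p]][per_real$method == pair[2L]]
      mann_whitney_u(a[!is.na(a)], b[!is.na(b)])
    })
    names(per_param) <- c("all", param_names)
    list(methods = pair, U = per_param$all$U, p.value = per_param$all$p.value,
         by_parameter = per_param)
  })

  structure(list(per_realisation = per_real, summary = summary_df,
                 by_condition = by_condition, u_tests = u_tests,
                 n_realisations = n_realisations, conditions = conditions,
                 master_seed = master_seed, seeds = seeds,
                 n_steps = n_steps, burn_in = burn_in, snr = snr),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d realisation(s) x {%s}, methods: %s\n",
              x$n_realisations, paste(x$conditions, collapse = ", "),
              paste(unique(x$per_realisation$method), collapse = ", ")))
  s <- x$summary
  s$`mean (sd)` <- sprintf("%.3f (%.3f)", s$mean, s$sd)
  print(s[, c("method", "parameter", "mean (sd)")], row.names = FALSE)
  for (u in x$u_tests)
    cat(sprintf("U test %s vs %s: U = %g, p = %.4g\n", u$methods[1L],
                u$methods[2L], u$U, u$p.value))
  invisible(x)
}

# convenience accessor: mean NMSE for one method/parameter
report_nmse <- function(report, method, parameter = "all") {
  s <- report$summary
  s$mean[s$method == method & s$parameter == parameter]
}
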