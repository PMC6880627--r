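#' Configuration for multi-start nonlinear least-squares fitting
#'
#' Box constraints and optimiser settings for the L-BFGS-B baseline fitter.
#' The default bounds are conservative physiological limits:
#' `0.001 <= Fb <= 6`, `0.001 <= vp <= 0.3`, `0.001 <= ve <= 0.4`,
#' `0.001 <= PS <= 4` (mL/min/mL for the flows). A fit counts as successful
#' when the optimiser converges to a relative cost decrease below `tol`
#' within `max_iter` iterations and no parameter ends on a bound.
#'
#' @param lower,upper Named numeric vectors with elements `fb`, `vp`, `ve`,
#'   `ps`.
#' @param n_starts Number of uniform random initialisations per voxel.
#' @param tol Relative cost-decrease convergence tolerance.
#' @param max_iter Iteration cap per start.
#' @param seed Master seed; each voxel draws its starts from its own
#'   substream so results do not depend on voxel iteration order.
#' @param bound_tol Absolute closeness to a bound that counts as "at the
#'   bound" for the success criterion.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(fb = 0.001, vp = 0.001, ve = 0.001, ps = 0.001),
                       upper = c(fb = 6.0, vp = 0.3, ve = 0.4, ps = 4.0),
                       n_starts = 100L, tol = 1e-8, max_iter = 1000L,
                       seed = 1L, bound_tol = 1e-6) {
  nm <- c("fb", "vp", "ve", "ps")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)))
  lower <- lower[nm]; upper <- upper[nm]
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  structure(list(lower = lower, upper = upper, n_starts = as.integer(n_starts),
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), bound_tol = bound_tol),
            class = "fit_config")
}

# derive a per-voxel seed from the master seed (stable under iteration order)
voxel_seed <- function(master, index) {
  as.integer((as.double(master) * 1000003 + 7919 * as.double(index)) %%
               2147483647)
}

#' Least-squares cost of a parameter set
#'
#' Mean squared residual `chi^2 = (1/N) sum_j (C_model(t_j) - y(t_j))^2`
#' between the 2CXM prediction and an observed concentration curve.
#'
#' @param params A [kinetic_params()].
#' @param curve Observed [sampled_curve()].
#' @param aif Arterial input [sampled_curve()] on the same grid.
#' @return Non-negative scalar; zero iff the model reproduces the data
#'   exactly.
#' @export
chi_squared <- function(params, curve, aif) {
  check_same_grid(curve, aif)
  .cxm_chi2_cpp(aif$values, aif$dt, curve$values, params$fb, params$vp,
                params$ve, params$ps, params$tau0, params$hct)
}

#' Fit one voxel by multi-start box-constrained least squares
#'
#' Runs L-BFGS-B from `n_starts` initial positions drawn uniformly within
#' the bounds and returns the lowest-cost *successful* start; a start is
#' successful if the optimiser converges within the iteration cap and no
#' fitted parameter sits on a bound. When no start succeeds the lowest-cost
#' attempt is returned with `success = FALSE`. Optimiser errors in a start
#' are caught and counted as failures.
#'
#' @param curve Observed tissue [sampled_curve()].
#' @param aif Arterial input [sampled_curve()].
#' @param config A [fit_config()].
#' @param tau0 Fixed bolus delay (min) used in the model; delays are
#'   estimated externally, not fitted.
#' @param hct Haematocrit.
#' @param voxel_index Integer used to derive this voxel's RNG substream
#'   from `config$seed`.
#' @return Object of class `fit_result`: list with `params`
#'   ([kinetic_params()]), `cost`, `success`, `n_successful_starts`,
#'   `start_used`, `n_starts`.
#' @export
fit_voxel_nlls <- function(curve, aif, config = fit_config(), tau0 = 0,
                           hct = 0.45, voxel_index = 1L) {
  check_same_grid(curve, aif)
  lo <- config$lower; hi <- config$upper
  obj <- function(th)
    .cxm_chi2_cpp(aif$values, aif$dt, curve$values, th[1L], th[2L], th[3L],
                  th[4L], tau0, hct)
  set.seed(voxel_seed(config$seed, voxel_index))
  # one row of four draws per start, so the first k starts of a larger
  # n_starts run are exactly the starts of an n_starts = k run
  starts <- matrix(runif(4L * config$n_starts), ncol = 4L, byrow = TRUE)
  starts <- sweep(sweep(starts, 2L, hi - lo, "*"), 2L, lo, "+")
  colnames(starts) <- names(lo)
  factr <- config$tol / .Machine$double.eps
  best <- NULL; best_any <- NULL
  n_success <- 0L
  for (s in seq_len(config$n_starts)) {
    fit <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = config$max_iter, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) next
    at_bound <- any(fit$par - lo < config$bound_tol) ||
      any(hi - fit$par < config$bound_tol)
    ok <- fit$convergence == 0L && !at_bound
    if (ok) {
      n_success <- n_success + 1L
      if (is.null(best) || fit$value < best$value) {
        best <- fit; best$start <- s
      }
    }
    if (is.null(best_any) || fit$value < best_any$value) {
      best_any <- fit; best_any$start <- s
    }
  }
  if (is.null(best_any))
    stop("all optimiser starts raised errors for this voxel", call. = FALSE)
  use <- if (!is.null(best)) best else best_any
  structure(list(
    params = kinetic_params(use$par[1L], use$par[2L], use$par[3L],
                            max(use$par[4L], 0), tau0 = tau0, hct = hct),
    cost = use$value,
    success = !is.null(best),
    n_successful_starts = n_success,
    start_used = use$start,
    n_starts = config$n_starts), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s, cost %.3e, %d/%d successful starts (used start %d)\n",
    if (x$success) "success" else "FAILED", x$cost, x$n_successful_starts,
    x$n_starts, x$start_used))
  print(x$params)
  invisible(x)
}

#' Fit every masked voxel of a series by multi-start least squares
#'
#' @param series A [simulate_series()] object, or a list with a `(t, y, x)`
#'   concentration array in `noisy`, a logical matrix `mask` (taken from
#'   `truth$mask` for synthetic series), `aif`, `times`, and optional
#'   `tau0`/`hct`.
#' @param config A [fit_config()].
#' @param use_clean Fit the noise-free curves instead of the noisy ones.
#' @return List of class `slice_fit`: per-parameter estimate matrices in
#'   `maps`, per-voxel `results`, the `failure_fraction` (failed voxels /
#'   masked voxels) and `n_masked`.
#' @export
fit_slice_nlls <- function(series, config = fit_config(), use_clean = FALSE) {
  mask <- series$mask %||% series$truth$mask
  if (is.null(mask) || !any(mask)) stop("mask is empty", call. = FALSE)
  data <- if (use_clean) series$clean else series$noisy
  tau0 <- series$tau0 %||% 0
  hct <- series$hct %||% 0.45
  nr <- nrow(mask); nc <- ncol(mask)
  maps <- list(fb = matrix(NA_real_, nr, nc), vp = matrix(NA_real_, nr, nc),
               ve = matrix(NA_real_, nr, nc), ps = matrix(NA_real_, nr, nc))
  results <- vector("list", nr * nc)
  dim(results) <- c(nr, nc)
  n_masked <- 0L; n_failed <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    n_masked <- n_masked + 1L
    curve <- sampled_curve(series$times, data[, i, j])
    res <- fit_voxel_nlls(curve, series$aif, config, tau0 = tau0, hct = hct,
                          voxel_index = (i - 1L) * nc + j)
    results[[i, j]] <- res
    if (!res$success) n_failed <- n_failed + 1L
    maps$fb[i, j] <- res$params$fb
    maps$vp[i, j] <- res$params$vp
    maps$ve[i, j] <- res$params$ve
    maps$ps[i, j] <- res$params$ps
  }
  structure(list(maps = maps, results = results,
                 failure_fraction = n_failed / n_masked,
                 outlier_fraction = sum(maps$fb[mask] > 5) / n_masked,
                 n_masked = n_masked, mask = mask),
            class = "slice_fit")
}
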