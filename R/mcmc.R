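#' Metropolis-Hastings sampler for the hierarchical Bayesian 2CXM model
#'
#' Samples the per-voxel posterior of the kinetic parameters, noise
#' variance and hyperparameters by sweeping the masked voxels in raster
#' order. Within each voxel and sweep, the four kinetic parameters are
#' proposed jointly by a Gaussian random walk and accepted or rejected as
#' one block (joint proposals respect the strong correlations between the
#' 2CXM parameters); the noise variance is then drawn exactly from its
#' conjugate Inverse-Gamma full conditional, and, in the hierarchical
#' model, the prior means `alpha_b` and `alpha_ps` take their own
#' random-walk steps. The spatial Markov-random-field term conditions each
#' voxel on its neighbours' most recent samples, with weights `W_k` built
#' from previous accepted samples per `spec$weight_source` (inverse-scale
#' weighting, floored to avoid blow-up; see [prior_spec()]).
#'
#' During burn-in only, per-voxel proposal standard deviations are scaled
#' by x1.1 / /1.1 every `tune_interval` sweeps to steer the block
#' acceptance rate into `[0.2, 0.3]` (around the 0.234 random-walk
#' optimum), then frozen.
#'
#' @param series A [simulate_series()] object, or a list with fields
#'   `noisy` (`(t, y, x)` array), `times`, `aif`, a mask (either `mask` or
#'   `truth$mask`), and optional `tau0`, `hct`.
#' @param spec A [prior_spec()].
#' @param n_steps Chain length in sweeps.
#' @param burn_in Sweeps discarded before summarisation (must be
#'   < `n_steps`); also the adaptation window.
#' @param seed Integer seed; identical seeds give bit-identical chains.
#' @param graph Optional [build_neighbour_graph()]; built from the mask by
#'   default.
#' @param use_clean Fit the noise-free curves (synthetic series only).
#' @param init_method `"nlls"` (default) starts each voxel's chain at a
#'   cheap few-start least-squares estimate of its own curve, the standard
#'   way to start a random-walk chain near the posterior mode --
#'   important here because the 2CXM likelihood has long flat ridges at
#'   realistic SNR, and a chain started far up the ridge can take many
#'   sweeps to drift down. `"mid"` starts every voxel at mid-support
#'   values.
#' @param init Optional named list overriding the default initial state
#'   (`fb`, `vp`, `ve`, `ps`, `sigma2`, `alpha_b`, `alpha_ps`; scalars or
#'   per-voxel vectors).
#' @param proposal_scales Initial random-walk standard deviations for
#'   `(fb, vp, ve, ps)`.
#' @param alpha_proposal_sd Random-walk standard deviation of the
#'   hyperparameter steps.
#' @param tune_interval Sweeps between proposal-scale adaptations during
#'   burn-in.
#' @param ridge_prob Probability that a sweep's block proposal is a
#'   flow/plasma-volume ridge move (`fb` scaled by `exp(-eps)`, `vp` by
#'   `exp(+eps)`) instead of an isotropic Gaussian step; the two
#'   parameters are strongly anti-correlated in the 2CXM likelihood and
#'   isotropic steps alone traverse that valley very slowly.
#' @param ridge_scale Standard deviation of the log-scale ridge step.
#' @param use_likelihood Test hook: `FALSE` drops the likelihood so the
#'   chain samples the prior (the noise variance is then held at its
#'   initial value, as its conditional no longer involves the data).
#' @param update_kinetics Test hook: `FALSE` freezes the kinetic block (for
#'   validating the conjugate noise-variance update in isolation).
#' @return Object of class `chain_state`: `samples` array of shape
#'   `(n_steps, n_voxels, 7)` with parameter slices
#'   `fb, vp, ve, ps, sigma2, alpha_b, alpha_ps`, the `graph`,
#'   `acceptance_fraction` (post-burn-in block acceptance), per-voxel
#'   `proposal_scales` after tuning, `n_steps`, `burn_in`, `seed`, `spec`.
#' @export
run_mcmc <- function(series, spec = prior_spec(), n_steps = 4000L,
                     burn_in = 1000L, seed = 1L, graph = NULL,
                     use_clean = FALSE, init_method = c("nlls", "mid"),
                     init = NULL,
                     proposal_scales = c(fb = 0.15, vp = 0.01, ve = 0.02,
                                         ps = 0.08),
                     alpha_proposal_sd = 0.3, tune_interval = 50L,
                     ridge_prob = 0.25, ridge_scale = 0.15,
                     use_likelihood = TRUE, update_kinetics = TRUE) {
  if (n_steps <= burn_in) stop("`n_steps` must exceed `burn_in`", call. = FALSE)
  mask <- series$mask %||% series$truth$mask
  if (is.null(graph)) {
    graph <- if (spec$spatial) build_neighbour_graph(mask)
    else trivial_graph(mask)  # no spatial term: neighbours never consulted
  }
  data <- if (use_clean) series$clean else series$noisy
  aif <- series$aif
  tau0 <- series$tau0 %||% 0
  hct <- series$hct %||% 0.45
  dt <- aif$dt
  nvox <- nrow(graph$voxels)
  nt <- dim(data)[1L]
  y <- matrix(0, nt, nvox)  # one column per masked voxel
  for (k in seq_len(nvox))
    y[, k] <- data[, graph$voxels[k, 1L], graph$voxels[k, 2L]]

  init_method <- match.arg(init_method)
  theta0 <- matrix(rep(c(3, 0.1, 0.2, 1), each = nvox), nvox, 4L,
                   dimnames = list(NULL, c("fb", "vp", "ve", "ps")))
  if (init_method == "nlls" && is.null(init)) {
    cfg0 <- fit_config(n_starts = 5L, seed = seed)
    for (k in seq_len(nvox)) {
      f <- fit_voxel_nlls(sampled_curve(aif$times, y[, k]), aif, cfg0,
                          tau0 = tau0, hct = hct, voxel_index = k)
      th <- c(f$params$fb, f$params$vp, f$params$ve, f$params$ps)
      # polish to full convergence: the baseline fitter's 1e-8 stopping rule
      # leaves a cost plateau spanning a few percent in Fb
      pol <- tryCatch(
        optim(th, function(p) .cxm_chi2_cpp(aif$values, dt, y[, k], p[1L],
                                            p[2L], p[3L], p[4L], tau0, hct),
              method = "L-BFGS-B", lower = cfg0$lower, upper = cfg0$upper,
              control = list(maxit = 500L, factr = 10)),
        error = function(e) NULL)
      if (!is.null(pol)) th <- pol$par
      # clip strictly inside the prior supports
      th <- pmin(pmax(th, 1e-3), c(Inf, spec$vp_max, spec$ve_max, Inf))
      theta0[k, ] <- th
    }
  }
  set.seed(seed)
  # noise variance starts at the baseline-frame sample variance; the first
  # conjugate update replaces it immediately
  state <- list(
    theta = theta0,
    sigma2 = pmax(apply(y[seq_len(min(5L, nt)), , drop = FALSE], 2L, var),
                  1e-8),
    alpha_b = if (spec$hierarchical)
      pmin(pmax(theta0[, 1L], spec$alpha_b_support[1L]),
           spec$alpha_b_support[2L])
    else rep(spec$alpha_b_fixed, nvox),
    alpha_ps = if (spec$hierarchical)
      pmin(pmax(theta0[, 4L], spec$alpha_ps_support[1L]),
           spec$alpha_ps_support[2L])
    else rep(spec$alpha_ps_fixed, nvox))
  if (!is.null(init))
    for (nm in names(init)) {
      if (nm %in% colnames(state$theta)) state$theta[, nm] <- init[[nm]]
      else state[[nm]] <- rep(init[[nm]], length.out = nvox)
    }

  ssr <- numeric(nvox)
  for (k in seq_len(nvox))
    ssr[k] <- .cxm_ssr_cpp(aif$values, dt, y[, k], state$theta[k, 1L],
                           state$theta[k, 2L], state$theta[k, 3L],
                           state$theta[k, 4L], tau0, hct)
  if (any(!is.finite(ssr)))
    stop("non-finite likelihood at initialisation", call. = FALSE)

  scales <- matrix(rep(proposal_scales, each = nvox), nvox, 4L)
  samples <- array(NA_real_, dim = c(n_steps, nvox, 7L),
                   dimnames = list(NULL, NULL,
                                   c("fb", "vp", "ve", "ps", "sigma2",
                                     "alpha_b", "alpha_ps")))
  acc_post <- 0L                 # accepted blocks after burn-in
  acc_window <- integer(nvox)    # per-voxel acceptances in tuning window
  c_shape <- spec$sigma2_shape + nt / 2

  for (s in seq_len(n_steps)) {
    for (k in seq_len(nvox)) {
      th <- state$theta[k, ]
      nb <- graph$neighbours[[k]]
      nb_theta <- state$theta[nb, , drop = FALSE]
      w <- spatial_weights(th, nb_theta, spec)
      if (update_kinetics) {
        if (runif(1L) < ridge_prob) {
          # ridge move: the 2CXM likelihood is nearly invariant under
          # trading flow against plasma volume; a multiplicative
          # anti-correlated step (unit Jacobian, symmetric) walks along
          # that valley far faster than isotropic steps can
          eps <- rnorm(1L) * ridge_scale
          prop <- th * c(exp(-eps), exp(eps), 1, 1)
        } else {
          prop <- th + rnorm(4L) * scales[k, ]
        }
        lp_new <- log_prior_kinetic(prop, state$alpha_b[k], state$alpha_ps[k],
                                    nb_theta, w, spec)
        if (is.finite(lp_new)) {
          lp_old <- log_prior_kinetic(th, state$alpha_b[k], state$alpha_ps[k],
                                      nb_theta, w, spec)
          if (use_likelihood) {
            ssr_new <- .cxm_ssr_cpp(aif$values, dt, y[, k], prop[1L], prop[2L],
                                    prop[3L], prop[4L], tau0, hct)
            if (!is.finite(ssr_new))
              stop(sprintf("non-finite likelihood at voxel %d, step %d", k, s),
                   call. = FALSE)
            ll_new <- -ssr_new / (2 * state$sigma2[k])
            ll_old <- -ssr[k] / (2 * state$sigma2[k])
          } else {
            ssr_new <- ssr[k]; ll_new <- 0; ll_old <- 0
          }
          if (log(runif(1L)) < (ll_new + lp_new) - (ll_old + lp_old)) {
            state$theta[k, ] <- prop
            ssr[k] <- ssr_new
            acc_window[k] <- acc_window[k] + 1L
            if (s > burn_in) acc_post <- acc_post + 1L
          }
        }
      }
      # conjugate Inverse-Gamma update of the noise variance
      if (use_likelihood) {
        state$sigma2[k] <- 1 / rgamma(1L, shape = c_shape,
                                      rate = spec$sigma2_scale + ssr[k] / 2)
      }
      # random-walk steps on the per-voxel prior means (hierarchical only);
      # their conditionals involve only the Gaussian Fb / PS prior terms
      if (spec$hierarchical) {
        ab_prop <- state$alpha_b[k] + rnorm(1L) * alpha_proposal_sd
        if (ab_prop >= spec$alpha_b_support[1L] &&
            ab_prop <= spec$alpha_b_support[2L]) {
          dl <- ((state$theta[k, 1L] - state$alpha_b[k])^2 -
                   (state$theta[k, 1L] - ab_prop)^2) / (2 * spec$fb_var)
          if (log(runif(1L)) < dl) state$alpha_b[k] <- ab_prop
        }
        as_prop <- state$alpha_ps[k] + rnorm(1L) * alpha_proposal_sd
        if (as_prop >= spec$alpha_ps_support[1L] &&
            as_prop <= spec$alpha_ps_support[2L]) {
          dl <- ((state$theta[k, 4L] - state$alpha_ps[k])^2 -
                   (state$theta[k, 4L] - as_prop)^2) / (2 * spec$ps_var)
          if (log(runif(1L)) < dl) state$alpha_ps[k] <- as_prop
        }
      }
    }
    samples[s, , 1:4] <- state$theta
    samples[s, , 5L] <- state$sigma2
    samples[s, , 6L] <- state$alpha_b
    samples[s, , 7L] <- state$alpha_ps
    # proposal-scale adaptation, burn-in only
    if (s <= burn_in && s %% tune_interval == 0L) {
      rate <- acc_window / tune_interval
      scales[rate < 0.2, ] <- scales[rate < 0.2, , drop = FALSE] / 1.1
      scales[rate > 0.3, ] <- scales[rate > 0.3, , drop = FALSE] * 1.1
      acc_window[] <- 0L
    }
  }
  structure(list(samples = samples, graph = graph,
                 acceptance_fraction =
                   acc_post / (as.double(nvox) * (n_steps - burn_in)),
                 proposal_scales = scales, n_steps = n_steps,
                 burn_in = burn_in, seed = seed, spec = spec),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf(
    "<chain_state> %d sweeps (burn-in %d) over %d voxels; post-burn-in block acceptance %.3f\n",
    x$n_steps, x$burn_in, dim(x$samples)[2L], x$acceptance_fraction))
  invisible(x)
}

# Gelman-Rubin potential scale reduction from a (n x m) matrix of m chains
rhat_statistic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  means <- colMeans(draws)
  W <- mean(apply(draws, 2L, var))
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarise MCMC chains into posterior parameter maps
#'
#' Computes per-voxel posterior medians and coefficients of variation
#' (posterior sd / posterior mean) for every parameter from the
#' post-burn-in samples, arranged as maps over the mask. When two or more
#' independently seeded chains are supplied, the Gelman-Rubin R statistic
#' is computed per voxel and parameter as a convergence diagnostic.
#'
#' @param chain A [run_mcmc()] result.
#' @param burn_in Samples to discard; defaults to the chain's own burn-in.
#' @param more_chains Optional list of further `chain_state` objects from
#'   independent seeds, used only for R-hat.
#' @return Object of class `posterior_summary`: lists of matrices `median`,
#'   `cov` and (when requested) `rhat`, each with entries
#'   `fb, vp, ve, ps, sigma2`, plus `burn_in` and the mask.
#' @export
summarize_posterior <- function(chain, burn_in = chain$burn_in,
                                more_chains = NULL) {
  if (burn_in >= chain$n_steps)
    stop("`burn_in` must be below the chain length", call. = FALSE)
  keep <- seq.int(burn_in + 1L, chain$n_steps)
  pars <- c("fb", "vp", "ve", "ps", "sigma2")
  mask <- chain$graph$mask
  vox <- chain$graph$voxels
  blank <- matrix(NA_real_, nrow(mask), ncol(mask))
  med <- cv <- rh <- stats::setNames(vector("list", length(pars)), pars)
  for (p in pars) {
    m <- blank; v <- blank; r <- blank
    draws <- chain$samples[keep, , p]
    for (k in seq_len(nrow(vox))) {
      x <- draws[, k]
      m[vox[k, 1L], vox[k, 2L]] <- median(x)
      v[vox[k, 1L], vox[k, 2L]] <- sd(x) / mean(x)
      if (!is.null(more_chains)) {
        all_d <- cbind(x, vapply(more_chains,
                                 function(ch) ch$samples[keep, k, p],
                                 numeric(length(keep))))
        r[vox[k, 1L], vox[k, 2L]] <- rhat_statistic(all_d)
      }
    }
    med[[p]] <- m; cv[[p]] <- v; rh[[p]] <- r
  }
  structure(list(median = med, cov = cv,
                 rhat = if (!is.null(more_chains)) rh else NULL,
                 burn_in = burn_in, mask = mask),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> burn-in %d; median Fb over mask: %.3g mL/min/mL\n",
              x$burn_in, median(x$median$fb[x$mask])))
  invisible(x)
}
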