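# single-voxel series helper: a (t, 1, 1) array wrapped like a simulation
one_voxel_series <- function(values, dt = 0.012, aif = NULL) {
  times <- seq(0, by = dt, length.out = length(values))
  if (is.null(aif)) aif <- gamma_variate_aif(times)
  list(noisy = array(values, dim = c(length(values), 1L, 1L)),
       clean = NULL, aif = aif, times = times, dt = dt,
       mask = matrix(TRUE, 1, 1), tau0 = 0, hct = 0.45)
}

test_that("no stored sample ever leaves its prior support", {
  ser <- simulate_series(build_phantom("stress_defect"), seed = 3)
  ch <- run_mcmc(ser, n_steps = 400, burn_in = 200, seed = 8)
  s <- ch$samples
  expect_true(all(s[, , "fb"] > 0))
  expect_true(all(s[, , "ps"] > 0))
  expect_true(all(s[, , "vp"] > 0 & s[, , "vp"] <= 0.3))
  expect_true(all(s[, , "ve"] > 0 & s[, , "ve"] <= 0.4))
  expect_true(all(s[, , "sigma2"] > 0))
  expect_true(all(s[, , "alpha_b"] >= 0.001 & s[, , "alpha_b"] <= 7))
  expect_true(all(s[, , "alpha_ps"] >= 0.001 & s[, , "alpha_ps"] <= 5))
})

test_that("identical seeds give bit-identical chains", {
  ser <- simulate_series(build_phantom("stress"), seed = 3)
  a <- run_mcmc(ser, n_steps = 250, burn_in = 100, seed = 13)
  b <- run_mcmc(ser, n_steps = 250, burn_in = 100, seed = 13)
  expect_identical(a$samples, b$samples)
  expect_identical(a$acceptance_fraction, b$acceptance_fraction)
  c <- run_mcmc(ser, n_steps = 250, burn_in = 100, seed = 14)
  expect_false(identical(a$samples, c$samples))
})

test_that("with the likelihood switched off the chain samples the prior", {
  set.seed(1)
  ser <- one_voxel_series(rnorm(50, 0, 0.01))
  spec <- prior_spec(spatial = FALSE)
  # heavy thinning: the KS statistic assumes independent draws, and the
  # random-walk chain decorrelates over tens of sweeps
  ch <- run_mcmc(ser, spec = spec, n_steps = 61000, burn_in = 1000,
                 seed = 21, use_likelihood = FALSE,
                 init = list(sigma2 = 0.01))
  vp <- ch$samples[seq(1020, 61000, by = 20), 1, "vp"]
  expect_length(vp, 3000L)
  ks <- suppressWarnings(stats::ks.test(vp, "punif", 0, 0.3))
  expect_gt(ks$p.value, 0.01)
  # uniform moments as a second check (tolerance sized to the chain's
  # autocorrelation-adjusted Monte-Carlo error)
  expect_equal(mean(vp), 0.15, tolerance = 0.03)
})

test_that("the noise-variance update matches its conjugate closed form", {
  times <- time_grid(0.012, 1.5)
  aif <- gamma_variate_aif(times)
  truth <- kinetic_params(3.5, 0.08, 0.16, 1.0)
  clean <- forward_model(truth, aif)$values
  set.seed(2)
  y <- clean + rnorm(length(clean), sd = 0.05)
  ser <- one_voxel_series(y, aif = aif)
  spec <- prior_spec(spatial = FALSE)
  ch <- run_mcmc(ser, spec = spec, n_steps = 3500, burn_in = 500, seed = 31,
                 update_kinetics = FALSE,
                 init = list(fb = 3.5, vp = 0.08, ve = 0.16, ps = 1.0))
  draws <- ch$samples[501:3500, 1, "sigma2"]
  n <- length(y)
  ssr <- sum((clean - y)^2)
  shape <- 0.001 + n / 2
  rate <- 0.001 + ssr / 2
  true_mean <- rate / (shape - 1)
  true_var <- rate^2 / ((shape - 1)^2 * (shape - 2))
  mc_se <- sqrt(true_var / length(draws))
  expect_lt(abs(mean(draws) - true_mean), 3 * mc_se)
  # variance agrees within a generous Monte-Carlo band
  expect_equal(var(draws), true_var, tolerance = 0.2)
})

test_that("noise-free stress curves are recovered within 5% everywhere", {
  ser <- simulate_series(build_phantom("stress"), snr = Inf, seed = 1)
  ch <- run_mcmc(ser, n_steps = 600, burn_in = 300, seed = 17,
                 use_clean = TRUE)
  summ <- summarize_posterior(ch)
  expect_true(all(abs(summ$median$fb - 3.5) / 3.5 < 0.05))
  expect_true(all(abs(summ$median$vp - 0.08) / 0.08 < 0.05))
  expect_true(all(abs(summ$median$ve - 0.16) / 0.16 < 0.05))
  expect_true(all(abs(summ$median$ps - 1.0) < 0.05))
})

test_that("hierarchical priors adapt to a perfusion defect where fixed priors cannot", {
  ph <- build_phantom("stress_defect")
  defect <- ph$maps$fb == 1.0
  ser <- simulate_series(ph, seed = 7)
  hier <- summarize_posterior(run_mcmc(ser, n_steps = 1000, burn_in = 500,
                                       seed = 19))
  nonh <- summarize_posterior(run_mcmc(
    ser, spec = prior_spec(hierarchical = FALSE, fb_var = 0.2, ps_var = 0.2),
    n_steps = 1000, burn_in = 500, seed = 19))
  # flow inside the defect is strictly below the healthy surround
  expect_lt(mean(hier$median$fb[defect]), mean(hier$median$fb[!defect]))
  # and the hierarchical defect-region error beats the fixed-prior variant
  expect_lt(mean(abs(hier$median$fb[defect] - 1)),
            mean(abs(nonh$median$fb[defect] - 1)))
})

test_that("the Laplace spatial prior preserves the defect edge better than Gaussian", {
  ph <- build_phantom("stress_defect")
  ser <- simulate_series(ph, seed = 7)
  step_size <- function(summ) {
    g <- build_neighbour_graph(ph$mask)
    defect <- ph$maps$fb == 1.0
    steps <- c()
    for (i in seq_len(nrow(g$voxels))) for (j in g$neighbours[[i]]) {
      a <- g$voxels[i, ]; b <- g$voxels[j, ]
      if (defect[a[1], a[2]] && !defect[b[1], b[2]])
        steps <- c(steps, abs(summ$median$fb[a[1], a[2]] -
                                summ$median$fb[b[1], b[2]]))
    }
    mean(steps)
  }
  l1 <- summarize_posterior(run_mcmc(ser, spec = prior_spec(spatial_norm = 1),
                                     n_steps = 1000, burn_in = 500, seed = 23))
  l2 <- summarize_posterior(run_mcmc(ser, spec = prior_spec(spatial_norm = 2),
                                     n_steps = 1000, burn_in = 500, seed = 23))
  expect_gt(step_size(l1), step_size(l2))
})

test_that("posterior summaries follow their definitions", {
  # hand-built two-voxel chain
  mask <- matrix(c(TRUE, TRUE), 1, 2)
  g <- build_neighbour_graph(mask)
  n <- 400L
  samples <- array(NA_real_, c(n, 2L, 7L),
                   dimnames = list(NULL, NULL,
                                   c("fb", "vp", "ve", "ps", "sigma2",
                                     "alpha_b", "alpha_ps")))
  samples[, 1L, ] <- 2  # constant chain
  set.seed(4)
  for (p in dimnames(samples)[[3]]) samples[, 2L, p] <- rnorm(n, 2, 0.2)
  chain <- structure(list(samples = samples, graph = g, n_steps = n,
                          burn_in = 100L, seed = 1L, spec = prior_spec()),
                     class = "chain_state")
  s <- summarize_posterior(chain)
  expect_equal(s$median$fb[1, 1], 2)
  expect_equal(s$cov$fb[1, 1], 0)
  expect_equal(s$cov$fb[1, 2], 0.1, tolerance = 0.15)
  expect_error(summarize_posterior(chain, burn_in = 400L), "burn_in")
})

test_that("the R statistic is computed from multiple chains and detects identity", {
  draws <- matrix(rnorm(2000), 1000, 2)
  r <- perfusr:::rhat_statistic(draws)
  expect_lt(abs(r - 1), 0.02)
  # two identical chains: the degenerate closed form sqrt((n-1)/n)
  same <- cbind(draws[, 1], draws[, 1])
  expect_equal(perfusr:::rhat_statistic(same), sqrt(999 / 1000))
  expect_lte(perfusr:::rhat_statistic(same), 1)
  # diverged chains are flagged
  far <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(perfusr:::rhat_statistic(far), 2)
})
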