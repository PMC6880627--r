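test_that("residue function starts at one, decays monotonically, stays in [0,1]", {
  times <- time_grid(0.012, 3)
  set.seed(1)
  for (i in 1:5) {
    p <- random_params()
    r <- residue_function(p, times)$values
    expect_equal(r[1], 1.0)
    expect_true(all(diff(r) <= 1e-12))
    expect_true(all(r >= 0 & r <= 1))
    expect_lt(r[length(r)], 0.05)
  }
})

test_that("residue function reduces to the one-compartment limit when PS = 0", {
  times <- time_grid(0.01, 2)
  p <- kinetic_params(1.0, 0.08, 0.16, ps = 0)
  fp <- p$fb / (1 - p$hct)
  expect_equal(residue_function(p, times)$values, exp(-fp * times / p$vp),
               tolerance = 1e-12)
})

test_that("analytic residue function matches the narrow-pulse ODE oracle", {
  times <- time_grid(0.02, 1.5)
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    r_analytic <- residue_function(p, times)$values
    r_ode <- ode_residue(p, times)
    expect_lt(max(abs(r_analytic - r_ode)) / max(r_ode), 1e-5)
  }
})

test_that("nearly coincident eigenvalues stay finite and accurate", {
  # equal diagonal rates with a small exchange coupling: the eigenvalue gap
  # shrinks to ~10% of their magnitude, stressing the bi-exponential form
  times <- time_grid(0.01, 1.5)
  p <- kinetic_params(fb = 0.55, vp = 0.3, ve = 0.003, ps = 0.01)
  r <- residue_function(p, times)$values
  expect_true(all(is.finite(r)))
  expect_equal(r[1], 1.0)
  expect_true(all(diff(r) <= 1e-12))
  expect_lt(max(abs(r - ode_residue(p, times))), 1e-4)
})

test_that("forward model matches the ODE-system oracle", {
  times <- time_grid(0.012, 3)
  aif <- gamma_variate_aif(times)
  # stress phantom parameters
  p <- kinetic_params(3.5, 0.08, 0.16, 1.0)
  mine <- forward_model(p, aif)$values
  orac <- ode_tissue_curve(p, aif)
  expect_lt(sqrt(sum((mine - orac)^2) / sum(orac^2)), 1e-4)
  set.seed(11)
  for (i in 1:5) {
    p <- random_params()
    mine <- forward_model(p, aif)$values
    orac <- ode_tissue_curve(p, aif)
    expect_lt(sqrt(sum((mine - orac)^2) / sum(orac^2)), 1e-4)
  }
})

test_that("forward model is linear in the AIF and vanishes for zero input", {
  times <- time_grid(0.012, 2)
  aif <- gamma_variate_aif(times)
  p <- kinetic_params(2.0, 0.1, 0.2, 0.8)
  zero <- sampled_curve(times, rep(0, length(times)))
  expect_equal(forward_model(p, zero)$values, rep(0, length(times)))
  scaled <- sampled_curve(times, 3.7 * aif$values)
  expect_equal(forward_model(p, scaled)$values,
               3.7 * forward_model(p, aif)$values, tolerance = 1e-12)
})

test_that("unit-area narrow pulse reproduces the scaled residue function", {
  dt <- 0.002
  times <- time_grid(dt, 1)
  pulse <- sampled_curve(times, c(0, 1 / dt, rep(0, length(times) - 2)))
  p <- kinetic_params(1.5, 0.1, 0.2, 0.5)
  fp <- p$fb / (1 - p$hct)
  out <- forward_model(p, pulse)$values
  rf <- residue_function(p, times)$values
  # the discrete pulse is delayed by one sample
  expect_equal(out[-1], (fp * rf)[-length(rf)], tolerance = 0.02)
})

test_that("on-grid delay equals shifting the AIF by whole samples", {
  times <- time_grid(0.012, 2)
  aif <- gamma_variate_aif(times)
  k <- 5L
  p0 <- kinetic_params(2.0, 0.1, 0.2, 0.8, tau0 = k * 0.012)
  shifted <- sampled_curve(times, c(rep(0, k), aif$values[1:(length(times) - k)]))
  p_noshift <- kinetic_params(2.0, 0.1, 0.2, 0.8, tau0 = 0)
  expect_equal(forward_model(p0, aif)$values,
               forward_model(p_noshift, shifted)$values, tolerance = 1e-12)
})

test_that("forward model converges to the plasma-only model as ve, PS vanish", {
  times <- time_grid(0.012, 2)
  aif <- gamma_variate_aif(times)
  limit <- forward_model(kinetic_params(2, 0.1, 1e-6, 1e-8), aif)$values
  one_comp <- forward_model(kinetic_params(2, 0.1, 0.3, 0), aif)$values
  expect_equal(limit, one_comp, tolerance = 1e-4)
})

test_that("forward model rejects bad delays and mismatched grids", {
  times <- time_grid(0.012, 2)
  aif <- gamma_variate_aif(times)
  expect_error(forward_model(kinetic_params(1, 0.1, 0.2, 1, tau0 = 5), aif),
               "tau0")
  other <- gamma_variate_aif(time_grid(0.017, 2))
  expect_error(forward_model(kinetic_params(1, 0.1, 0.2, 1), other,
                             times = times), "grid")
})

test_that("gamma-variate AIF has the advertised support, peak and scaling", {
  times <- time_grid(0.005, 2)
  aif <- gamma_variate_aif(times, shape = 4, scale = 0.04, onset = 0.1)
  expect_true(all(aif$values[times <= 0.1] == 0))
  expect_true(all(aif$values >= 0))
  # analytic peak location onset + shape * scale
  expect_equal(times[which.max(aif$values)], 0.1 + 4 * 0.04,
               tolerance = 0.005)
  expect_equal(max(aif$values), 5, tolerance = 1e-3)
  expect_equal(sum(abs(gamma_variate_aif(times, amplitude = 0)$values)), 0)
  expect_error(gamma_variate_aif(times, shape = -1), "shape")
  expect_error(gamma_variate_aif(times, scale = 0), "scale")
})

test_that("signal-to-concentration conversion is linear with the stated constants", {
  S <- c(10, 10, 10)
  expect_equal(signal_to_concentration(S, S0 = 10, S_lv0 = 20), c(0, 0, 0))
  # 100% relative enhancement with r1 = 4.5 /s/mM, T1b = 1736 ms
  c1 <- signal_to_concentration(S = 2, S0 = 1, S_lv0 = 1, T1b = 1736)
  expect_equal(c1, 1 / (4.5 * 1.736))
  expect_equal(signal_to_concentration(S = 3, S0 = 1, S_lv0 = 1, T1b = 1736),
               2 * c1)
  expect_error(signal_to_concentration(S, 10, S_lv0 = 0), "S_lv0")
})

test_that("kinetic parameter invariants are enforced", {
  expect_error(kinetic_params(-1, 0.1, 0.2, 1), "fb")
  expect_error(kinetic_params(1, 0, 0.2, 1), "vp")
  expect_error(kinetic_params(1, 0.6, 0.5, 1), "vp \\+ ve")
  expect_error(kinetic_params(1, 0.1, 0.2, -0.1), "ps")
  expect_error(kinetic_params(1, 0.1, 0.2, 1, hct = 1), "hct")
})
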