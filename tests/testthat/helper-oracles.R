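# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the ODE oracle integrates the compartment
# system numerically (deSolve), and the rank-test oracle enumerates group
# assignments exhaustively.

# Tissue concentration by stiff numerical integration of the coupled
# plasma/interstitium ODEs, driven by the linear interpolant of the sampled
# AIF (shifted by tau0 the same way the analytic path shifts it, so the two
# share their input and differ only in the solution method).
ode_tissue_curve <- function(params, aif, rtol = 1e-10) {
  fp <- params$fb / (1 - params$hct)
  shifted <- approx(aif$times, aif$values, xout = aif$times - params$tau0,
                    yleft = 0, rule = 2)$y
  af <- approxfun(aif$times, shifted, yleft = 0, rule = 2)
  deriv <- function(t, y, parms) {
    dcp <- (fp * (af(t) - y[1]) + params$ps * (y[2] - y[1])) / params$vp
    dce <- params$ps * (y[1] - y[2]) / params$ve
    list(c(dcp, dce))
  }
  sol <- deSolve::ode(c(0, 0), aif$times, deriv, NULL, method = "lsoda",
                      rtol = rtol, atol = 1e-13)
  params$vp * sol[, 2] + params$ve * sol[, 3]
}

# Residue function by integrating the homogeneous system from the state an
# idealised unit-area impulse leaves behind (Cp(0+) = Fp/vp, Ce(0+) = 0),
# normalised so R(0) = 1.
ode_residue <- function(params, times) {
  fp <- params$fb / (1 - params$hct)
  deriv <- function(t, y, parms) {
    dcp <- (-fp * y[1] + params$ps * (y[2] - y[1])) / params$vp
    dce <- params$ps * (y[1] - y[2]) / params$ve
    list(c(dcp, dce))
  }
  sol <- deSolve::ode(c(fp / params$vp, 0), times, deriv, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-13)
  (params$vp * sol[, 2] + params$ve * sol[, 3]) / fp
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n + m, n) assignments of the pooled values to group A.
enumerate_mwu <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  m <- length(b)
  u_all <- apply(utils::combn(n + m, n), 2L, u_of)
  mu <- n * m / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p.value = min(1, p))
}

# random valid kinetic parameter set, away from degenerate corners
random_params <- function() {
  kinetic_params(fb = runif(1, 0.3, 5.5), vp = runif(1, 0.02, 0.25),
                 ve = runif(1, 0.05, 0.4), ps = runif(1, 0.05, 3.5))
}

# small shared fixtures
stress_series <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache) || cache$seed != seed)
      cache <<- simulate_series(build_phantom("stress"), seed = seed)
    cache
  }
})
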