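#' Least-squares cost surface demonstration
#'
#' Reproduces the classic illustration of why gradient-based 2CXM fitting
#' is fragile: a tissue curve is simulated from known parameters
#' (`Fb = 1.0`, `vp = 0.08`, `ve = 0.16`, `PS = 0.4`, `tau0 = 0.1` min by
#' default), optionally corrupted with Rician noise, and the chi-squared
#' cost is evaluated on a grid over `(Fb, tau0)` taking the minimum over a
#' grid of the remaining three parameters (a minimum-intensity projection
#' of the 5-D cost surface). With noise the projected surface develops
#' local optima away from the truth.
#'
#' @param truth A [kinetic_params()]; the simulated ground truth.
#' @param snr Signal-to-noise ratio of the added Rician noise; `Inf` for
#'   the noise-free surface.
#' @param seed Noise seed.
#' @param fb_grid,tau0_grid Grid values for the projected axes.
#' @param dt,duration Simulation grid (min).
#' @return List with the cost `surface` (matrix `length(fb_grid)` x
#'   `length(tau0_grid)`), the axes, the `truth` and the location of the
#'   surface minimum.
#' @export
cost_surface_demo <- function(truth = kinetic_params(1.0, 0.08, 0.16, 0.4,
                                                     tau0 = 0.1),
                              snr = 15, seed = 1L,
                              fb_grid = seq(0.2, 3, length.out = 30L),
                              tau0_grid = seq(0, 0.3, length.out = 16L),
                              dt = 0.012, duration = 3) {
  times <- time_grid(dt, duration)
  aif <- gamma_variate_aif(times)
  clean <- forward_model(truth, aif)$values
  yobs <- if (is.finite(snr))
    add_rician_noise(clean, max(clean) / snr, seed = seed) else clean
  # profile out (vp, ve, PS) at each (Fb, tau0) grid point by bounded
  # local minimisation from two starts
  starts <- list(c(0.08, 0.16, 0.4), c(0.2, 0.3, 1.5))
  surface <- matrix(Inf, length(fb_grid), length(tau0_grid))
  for (a in seq_along(fb_grid)) for (b in seq_along(tau0_grid)) {
    obj <- function(th)
      .cxm_chi2_cpp(aif$values, dt, yobs, fb_grid[a], th[1L], th[2L],
                    th[3L], tau0_grid[b], truth$hct)
    best <- Inf
    for (st in starts) {
      fit <- tryCatch(
        optim(st, obj, method = "L-BFGS-B", lower = c(0.001, 0.001, 0.001),
              upper = c(0.3, 0.4, 4), control = list(maxit = 300L)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$value < best) best <- fit$value
    }
    surface[a, b] <- best
  }
  minimum <- which(surface == min(surface), arr.ind = TRUE)[1L, ]
  list(surface = surface, fb_grid = fb_grid, tau0_grid = tau0_grid,
       truth = truth, minimum = c(fb = fb_grid[minimum[1L]],
                                  tau0 = tau0_grid[minimum[2L]]))
}
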