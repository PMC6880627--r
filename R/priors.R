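#' Prior specification for the hierarchical Bayesian 2CXM model
#'
#' Defines every constant of the voxel-wise posterior. Blood flow and PS get
#' Gaussian conditional priors whose means `alpha_b`, `alpha_ps` are
#' themselves per-voxel random variables with flat hyperpriors on closed
#' supports (the hierarchical layer that lets healthy and ischaemic voxels
#' pull their own prior means apart); `vp` and `ve` get flat priors on
#' bounded supports; the noise variance `sigma2` gets a vague Inverse-Gamma
#' prior; and neighbouring voxels are tied by a Laplace (L1,
#' edge-preserving) Markov-random-field prior on weighted parameter
#' differences.
#'
#' @param fb_var,ps_var Variances of the Gaussian conditional priors on
#'   `Fb` and `PS` (0.1 in the hierarchical model).
#' @param vp_max,ve_max Upper ends of the flat supports `(0, vp_max]`,
#'   `(0, ve_max]`.
#' @param sigma2_shape,sigma2_scale Inverse-Gamma shape `c` and scale `d`
#'   of the noise-variance prior (0.001 each: vague).
#' @param spatial_rate Rate of the spatial Laplace prior on weighted
#'   neighbour differences (1/0.2 = 5).
#' @param spatial_norm 1 for the Laplace (L1) spatial prior, 2 for a
#'   Gaussian (L2) variant used only for comparison.
#' @param spatial Logical; disable to drop the spatial term entirely.
#' @param alpha_b_support,alpha_ps_support Closed hyperprior supports for
#'   the prior means of `Fb` and `PS`.
#' @param hierarchical Logical. `FALSE` freezes the prior means at
#'   `alpha_b_fixed` / `alpha_ps_fixed` (no hyperprior step), the
#'   non-hierarchical comparator with `Fb ~ N(X, 0.2)` and
#'   `PS ~ N(1, 0.2)`.
#' @param alpha_b_fixed,alpha_ps_fixed Fixed prior means used when
#'   `hierarchical = FALSE`.
#' @param weight_floor Per-parameter floor applied to the previous sample
#'   before inverting it into the spatial weight `W_k`, preventing
#'   division blow-up (defaults to the NLLS lower bounds).
#' @param weight_source Whose previous sample the spatial weight inverts:
#'   the voxel's own (`"self"`), the neighbour's (`"neighbour"`), or their
#'   mean (`"symmetric"`, the default). The weights exist to put the four
#'   parameters on a common relative scale; the symmetric form
#'   `W_k = 2/(theta_k^i + theta_k^j)` treats the two sides of a tissue
#'   boundary evenly, so a healthy/ischaemic edge is penalised by the
#'   *relative* flow difference rather than by whichever side's magnitude
#'   happens to be used.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(fb_var = 0.1, ps_var = 0.1, vp_max = 0.3,
                       ve_max = 0.4, sigma2_shape = 0.001,
                       sigma2_scale = 0.001, spatial_rate = 5,
                       spatial_norm = 1, spatial = TRUE,
                       alpha_b_support = c(0.001, 7),
                       alpha_ps_support = c(0.001, 5),
                       hierarchical = TRUE, alpha_b_fixed = 3.5,
                       alpha_ps_fixed = 1.0,
                       weight_floor = c(fb = 0.001, vp = 0.001, ve = 0.001,
                                        ps = 0.001),
                       weight_source = c("symmetric", "self", "neighbour")) {
  weight_source <- match.arg(weight_source)
  stopifnot(fb_var > 0, ps_var > 0, vp_max > 0, ve_max > 0,
            sigma2_shape > 0, sigma2_scale > 0, spatial_rate > 0,
            spatial_norm %in% c(1, 2), all(weight_floor > 0))
  structure(list(fb_var = fb_var, ps_var = ps_var, vp_max = vp_max,
                 ve_max = ve_max, sigma2_shape = sigma2_shape,
                 sigma2_scale = sigma2_scale, spatial_rate = spatial_rate,
                 spatial_norm = spatial_norm, spatial = spatial,
                 alpha_b_support = alpha_b_support,
                 alpha_ps_support = alpha_ps_support,
                 hierarchical = hierarchical,
                 alpha_b_fixed = alpha_b_fixed,
                 alpha_ps_fixed = alpha_ps_fixed,
                 weight_floor = weight_floor,
                 weight_source = weight_source),
            class = "prior_spec")
}

#' Gaussian log-likelihood of a concentration curve
#'
#' i.i.d. Gaussian observation model `y(t_j) ~ N(C_model(t_j), sigma2)`:
#' `log L = -(N/2) log(2 pi sigma2) - SSR / (2 sigma2)`.
#'
#' @param params A [kinetic_params()].
#' @param sigma2 Noise variance (> 0).
#' @param curve Observed [sampled_curve()].
#' @param aif Arterial input [sampled_curve()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, sigma2, curve, aif) {
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  check_same_grid(curve, aif)
  ssr <- .cxm_ssr_cpp(aif$values, aif$dt, curve$values, params$fb, params$vp,
                      params$ve, params$ps, params$tau0, params$hct)
  n <- length(curve$values)
  -(n / 2) * log(2 * pi * sigma2) - ssr / (2 * sigma2)
}

# Spatial weights W_k for one voxel, as a 4 x n_nb matrix matching the
# transposed neighbour layout of spatial_log_term(). Built from *previous*
# accepted samples only (never the proposal), so they are constants of the
# acceptance decision. Floored to avoid division blow-up.
spatial_weights <- function(theta_prev, neighbour_theta, spec) {
  fl <- spec$weight_floor
  switch(spec$weight_source,
    self = 1 / pmax(theta_prev, fl),                      # length 4, recycles
    neighbour = 1 / pmax(t.default(neighbour_theta), fl),
    symmetric = 2 / pmax(t.default(neighbour_theta) + theta_prev, 2 * fl))
}

# spatial MRF log term for one voxel given its neighbours' current values.
# theta: length 4; neighbour_theta: n_nb x 4 matrix; weights: length-4
# vector or 4 x n_nb matrix.
spatial_log_term <- function(theta, neighbour_theta, weights, spec) {
  if (!spec$spatial || is.null(neighbour_theta) ||
      nrow(neighbour_theta) == 0L) return(0)
  # columns of t(neighbour_theta) are neighbours, so `theta` and vector
  # `weights` recycle down the parameter dimension without sweep()
  wd <- weights * abs(t.default(neighbour_theta) - theta)
  if (spec$spatial_norm == 1) -spec$spatial_rate * sum(wd)
  else -spec$spatial_rate * sum(wd * wd)
}

# kinetic-parameter part of the log prior (support indicators + Gaussians +
# spatial term); used inside the sampler where sigma2 terms cancel.
log_prior_kinetic <- function(theta, alpha_b, alpha_ps, neighbour_theta,
                              weights, spec) {
  fb <- theta[1L]; vp <- theta[2L]; ve <- theta[3L]; ps <- theta[4L]
  if (fb <= 0 || ps <= 0 || vp <= 0 || vp > spec$vp_max ||
      ve <= 0 || ve > spec$ve_max)
    return(-Inf)
  lp <- -0.5 * log(2 * pi * spec$fb_var) - (fb - alpha_b)^2 / (2 * spec$fb_var) -
    0.5 * log(2 * pi * spec$ps_var) - (ps - alpha_ps)^2 / (2 * spec$ps_var)
  lp + spatial_log_term(theta, neighbour_theta, weights, spec)
}

#' Log prior density of one voxel's parameters
#'
#' Evaluates the full conditional prior of Eq-style hierarchical model:
#' Gaussian terms for `Fb` and `PS` around their (hyper)means, flat
#' indicator terms for `vp` and `ve`, an Inverse-Gamma term for `sigma2`
#' and the spatial Laplace term over the voxel's neighbours. Returns `-Inf`
#' outside any support.
#'
#' @param params A [kinetic_params()].
#' @param sigma2 Noise variance.
#' @param hyper Numeric vector `c(alpha_b, alpha_ps)`.
#' @param neighbour_params Matrix with one row per neighbour and columns
#'   `(fb, vp, ve, ps)`; `NULL` for no spatial term.
#' @param spec A [prior_spec()].
#' @param weights Positive spatial weights `W_k`: either one value per
#'   kinetic parameter or a `4 x n_neighbours` matrix of per-pair weights
#'   (the sampler builds them from previous samples per
#'   `spec$weight_source`, floored at `spec$weight_floor`; see
#'   [prior_spec()]).
#' @return Scalar log prior density (up to the flat-indicator constants).
#' @export
log_prior <- function(params, sigma2, hyper, neighbour_params = NULL,
                      spec = prior_spec(), weights = rep(1, 4)) {
  if (any(weights <= 0)) stop("`weights` must be strictly positive", call. = FALSE)
  theta <- c(params$fb, params$vp, params$ve, params$ps)
  lp <- log_prior_kinetic(theta, hyper[1L], hyper[2L], neighbour_params,
                          weights, spec)
  if (!is.finite(lp)) return(-Inf)
  if (sigma2 <= 0) return(-Inf)
  cc <- spec$sigma2_shape; d <- spec$sigma2_scale
  lp + cc * log(d) - lgamma(cc) - (cc + 1) * log(sigma2) - d / sigma2
}

#' Log hyperprior of the prior means
#'
#' Flat on the closed boxes `alpha_b in [0.001, 7]`,
#' `alpha_ps in [0.001, 5]`: 0 inside, `-Inf` outside.
#'
#' @param alpha_b,alpha_ps Prior means of `Fb` and `PS`.
#' @param spec A [prior_spec()].
#' @return 0 or `-Inf`.
#' @export
log_hyperprior <- function(alpha_b, alpha_ps, spec = prior_spec()) {
  inside <- alpha_b >= spec$alpha_b_support[1L] &&
    alpha_b <= spec$alpha_b_support[2L] &&
    alpha_ps >= spec$alpha_ps_support[1L] &&
    alpha_ps <= spec$alpha_ps_support[2L]
  if (inside) 0 else -Inf
}

#' Neighbour graph of masked voxels
#'
#' Each masked voxel's neighbours are its in-mask 4-neighbours (above,
#' below, left, right). Where a 4-neighbour falls outside the mask -- as
#' happens along the edge of a myocardial segmentation -- an in-mask voxel
#' diagonally above or below is substituted, or failing that the closest
#' in-mask voxel. No voxel is its own neighbour.
#'
#' @param mask Logical matrix.
#' @return List of class `neighbour_graph`: `voxels` (n x 2 matrix of
#'   row/col indices of masked voxels, raster order), `neighbours` (list of
#'   integer vectors indexing into `voxels`), and `mask`.
#' @export
build_neighbour_graph <- function(mask) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (sum(mask) == 1L)
    stop("mask has a single voxel: no neighbour exists", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  # raster order: row-major sweep
  vox <- which(t(mask), arr.ind = FALSE)
  coords <- cbind(row = (vox - 1L) %/% nc + 1L, col = (vox - 1L) %% nc + 1L)
  index_of <- matrix(NA_integer_, nr, nc)
  for (k in seq_len(nrow(coords))) index_of[coords[k, 1L], coords[k, 2L]] <- k
  in_mask <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j]
  neighbours <- vector("list", nrow(coords))
  for (k in seq_len(nrow(coords))) {
    i <- coords[k, 1L]; j <- coords[k, 2L]
    nb <- integer(0)
    four <- list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
    diagonals <- list(c(i - 1L, j - 1L), c(i - 1L, j + 1L),
                      c(i + 1L, j - 1L), c(i + 1L, j + 1L))
    for (p in four) {
      if (in_mask(p[1L], p[2L])) {
        nb <- c(nb, index_of[p[1L], p[2L]])
      } else {
        # fallback: a diagonal in-mask voxel not already used, else the
        # closest in-mask voxel to the missing position
        sub <- NA_integer_
        for (q in diagonals) {
          if (in_mask(q[1L], q[2L]) && !(index_of[q[1L], q[2L]] %in% nb)) {
            sub <- index_of[q[1L], q[2L]]
            break
          }
        }
        if (is.na(sub)) {
          dists <- (coords[, 1L] - p[1L])^2 + (coords[, 2L] - p[2L])^2
          dists[k] <- Inf
          dists[nb] <- Inf
          if (any(is.finite(dists))) sub <- which.min(dists)
        }
        if (!is.na(sub)) nb <- c(nb, sub)
      }
    }
    neighbours[[k]] <- unique(nb)
  }
  structure(list(voxels = coords, neighbours = neighbours, mask = mask),
            class = "neighbour_graph")
}

# neighbourless graph used when the spatial prior is disabled
trivial_graph <- function(mask) {
  nc <- ncol(mask)
  vox <- which(t(mask), arr.ind = FALSE)
  coords <- cbind(row = (vox - 1L) %/% nc + 1L, col = (vox - 1L) %% nc + 1L)
  structure(list(voxels = coords,
                 neighbours = rep(list(integer(0)), nrow(coords)),
                 mask = mask),
            class = "neighbour_graph")
}
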