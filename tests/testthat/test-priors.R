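test_that("Gaussian log-likelihood has its closed form at zero residual", {
  times <- time_grid(0.012, 1)
  aif <- gamma_variate_aif(times)
  p <- kinetic_params(2, 0.1, 0.2, 0.8)
  clean <- forward_model(p, aif)
  n <- length(times)
  s2 <- 0.01
  expect_equal(log_likelihood(p, s2, clean, aif), -(n / 2) * log(2 * pi * s2))
  # doubling sigma^2 at fixed residuals changes the value by the closed form
  noisy <- sampled_curve(times, clean$values + 0.02)
  ssr <- n * chi_squared(p, noisy, aif)
  delta <- log_likelihood(p, 2 * s2, noisy, aif) -
    log_likelihood(p, s2, noisy, aif)
  expect_equal(delta, -(n / 2) * log(2) + (ssr / 2) * (1 / s2 - 1 / (2 * s2)))
  expect_error(log_likelihood(p, 0, clean, aif), "sigma2")
})

test_that("log-likelihood is maximised over sigma^2 at SSR/N", {
  times <- time_grid(0.012, 1)
  aif <- gamma_variate_aif(times)
  p <- kinetic_params(2, 0.1, 0.2, 0.8)
  noisy <- sampled_curve(times, forward_model(p, aif)$values + 0.03)
  n <- length(times)
  ssr <- n * chi_squared(p, noisy, aif)
  grid <- seq(0.2, 5, by = 0.01) * ssr / n
  ll <- vapply(grid, function(s) log_likelihood(p, s, noisy, aif), numeric(1))
  expect_equal(grid[which.max(ll)], ssr / n, tolerance = 0.01)
})

test_that("log prior respects supports and the spatial term's closed form", {
  spec <- prior_spec()
  p_in <- kinetic_params(3.5, 0.1, 0.2, 1.0)
  p_out <- kinetic_params(3.5, 0.35, 0.2, 1.0)  # vp above its 0.3 support
  hyper <- c(3.5, 1.0)
  expect_true(is.finite(log_prior(p_in, 0.01, hyper, NULL, spec)))
  expect_identical(log_prior(p_out, 0.01, hyper, NULL, spec), -Inf)
  # identical neighbours contribute nothing
  nb <- matrix(c(3.5, 0.1, 0.2, 1.0), 1, 4)
  expect_equal(log_prior(p_in, 0.01, hyper, nb, spec),
               log_prior(p_in, 0.01, hyper, NULL, spec))
  # single neighbour, one parameter differing by 0.1 at weight 1, rate 5
  nb2 <- matrix(c(3.6, 0.1, 0.2, 1.0), 1, 4)
  expect_equal(log_prior(p_in, 0.01, hyper, nb2, spec, weights = rep(1, 4)) -
                 log_prior(p_in, 0.01, hyper, nb, spec, weights = rep(1, 4)),
               -0.5)
})

test_that("hyperprior is flat on its closed supports and -Inf outside", {
  expect_identical(log_hyperprior(3.5, 1.0), 0)
  expect_identical(log_hyperprior(7.5, 1.0), -Inf)
  expect_identical(log_hyperprior(3.5, 5.5), -Inf)
  expect_identical(log_hyperprior(0.001, 5), 0)  # boundaries inclusive
  expect_identical(log_hyperprior(7, 0.001), 0)
})

test_that("neighbour graph gives interior voxels their 4-neighbourhood", {
  g <- build_neighbour_graph(matrix(TRUE, 6, 6))
  interior <- which(g$voxels[, 1] == 3 & g$voxels[, 2] == 3)
  nb <- g$neighbours[[interior]]
  expect_length(nb, 4L)
  got <- g$voxels[nb, , drop = FALSE]
  expect_setequal(paste(got[, 1], got[, 2]),
                  c("2 3", "4 3", "3 2", "3 4"))
})

test_that("edge voxels fall back to diagonal in-mask substitutes", {
  g <- build_neighbour_graph(matrix(TRUE, 6, 6))
  corner <- which(g$voxels[, 1] == 1 & g$voxels[, 2] == 1)
  nb <- g$voxels[g$neighbours[[corner]], , drop = FALSE]
  # the two in-mask 4-neighbours plus a diagonal substitute
  expect_true(all(c("2 1", "1 2") %in% paste(nb[, 1], nb[, 2])))
  expect_gte(nrow(nb), 3L)
  expect_false("1 1" %in% paste(nb[, 1], nb[, 2]))  # never its own neighbour
})

test_that("a C-shaped mask substitutes diagonals for out-of-mask neighbours", {
  mask <- matrix(TRUE, 4, 4)
  mask[2:3, 3:4] <- FALSE  # notch: voxel (2,2)'s right neighbour is gone
  g <- build_neighbour_graph(mask)
  k <- which(g$voxels[, 1] == 2 & g$voxels[, 2] == 2)
  nb <- g$voxels[g$neighbours[[k]], , drop = FALSE]
  labels <- paste(nb[, 1], nb[, 2])
  expect_true(all(c("1 2", "3 2", "2 1") %in% labels))
  # the missing (2,3) was replaced by an in-mask diagonal of (2,2)
  expect_true(any(c("1 1", "1 3", "3 1", "3 3") %in% labels))
})

test_that("in-mask 4-neighbour relations are symmetric", {
  mask <- matrix(TRUE, 5, 5)
  mask[c(1, 7, 13, 19, 25)] <- FALSE
  g <- build_neighbour_graph(mask)
  for (i in seq_len(nrow(g$voxels))) for (j in g$neighbours[[i]]) {
    d <- abs(g$voxels[i, ] - g$voxels[j, ])
    if (sum(d) == 1L)  # a true 4-neighbour pair
      expect_true(i %in% g$neighbours[[j]])
  }
})

test_that("degenerate masks are rejected", {
  expect_error(build_neighbour_graph(matrix(FALSE, 3, 3)), "empty")
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  expect_error(build_neighbour_graph(m), "single")
})
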