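test_that("level-set initializations have the stated geometry", {
  phi <- initialize_phi(c(65, 65), "circle", radius = 12)
  expect_equal(phi[33, 33], 12)
  expect_equal(phi[33, 45], 0)          # on the circle
  expect_identical(phi, initialize_phi(c(65, 65), "circle", radius = 12))

  cb <- initialize_phi(c(60, 60), "checkerboard", period = 5)
  expect_true(any(cb > 0) && any(cb < 0))
  expect_lt(abs(mean(cb)), 1e-10)
})

test_that("sharp Heaviside follows the step definition", {
  expect_equal(heaviside(0.5), 1)
  expect_equal(heaviside(-0.5), 0)
  expect_equal(heaviside(0), 1)
  # smooth surrogate is a sigmoid around 0
  expect_equal(heaviside(0, eps = 1), 0.5)
  expect_equal(dirac(0, 1), 1 / pi)
})

test_that("region means reduce to sharp-partition arithmetic", {
  u <- matrix(seq(0.1, 1.6, by = 0.1), 4, 4)
  phi <- matrix(rep(c(1, -1), each = 8), 4, 4)   # left half in, right out
  cm <- region_means(u, phi, eps = 0)
  expect_equal(unname(cm["c1"]), mean(u[, 1:2]))
  expect_equal(unname(cm["c2"]), mean(u[, 3:4]))

  const <- matrix(0.7, 4, 4)
  expect_equal(unname(region_means(const, phi, 0)), c(0.7, 0.7))

  all_in <- matrix(1, 4, 4)
  expect_true(is.na(region_means(u, all_in, 0)["c2"]))
})

test_that("a two-valued disc image is segmented exactly", {
  u <- matrix(0, 64, 64); u[20:40, 22:42] <- 1
  fit <- chan_vese(u, init_radius = 18, max_iters = 400)
  expect_identical(fit$mask, u > 0.5)
  expect_equal(fit$c1, 1, tolerance = 1e-8)
  expect_equal(fit$c2, 0, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("the energy audit is non-increasing along the flow", {
  u <- matrix(0, 64, 64); u[20:40, 22:42] <- 1
  fit <- chan_vese(u, tau = 0.5, init_radius = 18, reinit_every = 0,
                   means_eps = 1, track_energy = TRUE, max_iters = 300)
  expect_true(all(diff(fit$energy) <= 1e-6))
})

test_that("swapping the region weights and negating phi complements", {
  u <- matrix(0, 64, 64); u[20:40, 22:42] <- 1
  phi0 <- initialize_phi(dim(u), "circle", radius = 18)
  f1 <- chan_vese(u, lambda1 = 1, lambda2 = 2, init = phi0,
                  reinit_every = 0, max_iters = 200)
  f2 <- chan_vese(u, lambda1 = 2, lambda2 = 1, init = -phi0,
                  reinit_every = 0, max_iters = 200)
  expect_identical(f1$mask, !f2$mask)
})

test_that("the evolution is shift-invariant when the weights are equal", {
  u <- matrix(0, 64, 64); u[20:40, 22:42] <- 1
  phi0 <- initialize_phi(dim(u), "circle", radius = 18)
  fa <- chan_vese(u, lambda1 = 1, lambda2 = 1, init = phi0,
                  reinit_every = 0, max_iters = 150, normalize = FALSE)
  fb <- chan_vese(u + 0.3, lambda1 = 1, lambda2 = 1, init = phi0,
                  reinit_every = 0, max_iters = 150, normalize = FALSE)
  expect_identical(fa$mask, fb$mask)
})

test_that("a heavier length penalty yields a shorter boundary on noise", {
  u <- matrix(0, 64, 64); u[20:40, 22:42] <- 1
  un <- u + with_seed_noise(7, dim(u), 0.25)
  perimeter <- function(m) {
    sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
  }
  lo <- chan_vese(un, mu = 0.2, init_radius = 18, max_iters = 400)
  hi <- chan_vese(un, mu = 2, init_radius = 18, max_iters = 400)
  expect_lte(perimeter(hi$mask), perimeter(lo$mask))
})
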