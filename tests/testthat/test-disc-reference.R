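# Independent oracle for the closed-form disc solution: a finite-volume
# discretization of the radial ODE  (1/r)(r k theta')' = P theta - Qm  on
# a staggered grid (no node at r = 0), solved by the Thomas algorithm.
radial_fv_theta0 <- function(a, tumor, surround, rho_b = 1052, cp_b = 3800,
                             R = 0.06, h = 2.5e-5) {
  n <- round(R / h)
  r <- (seq_len(n) - 0.5) * h          # cell centres
  inside <- r < a
  kc <- ifelse(inside, tumor$k, surround$k)
  P <- ifelse(inside, tumor$wb, surround$wb) * rho_b * cp_b
  Q <- ifelse(inside, tumor$qm, surround$qm)
  rf <- seq_len(n - 1) * h             # interior faces
  kf <- 2 * kc[-n] * kc[-1] / (kc[-n] + kc[-1])
  w <- kf * rf / h                     # face conductances
  lower <- numeric(n); upper <- numeric(n); diag <- numeric(n); rhs <- numeric(n)
  for (i in seq_len(n)) {
    wl <- if (i > 1) w[i - 1] else 0   # zero-flux at r = 0
    wu <- if (i < n) w[i] else 0
    diag[i] <- -(wl + wu) / (r[i] * h) - P[i]
    if (i > 1) lower[i] <- wl / (r[i] * h)
    if (i < n) upper[i] <- wu / (r[i] * h)
    rhs[i] <- -Q[i]
  }
  # Dirichlet far field: theta(R) = surround plateau
  rhs[n] <- rhs[n] - (kc[n] * R / h) / (r[n] * h) *
    (surround$qm / (surround$wb * rho_b * cp_b))
  diag[n] <- diag[n] - (kc[n] * R / h) / (r[n] * h)
  # Thomas algorithm
  for (i in 2:n) {
    m <- lower[i] / diag[i - 1]
    diag[i] <- diag[i] - m * upper[i - 1]
    rhs[i] <- rhs[i] - m * rhs[i - 1]
  }
  x <- numeric(n)
  x[n] <- rhs[n] / diag[n]
  for (i in (n - 1):1) x[i] <- (rhs[i] - upper[i] * x[i + 1]) / diag[i]
  x[1]
}

tumor_props <- list(k = 0.565, qm = 25000, wb = 0.0016)
wm_props <- list(k = 0.503, qm = 4517.9, wb = 0.0036956)

test_that("a homogeneous medium yields the constant perfusion plateau", {
  ref <- disc_reference_temperature(0.01, wm_props, wm_props)
  plateau <- wm_props$qm / (wm_props$wb * 1052 * 3800)
  rr <- c(0, 0.003, 0.01, 0.02, 0.05)
  expect_equal(ref$theta(rr), rep(plateau, length(rr)), tolerance = 1e-10)
  expect_equal(ref$center_rise, 0, tolerance = 1e-10)
})

test_that("a very large tumor saturates at its own perfusion cap", {
  ref <- disc_reference_temperature(1, tumor_props, wm_props)
  cap <- tumor_props$qm / (tumor_props$wb * 1052 * 3800)
  expect_equal(ref$theta(0), cap, tolerance = 1e-6)
})

test_that("the Bessel profile matches an independent radial FV solve", {
  ref <- disc_reference_temperature(0.01, tumor_props, wm_props)
  fv <- radial_fv_theta0(0.01, tumor_props, wm_props)
  expect_lt(abs(ref$theta(0) - fv), 1e-4)
})

test_that("profile is continuous at the interface and decays outward", {
  a <- 0.0075
  ref <- disc_reference_temperature(a, tumor_props, wm_props)
  expect_lt(abs(ref$theta(a - 1e-9) - ref$theta(a + 1e-9)), 1e-6)
  r_out <- seq(a, 0.05, length.out = 50)
  expect_true(all(diff(ref$theta(r_out)) < 0))
})
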