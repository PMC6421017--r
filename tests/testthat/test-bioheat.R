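props_default <- tissue_properties()

test_that("stability bound matches direct evaluation of the inequality", {
  ph <- make_circular_phantom(64, 1, 0)     # WM only
  dx <- 1e-3
  wm_bound <- 2 * dx^2 * 1027.4 * 3600 /
    (0.0036956 * 1052 * 3800 * dx^2 + 12 * 0.503)
  expect_equal(max_stable_dt(ph, props_default), wm_bound, tolerance = 1e-12)
  expect_gt(wm_bound, 0.1)   # the standard 0.1 s step is admissible

  # unperfused tissue reduces to rho Cp dx^2 / (6 k)
  csf_only <- make_circular_phantom(64, 1, 0, surround = "CSF")
  expect_equal(max_stable_dt(csf_only, props_default),
               1000 * 4200 * dx^2 / (6 * 0.6), tolerance = 1e-12)

  # increasing conductivity strictly tightens the bound
  hot <- set_tissue_property(props_default, "WM", k = 2 * 0.503)
  expect_lt(max_stable_dt(ph, hot), wm_bound)
})

test_that("the 0.1 s step is stable for every tissue in the default table", {
  tt <- props_default$tissues
  dx <- 1e-3
  bounds <- 2 * dx^2 * tt$rho * tt$cp /
    (tt$wb * props_default$rho_b * props_default$cp_b * dx^2 + 12 * tt$k)
  expect_true(all(bounds > 0.1))
})

test_that("a time step above the stability bound is refused", {
  ph <- make_circular_phantom(48, 1, 10)
  bound <- max_stable_dt(ph, props_default)
  expect_error(solve_steady(ph, props_default,
                            solver_config(dt = 1.1 * bound)),
               "stability error")
  expect_error(solve_transient(ph, props_default,
                               solver_config(dt = 1.1 * bound),
                               solve_steady(ph, props_default,
                                            solver_config(max_iters = 10)),
                               sample_times = 1.1 * bound),
               "stability error")
})

test_that("uniform body temperature is a fixed point without sources", {
  # no metabolic heat, no perfusion: Laplace with uniform Dirichlet data
  inert <- props_default
  for (t in c("CSF", "GM", "WM", "TUMOR"))
    inert <- set_tissue_property(inert, t, qm = 0, wb = 0)
  ph <- make_circular_phantom(48, 1, 10)
  fld <- solve_steady(ph, inert, solver_config())
  expect_equal(max(abs(fld$values - 37)), 0)
  expect_true(fld$converged)

  # with perfusion but qm = 0 and T = Ta the sink term also vanishes
  perf <- props_default
  for (t in c("CSF", "GM", "WM", "TUMOR"))
    perf <- set_tissue_property(perf, t, qm = 0)
  fld2 <- solve_steady(ph, perf, solver_config())
  expect_equal(max(abs(fld2$values - 37)), 0)
})

test_that("steady solve is deterministic and respects the maximum principle", {
  d <- disc96()
  again <- solve_steady(d$phantom, props_default, solver_config())
  expect_identical(d$field$values, again$values)
  # Qm >= 0 everywhere: no pixel below min(T_boundary, Ta)
  expect_gte(min(d$field$values), 37)
  # background pixels stay at the boundary temperature
  expect_true(all(d$field$values[!brain_mask(d$phantom)] == 37))
  expect_true(d$field$converged)
})

test_that("steady centre rise increases with tumor diameter", {
  ctr <- c(48.5, 48.5)
  rise <- vapply(c(8, 12, 16), function(dm) {
    ph <- make_circular_phantom(96, 1, dm)
    f <- solve_steady(ph, props_default, solver_config())
    max(f$values)
  }, numeric(1))
  expect_true(all(diff(rise) > 0))
})

test_that("cold stress subtracts exactly and supports the protocol values", {
  d <- disc96()
  expect_identical(apply_cold_stress(d$field, 0)$values, d$field$values)
  for (tc in c(0.25, 0.5, 1.0))
    expect_equal(max(abs(d$field$values - apply_cold_stress(d$field, tc)$values
                         - tc)), 0)
  expect_error(apply_cold_stress(d$field, -1))
})

test_that("an equilibrium field persists through a transient solve", {
  d <- disc96()
  snaps <- solve_transient(d$phantom, props_default, solver_config(),
                           d$field, c(5, 20))
  for (s in snaps)
    expect_lt(max(abs(s$values - d$field$values)), 10 * 1e-7 * 5 / 0.1)
})

test_that("recovery from cold stress approaches equilibrium monotonically", {
  d <- disc96()
  cooled <- apply_cold_stress(d$field, 0.5)
  snaps <- solve_transient(d$phantom, props_default, solver_config(),
                           cooled, c(5, 100, 600))
  sup <- vapply(snaps, function(s) max(abs(s$values - d$field$values)),
                numeric(1))
  expect_true(all(diff(sup) <= 0))
})

test_that("thermal noise is seeded, scaled to the brain dynamic range", {
  v <- matrix(37 + seq(0, 2, length.out = 256 * 256), 256, 256)
  fld <- temp_field(v, 1)
  expect_identical(add_noise(fld, 0, seed = 1)$values, v)
  a <- add_noise(fld, 2, seed = 4)
  b <- add_noise(fld, 2, seed = 4)
  expect_identical(a$values, b$values)
  sigma <- 0.02 * diff(range(v))
  expect_lt(abs(sd(a$values - v) - sigma) / sigma, 0.05)
})
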