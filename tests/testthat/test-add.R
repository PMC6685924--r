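test_that("sampled diameters respect the truncation bounds and the seed", {
  add <- add_spec("lognormal", meanlog = log(0.3), sdlog = 0.4,
                  d_min = 0.2, d_max = 1.2)
  d <- sample_diameters(add, 1e4, seed = 7)
  expect_length(d, 1e4)
  expect_true(all(d >= 0.2 & d <= 1.2))
  expect_identical(d, sample_diameters(add, 1e4, seed = 7))
  expect_false(identical(d[1:10], sample_diameters(add, 10, seed = 8)))
})

test_that("a degenerate single-diameter ADD reproduces that diameter", {
  add <- add_spec("empirical", diameters = 1.0, d_min = 0.5, d_max = 1.5)
  expect_equal(sample_diameters(add, 5, seed = 1), rep(1.0, 5))
})

test_that("truncated-lognormal sample mean matches the analytic moment", {
  add <- fixture_add()
  # independent oracle: numerical integration of the truncated density
  dens_mass <- integrate(function(z) dlnorm(z, add$meanlog, add$sdlog),
                         add$d_min, add$d_max)$value
  m1_num <- integrate(function(z) z * dlnorm(z, add$meanlog, add$sdlog),
                      add$d_min, add$d_max)$value / dens_mass
  m <- add_moments(add)
  expect_equal(m$m1, m1_num, tolerance = 1e-6)
  d <- sample_diameters(add, 1e4, seed = 3)
  expect_equal(mean(d), m1_num, tolerance = 0.02)
})

test_that("invalid distribution parameters are rejected", {
  expect_error(add_spec("lognormal", meanlog = NA, sdlog = 0.3), "finite")
  expect_error(add_spec("lognormal", meanlog = 0, sdlog = 0.3,
                        d_min = -1, d_max = 1), "d_min")
  expect_error(add_spec("lognormal", meanlog = log(100), sdlog = 0.01,
                        d_min = 0.1, d_max = 1), "mass")
  expect_error(add_spec("empirical", diameters = numeric(0)), "empirical")
})

test_that("ECS width follows the atmosphere relation", {
  # single radius r at alpha = 0.5: V/S = r/2 and alpha/(1-alpha) = 1
  g1 <- geometry(data.frame(x = 1, y = 1, r = 0.4), c(2, 2), check = FALSE)
  expect_equal(ecs_width(g1, 0.5), 0.2)
  # radii {0.1, 0.2} um at alpha = 0.3: V/S = 0.025/0.3, d = 35.7 nm
  g2 <- geometry(data.frame(x = c(0.5, 1.5), y = c(0.5, 0.5), r = c(0.1, 0.2)),
                 c(2, 1), check = FALSE)
  expect_equal(ecs_width(g2, 0.3), (0.025 / 0.3) * (0.3 / 0.7),
               tolerance = 1e-12)
  expect_equal(ecs_width(g2, 0.3) * 1e3, 35.7, tolerance = 1e-3)
  expect_error(ecs_width(g2, 1.2), "alpha")
  expect_error(ecs_width(g2, 0), "alpha")
})

test_that("fixture ADD calibration round-trips and spans the target widths", {
  add <- fixture_add()
  cal <- attr(add, "calibration")
  # round trip: requested width recovered at the calibration alpha
  expect_equal(ecs_width(add, cal$alpha_max) * 1e3, cal$width_target_nm,
               tolerance = 0.05)
  w <- ecs_width(add, seq(0.18, 0.30, by = 0.01)) * 1e3
  expect_true(all(diff(w) > 0))
  # quasi-linear growth of width with ECS fraction over the span
  fit <- lm(w ~ seq(0.18, 0.30, by = 0.01))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("degenerate CV = 0 calibration gives the monodisperse diameter", {
  add <- calibrated_add(width_at_alpha_max = 35, alpha_max = 0.3, cv = 0)
  vs <- 35e-3 * 0.7 / 0.3
  expect_equal(add_moments(add)$m1, 4 * vs, tolerance = 1e-9)
})
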