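test_that("empty channel recovers plane Poiseuille flow", {
  sol <- empty_channel_solution()
  expect_lt(sol$stats$mass_balance_err, 1e-3)
  expect_lt(sol$stats$div_residual, 1e-8)
  uc <- cell_velocity(sol)
  prof <- uc[round(sol$nx / 2), ]
  # centreline velocity = 1.5 x mean; parabolic shape
  expect_equal(max(prof) / mean(prof), 1.5, tolerance = 0.01)
  yy <- ((seq_len(sol$ny) - 0.5) / sol$ny)
  expect_equal(prof / mean(prof), 6 * yy * (1 - yy), tolerance = 0.01)
  # pressure gradient = -12 mu U / h^2
  pbar <- apply(sol$p, 1, mean, na.rm = TRUE)
  xs <- (seq_len(sol$nx) - 0.5) * sol$h * 1e-6
  mid <- seq(round(sol$nx * 0.2), round(sol$nx * 0.8))
  slope <- coef(lm(pbar[mid] ~ xs[mid]))[2]
  H <- 10e-6
  expect_equal(as.numeric(slope), -12 * 1e-3 * 0.0024 / H^2, tolerance = 0.01)
})

test_that("Stokes linearity: fields scale with the inlet velocity", {
  g <- geometry(data.frame(x = 5, y = 5, r = 2), c(10, 10), check = FALSE)
  dom <- build_flow_domain(g, entrance_length = 5, exit_length = 5)
  s1 <- solve_creeping_flow(dom, flow_bc(inlet_velocity = 0.0012),
                            resolution = 0.2)
  s2 <- solve_creeping_flow(dom, flow_bc(inlet_velocity = 0.0024),
                            resolution = 0.2)
  dp1 <- max(s1$p, na.rm = TRUE) - min(s1$p, na.rm = TRUE)
  dp2 <- max(s2$p, na.rm = TRUE) - min(s2$p, na.rm = TRUE)
  expect_equal(dp2 / dp1, 2, tolerance = 0.005)
  expect_equal(s2$u[s2$nx, ] / s1$u[s1$nx, ], rep(2, s1$ny), tolerance = 1e-6)
})

test_that("mass is conserved through every cross-section", {
  gs <- small_shrunk()
  dom <- build_flow_domain(gs, entrance_length = 1, exit_length = 1)
  sol <- solve_creeping_flow(dom, flow_bc(), resolution = 0.015)
  expect_lt(sol$stats$mass_balance_err, 1e-3)
})

test_that("the creeping-flow Reynolds bound is enforced", {
  g <- geometry(data.frame(x = 5, y = 5, r = 2), c(10, 10), check = FALSE)
  dom <- build_flow_domain(g)
  expect_error(solve_creeping_flow(dom, flow_bc(inlet_velocity = 10),
                                   resolution = 0.25), "Re")
})

test_that("grid refinement converges monotonically on a single-disc channel", {
  g <- geometry(data.frame(x = 5, y = 5, r = 2), c(10, 10), check = FALSE)
  dom <- build_flow_domain(g, entrance_length = 5, exit_length = 5)
  gs <- grid_sensitivity(dom, flow_bc(), levels = c(0.5, 0.25, 0.125, 0.0625))
  pct <- gs$pct_change[1:3]
  expect_true(all(diff(pct) < 0))
  expect_lt(pct[3], 1)
  # empty channel: all levels agree with the closed form
  g0 <- geometry(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
                 c(10, 10), check = FALSE)
  dom0 <- build_flow_domain(g0, entrance_length = 5, exit_length = 5)
  gs0 <- grid_sensitivity(dom0, flow_bc(), levels = c(0.5, 0.25, 0.125))
  # line averages equal the superficial mean = inlet velocity
  expect_equal(unlist(gs0[, c("line1", "line2", "line3")]),
               rep(0.0024, 9), tolerance = 0.001, ignore_attr = TRUE)
  expect_error(grid_sensitivity(dom0, flow_bc(), levels = c(0.5, 0.25)),
               "3 strictly")
})

test_that("channelling profile is parabolic for an empty channel and
           mirror-symmetric for a symmetric geometry", {
  sol <- empty_channel_solution()
  pr <- channelling_profile(sol, smooth = 0)
  expect_equal(which.max(pr$u), round(sol$ny / 2), tolerance = 1)
  cb <- channelling_bounds(sol, smooth = 0)
  expect_equal(cb$lower, 0)
  expect_equal(cb$upper, sol$domain$height)
  # mirror-symmetric two-disc geometry: symmetric profile
  g <- geometry(data.frame(x = c(5, 5), y = c(3, 7), r = 1.2), c(10, 10),
                check = FALSE)
  dom <- build_flow_domain(g, entrance_length = 5, exit_length = 5)
  s <- solve_creeping_flow(dom, flow_bc(), resolution = 0.1)
  pr2 <- channelling_profile(s, smooth = 0)
  expect_equal(pr2$u, rev(pr2$u), tolerance = 0.02 * max(pr2$u))
})

test_that("build_flow_domain tags and checks the geometry", {
  g <- geometry(data.frame(x = c(1, 1.9), y = c(1, 1), r = c(0.4, 0.4)),
                c(3, 2), check = FALSE)
  expect_error(build_flow_domain(g, gap_tol = 0.2), "gap")
  dom <- build_flow_domain(g, entrance_length = 2, exit_length = 1)
  expect_equal(dom$total_length, 6)
  expect_equal(dom$height, 2)
})
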