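test_that("empty-channel window permeability equals h^2/12", {
  sol <- empty_channel_solution()
  H <- 10e-6
  wp <- window_permeability(sol, 10)
  expect_equal(wp$k, H^2 / 12, tolerance = 0.01)
  # doubling the inlet velocity leaves k unchanged (Stokes regime)
  g <- geometry(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
                c(10, 10), check = FALSE)
  dom <- build_flow_domain(g, entrance_length = 10, exit_length = 10)
  s2 <- solve_creeping_flow(dom, flow_bc(inlet_velocity = 0.0048),
                            resolution = 0.25)
  expect_equal(window_permeability(s2, 10)$k, wp$k,
               tolerance = 0.005)
})

test_that("square-array permeability matches the Gebart closed form", {
  ga <- ordered_array_geometry("square", radius = 1, porosity = 0.45,
                               n_cells = 8)
  dom <- build_flow_domain(ga, entrance_length = 4, exit_length = 4)
  sol <- solve_creeping_flow(dom, flow_bc(), resolution = 0.035)
  a <- ga$domain[1] / 8
  wp <- window_permeability(sol, 4 * a)
  kg <- gebart_permeability(1e-6, 0.45, "square")
  expect_lt(abs(wp$k - kg) / kg, 0.15)
})

test_that("replicate statistics follow the mean / sample-sd definitions", {
  st <- permeability_stats(c(1, 3))
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2))
  expect_equal(permeability_stats(c(5, 5, 5))$sd, 0)
  # identical replicates give zero spread at every size
  expect_equal(permeability_stats(rep(2.5e-16, 6))$sd, 0)
})

test_that("RVE selection picks the first size passing both criteria", {
  sw <- structure(list(
    sizes = 1:8, k_mean = c(1.5, 1.2, 1.06, 1.01, 1.0, 1.0, 1.0, 1.0),
    k_sd = c(0.5, 0.2, 0.08, 0.04, 0.03, 0.02, 0.02, 0.02),
    n = 6, k_matrix = NULL, bounds = NULL, n_divisions = 20, n_used = 16,
    height = 10), class = "rve_sweep")
  sel <- select_rve(sw, plateau_tol = 0.05, cv_tol = 0.05)
  expect_true(sel$found)
  expect_equal(sel$rve_um, 4)   # first size with plateau AND cv <= 0.05
  # a sweep that never settles reports an explicit no-RVE result
  sw$k_sd <- rep(0.5, 8)
  sel2 <- select_rve(sw)
  expect_false(sel2$found)
  expect_error(select_rve(structure(list(sizes = 1:3, k_mean = rep(1, 3),
                                         k_sd = rep(0, 3)),
                                    class = "rve_sweep")), "5 usable")
})

test_that("window permeability rejects degenerate windows", {
  sol <- empty_channel_solution()
  expect_error(window_permeability(sol, 0.01), "too small")
  g <- geometry(data.frame(x = 5, y = 5, r = 1.8), c(10, 10), check = FALSE)
  dom <- build_flow_domain(g, entrance_length = 3, exit_length = 3)
  s <- solve_creeping_flow(dom, flow_bc(), resolution = 0.1)
  expect_error(window_permeability(s, 2), "no fluid")
})

test_that("full-region equivalence: window k matches end-to-end Darcy k", {
  gs <- small_shrunk()
  dom <- build_flow_domain(gs, entrance_length = 1, exit_length = 1)
  sol <- solve_creeping_flow(dom, flow_bc(), resolution = 0.015)
  H <- gs$domain[2]
  wp <- window_permeability(sol, H * 0.98)
  # independent route: total flux through the porous zone and the pressure
  # drop across it
  cols <- which((seq_len(sol$nx) - 0.5) * sol$h >= dom$entrance &
                (seq_len(sol$nx) - 0.5) * sol$h <= dom$entrance +
                  dom$porous_length)
  v_sup <- sol$bc$inlet_velocity      # by mass conservation
  pbar <- apply(sol$p, 1, mean, na.rm = TRUE)
  dp <- pbar[cols[1]] - pbar[cols[length(cols)]]
  L <- (cols[length(cols)] - cols[1]) * sol$h_m
  k2 <- sol$bc$viscosity * v_sup / (dp / L)
  expect_equal(wp$k, k2, tolerance = 0.25)
})

test_that("k is invariant to the inlet velocity on a porous geometry", {
  gs <- small_shrunk()
  dom <- build_flow_domain(gs, entrance_length = 1, exit_length = 1)
  s1 <- solve_creeping_flow(dom, flow_bc(inlet_velocity = 0.0024),
                            resolution = 0.02)
  s2 <- solve_creeping_flow(dom, flow_bc(inlet_velocity = 0.0012),
                            resolution = 0.02)
  k1 <- window_permeability(s1, gs$domain[2] / 2)$k
  k2 <- window_permeability(s2, gs$domain[2] / 2)$k
  expect_equal(k1, k2, tolerance = 0.005)
})
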