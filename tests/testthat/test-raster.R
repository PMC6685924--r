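test_that("rasterisation reproduces vector areas", {
  # empty geometry: all ECS
  g0 <- geometry(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
                 c(1, 1), check = FALSE)
  m0 <- rasterize_ecs(g0, 0.01)
  expect_true(all(m0$mask))
  # one centred disc: raster area within 1% of pi r^2
  g1 <- geometry(data.frame(x = 1, y = 1, r = 0.5), c(2, 2), check = FALSE)
  m1 <- rasterize_ecs(g1, 0.01)
  raster_area <- sum(!m1$mask) * m1$resolution^2
  expect_equal(raster_area, pi * 0.25, tolerance = 0.01)
  expect_error(rasterize_ecs(g1, 0.2), "resolution")
})

test_that("raster ECS fraction agrees with the exact vector alpha", {
  g <- small_pack()
  m <- rasterize_ecs(g, min(g$discs$r) / 10)
  expect_lt(abs(mean(m$mask) - g$alpha), 0.01)
})

test_that("three tangent discs yield a branch point near the pore centre", {
  r <- 1
  c3 <- tangent_disc_centers(c(2, 2), r, c(4, 2), r, r)
  top <- c3[which.max(c3[, 2]), ]
  g <- geometry(data.frame(x = c(2, 4, top[1]), y = c(2, 2, top[2]), r = r),
                c(6, 6), check = FALSE)
  bp <- skeleton_branch_points(rasterize_ecs(g, 0.05))
  expect_gt(nrow(bp), 0)
  pore <- c(3, 2 + sqrt(3) / 3)      # incentre of the tangency triangle
  d <- sqrt((bp[, 1] - pore[1])^2 + (bp[, 2] - pore[2])^2)
  expect_lt(min(d), 0.35)
})

test_that("a straight channel has no branch points", {
  # two half-plane-like obstacles leaving a straight corridor: emulate with
  # two big discs above and below
  g <- geometry(data.frame(x = c(5, 5), y = c(-97, 107), r = 100),
                c(10, 10), check = FALSE)
  bp <- skeleton_branch_points(rasterize_ecs(g, 0.1))
  expect_equal(nrow(bp), 0)
})

test_that("a 2x2 disc lattice with gaps branches near the cell centre", {
  a <- 2.6
  g <- ordered_array_geometry("square", radius = 1, porosity = 1 - pi / a^2,
                              n_cells = 2)
  bp <- skeleton_branch_points(rasterize_ecs(g, 0.05))
  expect_gt(nrow(bp), 0)
  centre <- g$domain / 2
  d <- sqrt((bp[, 1] - centre[1])^2 + (bp[, 2] - centre[2])^2)
  # independent oracle: the distance-transform maximum of the central pore
  # is the cell centre by symmetry
  expect_lt(min(d), 0.3)
})

test_that("a fully solid mask yields no branch points", {
  m <- structure(list(mask = matrix(FALSE, 20, 20), resolution = 0.1,
                      origin = c(0, 0), domain = c(2, 2)),
                 class = "binary_mask")
  expect_equal(nrow(skeleton_branch_points(m)), 0)
})
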