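test_that("tangent centres solve the two-circle intersection", {
  # equilateral triplet
  cc <- tangent_disc_centers(c(0, 0), 1, c(2, 0), 1, 1)
  expect_equal(nrow(cc), 2)
  expect_equal(sort(cc[, 2]), c(-sqrt(3), sqrt(3)), tolerance = 1e-12)
  expect_equal(cc[, 1], c(1, 1), ignore_attr = TRUE)
  # too far apart for the new radius
  expect_equal(nrow(tangent_disc_centers(c(0, 0), 1, c(10, 0), 1, 1)), 0)
  # unequal radii: at this spacing the construction circles (radii
  # r1 + r3 = 2.5 and r2 + r3 = 1.5 about centres 4 apart) touch
  # externally, so the tangency point is unique; both distance equations
  # hold there
  cc2 <- tangent_disc_centers(c(0, 0), 2, c(4, 0), 1, 0.5)
  expect_equal(nrow(cc2), 1)
  expect_equal(sqrt(sum(cc2[1, ]^2)), 2.5, tolerance = 1e-9)
  expect_equal(sqrt(sum((cc2[1, ] - c(4, 0))^2)), 1.5, tolerance = 1e-9)
  # a genuinely two-solution unequal-radii case
  cc3 <- tangent_disc_centers(c(0, 0), 2, c(3.5, 0), 1, 0.5)
  expect_equal(nrow(cc3), 2)
  for (i in 1:2) {
    expect_equal(sqrt(sum(cc3[i, ]^2)), 2.5, tolerance = 1e-9)
    expect_equal(sqrt(sum((cc3[i, ] - c(3.5, 0))^2)), 1.5, tolerance = 1e-9)
  }
  expect_error(tangent_disc_centers(c(0, 0), 1, c(0, 0), 1, 1), "coincident")
})

test_that("geometry invariants are enforced and alpha is exact", {
  expect_error(
    geometry(data.frame(x = c(0.5, 1.0), y = c(0.5, 0.5), r = c(0.4, 0.4)),
             c(2, 1)), "overlap")
  expect_error(
    geometry(data.frame(x = 0.1, y = 0.5, r = 0.4), c(2, 1)), "boundary")
  g <- geometry(data.frame(x = 1, y = 1, r = 0.5), c(2, 2), check = TRUE)
  expect_equal(g$alpha, 1 - pi * 0.25 / 4)
  # empty geometry: alpha = 1
  g0 <- geometry(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
                 c(1, 1), check = FALSE)
  expect_equal(ecs_volume_fraction(g0), 1.0)
  # one disc covering half the domain
  r <- sqrt(2 / pi)
  gh <- geometry(data.frame(x = 2, y = 2, r = r), c(4, 1), check = FALSE)
  expect_equal(ecs_volume_fraction(gh), 0.5, tolerance = 1e-12)
})

test_that("shrinking is exact, centre-preserving and refuses to densify", {
  g <- small_pack()
  expect_error(shrink_to_porosity(g, g$alpha - 0.05), "densify")
  # identity at the current alpha
  gid <- shrink_to_porosity(g, g$alpha)
  expect_equal(attr(gid, "shrink_factor"), 1, tolerance = 1e-12)
  # closed-form factor for 0.18 -> 0.30: ~7.6% diameter decrease
  s <- sqrt((1 - 0.30) / (1 - 0.18))
  expect_equal(s, 0.9239, tolerance = 1e-4)
  gs <- shrink_to_porosity(g, 0.40)
  expect_equal(gs$alpha, 0.40, tolerance = 1e-6)
  expect_equal(gs$discs$x, g$discs$x)
  expect_equal(attr(gs, "shrink_factor"),
               sqrt((1 - 0.40) / (1 - g$alpha)), tolerance = 1e-12)
  expect_identical(gs$provenance, "shrunk")
  validate_geometry(gs)
})

test_that("realised diameters match the target ADD before filling", {
  g <- small_pack()
  rep <- compare_add(g, fixture_add())
  expect_lt(abs(rep$mean_rel_change), 0.05)
  expect_lt(rep$ks_distance, 0.1)
})

test_that("shrinking preserves the diameter-distribution shape", {
  g <- small_pack()
  gs <- shrink_to_porosity(g, 0.40)
  s <- attr(gs, "shrink_factor")
  expect_equal(gs$discs$r, g$discs$r * s)
  rep0 <- compare_add(g, fixture_add())
  reps <- compare_add(gs, fixture_add())
  expect_equal(reps$mean_realised / rep0$mean_realised, s, tolerance = 1e-9)
})
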