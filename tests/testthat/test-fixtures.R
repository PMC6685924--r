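test_that("square-array pitch solves the porosity relation", {
  g <- ordered_array_geometry("square", radius = 1, porosity = 0.5,
                              n_cells = 3)
  a <- g$domain[1] / 3
  expect_equal(a, sqrt(pi / 0.5), tolerance = 1e-12)
  expect_equal(a, 2.5066, tolerance = 1e-4)
  expect_equal(g$alpha, 0.5, tolerance = 1e-12)
  validate_geometry(g)
  expect_error(ordered_array_geometry("square", porosity = 0.20),
               "packing limit")
})

test_that("hexagonal arrays respect their close-packing limit", {
  expect_error(ordered_array_geometry("hexagonal", porosity = 0.05),
               "packing limit")
  g <- ordered_array_geometry("hexagonal", radius = 1, porosity = 0.5,
                              n_cells = 4)
  validate_geometry(g)
  # natural-domain porosity is close to the request (finite-size effects)
  expect_equal(g$alpha, 0.5, tolerance = 0.15)
})

test_that("reference patterns land in their spatial classes", {
  expect_identical(
    csr_classify(reference_patterns("poisson", 800, seed = 3))$classification,
    "CSR")
  expect_lt(csr_classify(reference_patterns("lattice", 49, seed = 3))$slope, 1)
  expect_gt(csr_classify(reference_patterns("clustered", 400, seed = 3))$slope, 1)
  expect_identical(nrow(reference_patterns("poisson", 77, seed = 1)$points), 77L)
  expect_error(reference_patterns("poisson", 1), "n must be")
})

test_that("Gebart formula reproduces its defining algebra", {
  # square array: C (sqrt(phimax/phi) - 1)^{5/2} r^2
  k <- gebart_permeability(2, 0.5, "square")
  C <- 16 / (9 * pi * sqrt(2))
  expect_equal(k, C * (sqrt(pi / 4 / 0.5) - 1)^2.5 * 4, tolerance = 1e-12)
  expect_error(gebart_permeability(1, 0.1, "square"), "phi_max")
})

test_that("fixture ADD reproducibility under a fixed seed", {
  a1 <- calibrated_add()
  a2 <- calibrated_add()
  expect_equal(a1$meanlog, a2$meanlog, tolerance = 1e-12)
  p1 <- reference_patterns("clustered", 100, seed = 9)
  p2 <- reference_patterns("clustered", 100, seed = 9)
  expect_identical(p1$points, p2$points)
})
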