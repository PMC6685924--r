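test_that("R estimator matches hand evaluation for two points", {
  # two points distance 0.3 apart in the unit square, correction off, any
  # t above that distance: R = lambda^-1 * sum w^-1 I / N = (1/2)(2/2) = 0.5
  pp <- point_pattern(rbind(c(0.35, 0.5), c(0.65, 0.5)), c(1, 1))
  res <- ripley_R(pp, t_values = 0.45, edge_correction = FALSE)
  expect_equal(res$R, 0.5)
  # below the inter-point distance the count is empty
  res0 <- ripley_R(pp, t_values = 0.2, edge_correction = FALSE)
  expect_equal(res0$R, 0)
})

test_that("L linearisation is sqrt(R/pi) pointwise", {
  res <- structure(list(t = c(1, 2, 3), R = c(pi, pi * 4, 0.5),
                        window = c(10, 10), n = 10, edge_correction = TRUE,
                        normalised = FALSE, t_ref = 2.5),
                   class = "ripley_result")
  out <- l_function(res)
  expect_equal(out$L, c(1, 2, sqrt(0.5 / pi)))
  expect_equal(out$L[3], 0.3989, tolerance = 1e-3)
})

test_that("Poisson patterns recover R = pi t^2 and unit slope", {
  tv <- seq(0.02, 0.24, by = 0.02)
  nrep <- 40
  Rbar <- rowMeans(vapply(seq_len(nrep), function(s) {
    pp <- reference_patterns("poisson", 400, seed = 100 + s)
    ripley_R(pp, tv)$R
  }, numeric(length(tv))))
  expect_equal(Rbar, pi * tv^2, tolerance = 0.05)
  slopes <- vapply(seq_len(nrep), function(s)
    csr_classify(reference_patterns("poisson", 400, seed = 100 + s))$slope,
    numeric(1))
  expect_equal(mean(slopes), 1, tolerance = 0.03)
})

test_that("edge correction removes the downward boundary bias", {
  tv <- seq(0.05, 0.24, by = 0.05)
  bias <- function(corr) {
    Rbar <- rowMeans(vapply(1:30, function(s) {
      pp <- reference_patterns("poisson", 300, seed = 500 + s)
      ripley_R(pp, tv, edge_correction = corr)$R
    }, numeric(length(tv))))
    abs(Rbar - pi * tv^2)[length(tv)]
  }
  expect_lt(bias(TRUE), bias(FALSE))
})

test_that("estimator agrees with Ripley's own implementation", {
  skip_if_not_installed("spatial")
  pp <- reference_patterns("poisson", 300, seed = 11)
  spatial::ppregion(0, 1, 0, 1)
  ours <- ripley_R(pp, seq(0.01, 0.24, by = 0.01))
  theirs <- spatial::Kfn(list(x = pp$points[, 1], y = pp$points[, 2]),
                         fs = 0.24, k = 24)
  expect_equal(ours$L, theirs$y, tolerance = 0.02)
})

test_that("classification separates CSR, inhibition and clustering", {
  expect_identical(
    csr_classify(reference_patterns("poisson", 1000, seed = 2))$classification,
    "CSR")
  # coarse lattice (spacing comparable to the fitted range) shows the
  # inhibition signature clearly
  lat <- csr_classify(reference_patterns("lattice", 49, seed = 1))
  expect_lt(lat$slope, 1)
  expect_identical(lat$classification, "inhibited")
  # two tight clusters of 50 points each
  set.seed(4)
  pts <- rbind(cbind(0.3 + rnorm(50, sd = 0.01), 0.3 + rnorm(50, sd = 0.01)),
               cbind(0.7 + rnorm(50, sd = 0.01), 0.7 + rnorm(50, sd = 0.01)))
  clu <- csr_classify(point_pattern(pts, c(1, 1)))
  expect_gt(clu$slope, 1)
  expect_identical(clu$classification, "clustered")
})

test_that("packed disc centres behave as CSR at large distances", {
  g <- small_pack()
  pp <- point_pattern(as.matrix(g$discs[, c("x", "y")]), g$domain)
  cls <- csr_classify(pp)
  expect_lt(abs(cls$slope - 1), 0.1)
})

test_that("preconditions are enforced", {
  pp <- reference_patterns("poisson", 50, seed = 1)
  expect_error(ripley_R(pp, t_values = 0.6), "half the shorter")
  expect_error(csr_classify(pp, t_max = 0.3), "25%")
  expect_error(point_pattern(rbind(c(0.5, 0.5)), c(1, 1)), "at least 2")
  expect_error(point_pattern(rbind(c(2, 0.5), c(0.5, 0.5)), c(1, 1)),
               "outside")
})
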