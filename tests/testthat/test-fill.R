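test_that("fill_voids is a no-op at the current ECS fraction and rejects
           targets above it", {
  g <- small_pack()
  expect_identical(fill_voids(g, fixture_add(), alpha_stop = g$alpha), g)
  expect_error(fill_voids(g, fixture_add(), alpha_stop = g$alpha + 0.05),
               "exceeds")
  expect_error(fill_voids(g, fixture_add(), alpha_stop = -0.1), "positive")
})

test_that("filling densifies monotonically and preserves the invariants", {
  g <- small_pack()
  gf <- fill_voids(g, fixture_add(), alpha_stop = 0.15, seed = 1)
  expect_identical(gf$provenance, "filled")
  expect_lt(gf$alpha, g$alpha)
  expect_gt(attr(gf, "n_inserted"), 0)
  validate_geometry(gf)
  expect_gte(min_surface_gap(gf), gf$gap_tol * (1 - 1e-6))
  # original discs are untouched
  expect_equal(gf$discs[seq_len(nrow(g$discs)), ], g$discs,
               ignore_attr = TRUE)
  # every inserted diameter lies within the ADD bounds
  new_d <- 2 * gf$discs$r[-seq_len(nrow(g$discs))]
  expect_true(all(new_d >= fixture_add()$d_min - 1e-12 &
                  new_d <= fixture_add()$d_max + 1e-12))
})

test_that("the attainable floor sits near the physiological minimum", {
  g <- small_pack()
  gf <- fill_voids(g, fixture_add(), alpha_stop = 0.15, seed = 1)
  # the floor is above the requested stop but well below the packed level
  expect_gt(gf$alpha, 0.14)
  expect_lt(gf$alpha, 0.20)
  # filling enriches small diameters relative to the target ADD
  rep_fill <- compare_add(gf, fixture_add())
  expect_lt(rep_fill$mean_rel_change, 0)
})

test_that("fill then shrink keeps the diameter distortion below 10%", {
  g <- small_pack()
  gf <- fill_voids(g, fixture_add(), alpha_stop = 0.15, seed = 1)
  gs <- shrink_to_porosity(gf, 0.30)
  s <- attr(gs, "shrink_factor")
  expect_gt(s, 0.90)
  expect_lt(1 - s, 0.10)
})
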