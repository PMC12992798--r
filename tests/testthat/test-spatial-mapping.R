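# Spatial mapping: line-ellipsoid spans, depth alignment, structure
# classification, site localization, sweetspot distances.

vertical_geom <- function(target = c(0, 0, 0), offset = 0) {
  trajectory_geometry(target, c(0, 0, -1), implantation_offset = offset)
}

test_that("stn_span solves the line-ellipsoid chord", {
  atlas <- atlas_geometry(stn_center = c(0, 0, 2.25), stn_axes = c(4, 3, 2.25))
  span <- stn_span(vertical_geom(), atlas)
  expect_equal(unname(span), c(4.5, 0.0))

  # miss: line far outside the ellipsoid
  expect_null(stn_span(vertical_geom(target = c(50, 0, 0)), atlas))
  # tangent: grazing line counts as no intersection
  expect_null(stn_span(vertical_geom(target = c(4, 0, 0)), atlas))
})

test_that("stn_span respects an ellipsoid rotation", {
  # 90-degree rotation about z swaps the x/y semi-axes
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  atlas <- atlas_geometry(stn_center = c(0, 0, 0), stn_axes = c(4, 3, 2),
                          stn_rotation = R)
  # along x at y=0: effective semi-axis is now 3 (the rotated y-axis)
  g <- trajectory_geometry(c(-5, 0, 0), c(-1, 0, 0))
  span <- stn_span(g, atlas)
  expect_equal(unname(span[1] - span[2]), 6, tolerance = 1e-8)
})

test_that("align_depths shifts midpoints to the mean-length reference", {
  al <- align_depths(list(c(6, 2), c(5, 1)))
  expect_equal(al$reference_midpoint, 2.0)
  expect_equal(al$shifts, c(-2.0, -1.0))

  single <- align_depths(list(c(5, 1)))
  expect_equal(single$shifts, -1.0)
  expect_equal(unname(single$spans[[1]]), c(4, 0))

  # cohort whose midpoints already equal the reference: fixed point
  centred <- align_depths(list(c(4.5, 0.5), c(5.5, -0.5)))
  expect_equal(centred$shifts, c(0, 0))
  expect_error(align_depths(list()), class = "mertopo_insufficient_data")
})

test_that("alignment conserves span lengths and equalizes midpoints", {
  set.seed(21)
  spans <- replicate(30, {
    mid <- runif(1, 0, 4); len <- runif(1, 3, 6)
    c(mid + len / 2, mid - len / 2)
  }, simplify = FALSE)
  al <- align_depths(spans)
  lens_before <- vapply(spans, function(s) s[1] - s[2], numeric(1))
  lens_after <- vapply(al$spans, function(s) s[1] - s[2], numeric(1))
  expect_equal(lens_after, lens_before)
  mids <- vapply(al$spans, function(s) (s[1] + s[2]) / 2, numeric(1))
  expect_equal(mids, rep(al$reference_midpoint, 30))
})

test_that("trajectory exclusion drops missed and short traversals", {
  ex <- exclude_trajectories(list(NULL, c(4, 1.5), c(5, 1), c(3, 0)))
  expect_equal(ex$keep, c(FALSE, FALSE, TRUE, TRUE))  # 3.0 mm is kept
  expect_equal(ex$excluded, c(no_stn = 1L, short_span = 1L))
})

test_that("structure classification gives STN precedence in overlaps", {
  atlas <- atlas_geometry()
  expect_equal(classify_structure(atlas$stn$center, atlas), "STN")
  expect_equal(classify_structure(c(100, 0, 0), atlas), "other")
  overlap <- atlas_geometry(stn_center = c(0, 0, 0), stn_axes = c(3, 3, 3),
                            snr_center = c(1, 0, 0), snr_axes = c(3, 3, 3))
  expect_equal(classify_structure(c(1, 0, 0), overlap), "STN")
})

test_that("MER site localization applies the implantation offset", {
  g <- vertical_geom()
  expect_equal(locate_mer_site(g, 0), c(0, 0, 0))
  expect_equal(locate_mer_site(g, 5), c(0, 0, 5))
  g_deep <- vertical_geom(offset = -1)  # implanted 1 mm deeper than planned
  expect_equal(locate_mer_site(g_deep, 5), c(0, 0, 4))
})

test_that("sweetspot distance is a Euclidean metric", {
  expect_equal(sweetspot_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(sweetspot_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(1, -2, 0.5); b <- c(-3, 1, 2); cc <- c(0, 0, 0)
  expect_equal(sweetspot_distance(a, b), sweetspot_distance(b, a))
  expect_lte(sweetspot_distance(a, b),
             sweetspot_distance(a, cc) + sweetspot_distance(cc, b))
})

test_that("electrode center is the contact midpoint with signed z deviation", {
  contacts <- cbind(0, 0, c(-2, 0, 2, 4))
  ec <- electrode_center(contacts, sweetspot = c(0, 0, 1))
  expect_equal(ec$center, c(0, 0, 1))
  expect_equal(ec$z_deviation, 0)
  ec2 <- electrode_center(c(2, 1, -3), sweetspot = c(2, 1, -1.5))
  expect_equal(ec2$center, c(2, 1, -3))    # single contact
  expect_equal(ec2$z_deviation, -1.5)
})

test_that("first-SUA normalized distance applies the neighbor rule", {
  span <- c(5, 1)
  expect_equal(as.numeric(first_sua_normalized_distance(span, c(4.2, 3.8, 3.0, 2.5))),
               0.2)
  expect_equal(as.numeric(first_sua_normalized_distance(span, c(5, 4.5, 3.5))), 0)
  # an isolated dorsal unit with no neighbors within 2 mm is skipped
  frac <- first_sua_normalized_distance(span, c(4.8, 2.0, 1.8, 1.5))
  expect_equal(as.numeric(frac), (5 - 2.0) / 4)
  expect_true(is.na(first_sua_normalized_distance(span, c(4, 0.5))))
  # ventral of exit: unclipped and flagged
  deep <- first_sua_normalized_distance(span, c(0.5, 0.3, 0.1))
  expect_gt(as.numeric(deep), 1)
  expect_true(attr(deep, "out_of_span"))
})

test_that("cohort structure labels agree with atlas classification at site positions", {
  co <- small_cohort()
  s <- co$segments
  agree <- vapply(seq_len(nrow(s)), function(j) {
    classify_structure(c(s$x[j], s$y[j], s$z[j]), co$atlas) ==
      s$structure_imaging[j]
  }, logical(1))
  expect_gte(mean(agree), 0.99)
  expect_true(all(s$structure_imaging != "STN" |
                    vapply(seq_len(nrow(s)), function(j) {
                      mertopo:::in_ellipsoid(c(s$x[j], s$y[j], s$z[j]),
                                             co$atlas$stn)
                    }, logical(1))))
})
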