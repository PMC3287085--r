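test_that("default bifurcation outline is closed, simple, with nominal widths", {
  ol <- default_outline()
  expect_s3_class(ol, "lumen_outline")
  expect_named(ol$branches, c("lms", "lad", "lcx"))
  # lumen width at LMS mid-span equals the diameter
  b <- ol$branches$lms
  i <- which.min(abs(b$s - 5))
  expect_equal(b$off_left[i] - b$off_right[i], 4.5)
  # closed polygon, verified simple by the independent brute-force oracle
  poly <- ol$polygon[seq(1, nrow(ol$polygon), by = 6), ]
  expect_true(polygon_is_simple_oracle(poly))
  expect_true(polygon_is_simple_oracle(
    plaqued_outline()$polygon[seq(1, nrow(plaqued_outline()$polygon), by = 6), ]))
})

test_that("degenerate angle/fillet combinations are rejected with a geometric diagnostic", {
  expect_error(build_bifurcation(vessel_spec(bifurcation_angle = 179.9,
                                             fillet_radius = 3)))
  expect_error(vessel_spec(bifurcation_angle = 181), "bifurcation_angle")
  expect_error(vessel_spec(lad_diameter = 5), "daughter")
})

test_that("plaque insertion follows the raised-cosine narrowing law", {
  ol <- default_outline()
  # delta = 0 leaves the outline unchanged
  ol0 <- apply_plaque(ol, plaque_spec("lms", 5, stenosis_fraction = 0))
  expect_identical(ol0$branches$lms$off_left, ol$branches$lms$off_left)
  expect_identical(ol0$branches$lms$off_right, ol$branches$lms$off_right)
  # delta = 0.6 -> throat width 0.4 D; implied circular-tube area loss 84%
  ol6 <- apply_plaque(ol, plaque_spec("lms", 5, stenosis_fraction = 0.6))
  b <- ol6$branches$lms
  wmin <- min(b$off_left - b$off_right)
  expect_equal(wmin, 0.4 * 4.5, tolerance = 1e-9)
  expect_equal(1 - (wmin / 4.5)^2, 0.84, tolerance = 1e-9)
  # locality: offsets outside the plaque extent are bitwise unchanged
  outside <- b$s < 5 - 2 | b$s > 5 + 2
  expect_identical(b$off_left[outside], ol$branches$lms$off_left[outside])
  expect_identical(b$off_right[outside], ol$branches$lms$off_right[outside])
  # eccentric plaque narrows one wall but keeps the same throat width
  ole <- apply_plaque(ol, plaque_spec("lms", 5, stenosis_fraction = 0.3,
                                      eccentric = TRUE))
  be <- ole$branches$lms
  expect_equal(min(be$off_left - be$off_right), 0.7 * 4.5, tolerance = 1e-9)
  expect_identical(be$off_right, ol$branches$lms$off_right)
})

test_that("invalid plaques are rejected", {
  ol <- default_outline()
  expect_error(plaque_spec("lms", 5, stenosis_fraction = 1.2), "stenosis_fraction")
  expect_error(apply_plaque(ol, plaque_spec("lad", 1.0)), "clean wall zone")
  ol1 <- apply_plaque(ol, plaque_spec("lms", 5))
  expect_error(apply_plaque(ol1, plaque_spec("lms", 6.5)), "overlapping")
})

test_that("measured stenosis is linear in the stenosis fraction", {
  ol <- default_outline()
  expect_equal(measure_stenosis(ol, "lms"), 0)
  expect_equal(measure_stenosis(ol, "lad"), 0)
  for (d in c(0.3, 0.5, 0.6)) {
    old <- apply_plaque(ol, plaque_spec("lms", 5, stenosis_fraction = d))
    expect_equal(measure_stenosis(old, "lms"), 100 * d, tolerance = 0.5)
  }
  ol2 <- plaqued_outline()
  expect_equal(measure_stenosis(ol2, "lms"), 60, tolerance = 0.5)
  expect_equal(measure_stenosis(ol2, "lad"), 60, tolerance = 0.5)
  expect_equal(measure_stenosis(ol2, "lcx"), 0)
})

test_that("fifteen section planes in three 0.5 mm groups, all inside the lumen", {
  ol <- plaqued_outline()
  sec <- define_sections(ol)
  expect_equal(nrow(sec), 15)
  expect_equal(sec$label, LETTERS[1:15])
  expect_equal(sec$branch, rep(c("lms", "lad", "lcx"), each = 5))
  for (g in list(1:5, 6:10, 11:15)) {
    expect_equal(diff(sec$s[g]), rep(0.5, 4), tolerance = 1e-9)
  }
  # A-B prestenotic, E at the LMS throat; F at the LAD throat with I-J
  # postplaque; K starts at the proximal LCx ostium
  expect_equal(sec$s[1:5], c(3, 3.5, 4, 4.5, 5))
  expect_equal(sec$s[6], 5.5)
  expect_equal(sec$s[11], 1.0)
  # every plane segment lies inside the lumen polygon (winding oracle),
  # checked at interior points along each segment
  for (i in seq_len(nrow(sec))) {
    for (f in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
      px <- sec$x0[i] + f * (sec$x1[i] - sec$x0[i])
      py <- sec$y0[i] + f * (sec$y1[i] - sec$y0[i])
      expect_true(pip_oracle(ol$polygon, px, py))
    }
  }
  # a group that would leave the branch is rejected
  expect_error(define_sections(ol, plaques = list(plaque_spec("lad", 24.5))),
               "outside the usable branch")
})
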