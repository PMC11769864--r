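test_that("end geometry construction from perpendicular planes", {
  # AP: y = 0, PP: z = 0, VP: x = 0 -> edge along X through the origin
  res <- construct_end_geometry(plane(c(0, 0, 0), c(0, 1, 0)),
                                plane(c(0, 0, 0), c(0, 0, 1)),
                                plane(c(0, 0, 0), c(1, 0, 0)), quadrant = 1)
  expect_equal(res$line$direction, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(res$point, c(0, 0, 0), tolerance = 1e-12)

  expect_error(construct_end_geometry(plane(c(0, 0, 0), c(0, 1, 0)),
                                      plane(c(0, 1, 0), c(0, 1, 0)),
                                      plane(c(0, 0, 0), c(1, 0, 0)),
                                      quadrant = 2),
               "quadrant 2")
})

test_that("end geometry is equivariant under rigid transforms of the planes", {
  ap <- plane(c(5, 0, 3), c(0, 1, 1) / sqrt(2))
  pp <- plane(c(5, 0, 3), c(0, -1, 1) / sqrt(2))
  vp <- plane(c(9, 0, 0), c(1, 0, 0))
  base <- construct_end_geometry(ap, pp, vp, quadrant = 1)
  set.seed(11)
  R <- random_rotation()
  t <- c(4, -2, 1)
  move_plane <- function(p) plane(drop(R %*% p$point) + t, drop(R %*% p$normal))
  moved <- construct_end_geometry(move_plane(ap), move_plane(pp), move_plane(vp),
                                  quadrant = 1)
  expect_equal(moved$point, drop(R %*% base$point) + t, tolerance = 1e-9)
  # directions agree up to the orientation convention's sign
  expect_equal(abs(sum(moved$line$direction * drop(R %*% base$line$direction))),
               1, tolerance = 1e-9)
})

test_that("P2' construction shifts VP2 by the reference length", {
  v2 <- line3(c(-55, 0, 0), c(1, 0, 0))
  vp2 <- plane(c(-55, 0, 0), c(-1, 0, 0))
  p2p <- construct_p2prime(v2, vp2, reference_bar(55.066), c(1, 0, 0))
  expect_equal(p2p, c(0.066, 0, 0), tolerance = 1e-9)

  # zero-length bar degenerates to P2 itself
  expect_equal(construct_p2prime(v2, vp2, reference_bar(1e-9), c(1, 0, 0)),
               c(-55, 0, 0), tolerance = 1e-6)
})

test_that("vector error is the componentwise P1 - P2' in micrometres", {
  z <- vector_error(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$VE, c(0, 0, 0))
  expect_equal(z$VE_norm, 0)

  r <- vector_error(c(0.010, 0, 0), c(0, 0, 0))
  expect_equal(r$VE, c(10, 0, 0))
  expect_equal(r$VE_norm, 10)
})

test_that("length deviation compares the measured span to the certified length", {
  bar <- reference_bar(55.066)
  expect_equal(length_deviation(c(0, 0, 0), c(55.066, 0, 0), bar), 0,
               tolerance = 1e-9)
  expect_equal(length_deviation(c(0, 0, 0), c(-55.000, 0, 0), bar), -66,
               tolerance = 1e-9)
  expect_equal(length_deviation(c(0, 0, 0), c(-55.166, 0, 0), bar), 100,
               tolerance = 1e-9)
})

test_that("angular deviations evaluate the projection formulas", {
  expect_equal(angle_overall(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_overall(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_overall(c(1, 0, 0), c(1, 1, 0)), 45, tolerance = 1e-12)

  expect_equal(angle_coronal(c(1, 0, 0), c(1, 0, 5) / sqrt(26)), 0)
  expect_equal(angle_coronal(c(1, 0, 0), c(1, 1, 0)), 45, tolerance = 1e-12)
  expect_equal(angle_coronal(c(2, 1, 0), c(2, -1, 0)),
               acos(3 / 5) * 180 / pi, tolerance = 1e-12)

  expect_equal(angle_axial(c(1, 0, 0), c(0, 0, 1)), 90)
  expect_equal(angle_axial(c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(angle_axial(c(1, 0, 1), c(1, 0, 0)), 45, tolerance = 1e-12)

  expect_error(angle_coronal(c(0, 0, 1), c(1, 0, 0)), "undefined projection")
  expect_error(angle_axial(c(0, 1, 0), c(1, 0, 0)), "undefined projection")
})

test_that("angles are symmetric and decompose consistently", {
  set.seed(19)
  for (i in 1:200) {
    v1 <- rnorm(3L); v2 <- rnorm(3L)
    v1[1] <- abs(v1[1]) + 0.1; v2[1] <- abs(v2[1]) + 0.1
    expect_equal(angle_overall(v1, v2), angle_overall(v2, v1), tolerance = 1e-10)
    expect_equal(angle_coronal(v1, v2), angle_coronal(v2, v1), tolerance = 1e-10)
    expect_equal(angle_axial(v1, v2), angle_axial(v2, v1), tolerance = 1e-10)

    flat <- c(v1[1], v1[2], 0); flat2 <- c(v2[1], v2[2], 0)
    expect_equal(angle_overall(flat, flat2), angle_coronal(flat, flat2),
                 tolerance = 1e-9)
    expect_equal(angle_axial(flat, flat2), 0, tolerance = 1e-9)

    up <- c(v1[1], 0, v1[3]); up2 <- c(v2[1], 0, v2[3])
    expect_equal(angle_overall(up, up2), angle_axial(up, up2), tolerance = 1e-9)
    expect_equal(angle_coronal(up, up2), 0, tolerance = 1e-9)
  }
})

test_that("an undistorted synthetic scan measures exactly zero deviation", {
  model <- the_model(coarse = TRUE)
  cfg <- scan_config(model$regions, reference_bar(), scan_id = "null")
  meas <- analyze_scan(model$mesh, cfg)
  expect_lt(max(abs(meas$VE)), 1e-3)
  expect_lt(abs(meas$deltaL), 1e-3)
  expect_lt(meas$alpha_overall, 1e-5)
  expect_lt(meas$alpha_coronal, 1e-5)
  expect_lt(meas$alpha_axial, 1e-5)
  expect_equal(meas$VE_norm, sqrt(sum(meas$VE^2)), tolerance = 1e-6)
})

test_that("injected end-2 rigid transforms propagate to the measurement", {
  model <- the_model(coarse = TRUE)
  cfg <- scan_config(model$regions, reference_bar(), scan_id = "d")

  tr <- distortion_params(translation_um = c(50, -30, 120))
  m1 <- analyze_scan(apply_distortion(model$mesh, model$end2_region, tr), cfg)
  expect_equal(m1$VE, c(-50, 30, -120), tolerance = 1e-6)

  rot <- distortion_params(rotation_deg = c(0, 0, 0.30))
  m2 <- analyze_scan(apply_distortion(model$mesh, model$end2_region, rot), cfg)
  expect_equal(m2$alpha_overall, 0.30, tolerance = 0.02)
  expect_equal(m2$alpha_coronal, 0.30, tolerance = 0.02)
  expect_lt(m2$alpha_axial, 0.02)
})

test_that("one global rigid transform leaves all measurands unchanged", {
  model <- the_model(coarse = TRUE)
  d <- distortion_params(translation_um = c(40, -25, 60),
                         rotation_deg = c(0.1, -0.2, 0.25))
  mesh <- apply_distortion(model$mesh, model$end2_region, d)
  base <- analyze_scan(mesh, scan_config(model$regions, reference_bar()))

  set.seed(3)
  R <- random_rotation()
  t <- c(12, -7, 30)
  moved <- triangle_mesh(sweep(mesh$vertices %*% t(R), 2L, t, FUN = "+"),
                         mesh$faces)
  cfg <- scan_config(model$regions, reference_bar(),
                     frame = reference_frame(origin = t, axes = R))
  realigned <- analyze_scan(moved, cfg)
  expect_equal(realigned$VE_norm, base$VE_norm, tolerance = 1e-6)
  expect_equal(realigned$deltaL, base$deltaL, tolerance = 1e-6)
  expect_equal(realigned$alpha_overall, base$alpha_overall, tolerance = 1e-6)
  expect_equal(realigned$alpha_coronal, base$alpha_coronal, tolerance = 1e-6)
  expect_equal(realigned$alpha_axial, base$alpha_axial, tolerance = 1e-6)
})

test_that("measurement rows carry the per-scan CSV layout", {
  model <- the_model(coarse = TRUE)
  cfg <- scan_config(model$regions, reference_bar(),
                     scan_id = "s1", strategy = "FL")
  row <- as.data.frame(analyze_scan(model$mesh, cfg))
  expect_equal(names(row),
               c("scan_id", "strategy", "deltaL_um", "VE_um", "VE_x_um",
                 "VE_y_um", "VE_z_um", "alpha_overall_deg",
                 "alpha_coronal_deg", "alpha_axial_deg"))
  expect_equal(row$scan_id, "s1")
  expect_equal(row$strategy, "FL")
})
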