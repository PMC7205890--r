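test_that("Green-Lagrange tensor vanishes for rigid motion", {
  ref <- rbind(c(0, 0), c(1, 0), c(0, 1))
  e0 <- lagrangian_tensor(ref, ref)
  expect_equal(unlist(e0), c(e_x1 = 0, e_x2 = 0, e_x1x2 = 0, e_x2x1 = 0))
  a <- 30 * pi / 180
  R <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  er <- lagrangian_tensor(ref, t(R %*% t(ref)) + 2.5)
  expect_lt(max(abs(unlist(er))), 1e-12)
})

test_that("uniaxial stretch gives (lambda^2 - 1) / 2", {
  ref <- rbind(c(0, 0), c(1, 0), c(0, 1))
  def <- ref; def[, 1] <- def[, 1] * 1.1
  e <- lagrangian_tensor(ref, def)
  expect_equal(e$e_x1, (1.1^2 - 1) / 2, tolerance = 1e-9)
  expect_equal(e$e_x2, 0, tolerance = 1e-12)
  expect_identical(e$e_x1x2, e$e_x2x1)
})

test_that("collinear reference triples are rejected", {
  expect_error(lagrangian_tensor(rbind(c(0, 0), c(1, 0), c(2, 0)),
                                 rbind(c(0, 0), c(1, 0), c(2, 0))),
               "collinear")
})

test_that("zero-motion contours track to constant positions and zero strain", {
  f <- list(endo = circle_contour(63, 63, 30, 90),
            epi = circle_contour(63, 63, 48, 90))
  contours <- rep(list(f), 5)
  tw <- track_wall(contours, n_points = 36, frame_window = c(1, 5))
  for (t in 2:5) {
    expect_lt(max(abs(tw$positions[, t, , ] - tw$positions[, 1, , ])), 0.25)
  }
  for (layer in c("endo", "mid", "epi")) {
    cv <- circumferential_strain(tw, layer)
    expect_true(all(abs(cv$values) < 0.005))
  }
  expect_true(all(abs(radial_strain(tw, "endo-mid")$values) < 0.005))
})

test_that("rigid translation is tracked within half a pixel per frame", {
  spec <- phantom_spec(size = 160, spacing = 0.03, rotation_deg = 0,
                       torsion_deg = 0, shear = 0, lambda_min = 1,
                       mu_max = 1, translation = c(16 * 0.03, 0),
                       profile = "linear")
  ph <- generate_phantom(spec)
  tw <- track_wall(ph$contours, n_points = 36)
  for (t in 2:17) {
    d <- tw$positions[, t, , ] - tw$positions[, 1, , ]
    expect_lt(max(abs(d[, , 1] - (t - 1))), 0.5) # 1 px/frame in x
    expect_lt(max(abs(d[, , 2])), 0.5)
  }
  # rigid-motion nullity of the strain curves
  for (cv in list(circumferential_strain(tw, "mid"),
                  radial_strain(tw, "endo-mid"))) {
    expect_lt(max(abs(cv$values)), 0.01)
  }
})

test_that("radial compression moves endocardial points along radii", {
  spec <- small_composite_spec(rotation_deg = 0, torsion_deg = 0, shear = 0,
                               translation = c(0, 0))
  ph <- generate_phantom(spec)
  tw <- track_wall(ph$contours, n_points = 36)
  ctr <- spec$center / spec$spacing
  p1 <- tw$positions["endo", 1, , ]
  ps <- tw$positions["endo", 8, , ] # peak systole
  th1 <- atan2(p1[, 2] - ctr[2], p1[, 1] - ctr[1])
  ths <- atan2(ps[, 2] - ctr[2], ps[, 1] - ctr[1])
  arc <- abs(((ths - th1 + pi) %% (2 * pi)) - pi) *
    sqrt(rowSums(sweep(ps, 2, ctr)^2))
  expect_lt(max(arc), 1) # tangential drift below 1 px
})

test_that("endocardial circumferential strain follows (lambda^2 - 1)/2", {
  spec <- small_composite_spec(rotation_deg = 0, torsion_deg = 0, shear = 0,
                               translation = c(0, 0))
  ph <- generate_phantom(spec)
  tw <- track_wall(ph$contours, n_points = 36)
  cv <- circumferential_strain(tw, "endo")
  lam <- sapply(1:17, function(t) 1 + (spec$lambda_min - 1) *
                  lvstrain:::phantom_profile(spec, t))
  expect_true(all(abs(cv$values - (lam^2 - 1) / 2) < 0.01))
  # inner wall swings further than the outer wall
  ce <- circumferential_strain(tw, "epi")
  expect_gt(max(abs(cv$values)), max(abs(ce$values)))
})

test_that("radial strain follows the thickening ratio and peaks at systole", {
  spec <- small_composite_spec(rotation_deg = 0, torsion_deg = 0, shear = 0,
                               translation = c(0, 0))
  ph <- generate_phantom(spec)
  tw <- track_wall(ph$contours, n_points = 36)
  rv <- radial_strain(tw, "endo-mid")
  mu <- sapply(1:17, function(t) 1 + (spec$mu_max - 1) *
                 lvstrain:::phantom_profile(spec, t))
  expect_true(all(abs(rv$values - (mu^2 - 1) / 2) < 0.02))
  # end-systolic synchronisation: radial peak within 1 frame of the
  # circumferential minimum
  cvm <- circumferential_strain(tw, "mid")
  expect_lt(abs(which.max(rv$values) - which.min(cvm$values)), 2)
  expect_gt(max(rv$values), 0) # positive during systolic thickening
})

test_that("strain conventions agree to first order for small strain", {
  spec <- small_composite_spec(rotation_deg = 0, torsion_deg = 0, shear = 0,
                               translation = c(0, 0), lambda_min = 0.96,
                               mu_max = 1.04)
  ph <- generate_phantom(spec)
  tw <- track_wall(ph$contours, n_points = 36)
  gl <- circumferential_strain(tw, "endo", "green-lagrange")
  en <- circumferential_strain(tw, "endo", "engineering")
  expect_lt(max(abs(gl$values)), 0.05)
  expect_lt(max(abs(gl$values - en$values)), 0.005)
})

test_that("sector curves respect symmetry, counts, and recombine globally", {
  spec <- small_composite_spec(rotation_deg = 0, torsion_deg = 0, shear = 0,
                               translation = c(0, 0))
  # exact positions: axisymmetry makes every sector equal the global curve
  twx <- lvstrain:::exact_tracked_wall(spec, 48)
  scx <- sector_strain(twx, "circumferential", "mid", level = "basal")
  globx <- circumferential_strain(twx, "mid")
  for (cv in scx) expect_lt(max(abs(cv$values - globx$values)), 0.005)
  # tracked pipeline: same symmetry at the rasterisation noise level
  ph <- generate_phantom(spec)
  tw <- track_wall(ph$contours, n_points = 48)
  sc6 <- sector_strain(tw, "circumferential", "mid", level = "basal")
  sc4 <- sector_strain(tw, "circumferential", "mid", level = "apical")
  expect_length(sc6, 6)
  expect_length(sc4, 4)
  glob <- circumferential_strain(tw, "mid")
  for (cv in sc6) expect_lt(max(abs(cv$values - glob$values)), 0.02)
  # point-count-weighted sector average reproduces the global curve
  w <- vapply(sc6, function(cv) cv$n_points, numeric(1))
  avg <- Reduce(`+`, Map(function(cv, wi) cv$values * wi, sc6, w)) / sum(w)
  expect_equal(avg, glob$values, tolerance = 1e-9)
})

test_that("a motion-suppressed wedge is confined to its sector", {
  # exact-map positions isolate the sector machinery from tracking noise
  # (the sharp wedge makes the contours' motion discontinuous, which the
  # centroid-based fallback tracker smears; see the methods vignette)
  spec <- small_composite_spec(rotation_deg = 0, torsion_deg = 0, shear = 0,
                               translation = c(0, 0),
                               wedge = list(start = pi / 6,
                                            width = pi / 3, factor = 0))
  tw <- lvstrain:::exact_tracked_wall(spec, 240)
  sc <- sector_strain(tw, "circumferential", "endo", level = "basal",
                      reference_angle = pi / 6)
  # sector 1 covers exactly the suppressed wedge: only the two chord
  # segments straddling the wedge edges contribute
  expect_lt(max(abs(sc[[1]]$values)), 0.01)
  lam8 <- 1 + (spec$lambda_min - 1) * lvstrain:::phantom_profile(spec, 8)
  ref <- (lam8^2 - 1) / 2
  for (k in 3:5) { # sectors away from the wedge edges are unchanged
    expect_lt(abs(sc[[k]]$values[8] - ref), 0.01)
  }
})

test_that("slope metrics compute secants of the strain limbs", {
  cv <- lvstrain:::new_strain_curve(c(0, -0.1, -0.2, -0.1, 0), 1:5,
                                    "circumferential", "mid",
                                    "green-lagrange")
  m <- slope_metrics(cv)
  expect_equal(m$peak, -0.2)
  expect_identical(m$peak_frame, 3L)
  expect_equal(m$S1, -0.1)
  expect_equal(m$S2, 0.1)
  expect_false(m$monotone)
  # linearity in the curve scale
  cv2 <- cv; cv2$values <- cv$values * 3
  m2 <- slope_metrics(cv2)
  expect_equal(c(m2$S1, m2$S2, m2$peak), 3 * c(m$S1, m$S2, m$peak))
  # monotone curve: S2 undefined
  cvm <- cv; cvm$values <- c(0, -0.05, -0.1, -0.15, -0.2)
  mm <- slope_metrics(cvm)
  expect_true(mm$monotone)
  expect_true(is.na(mm$S2))
})

test_that("tracked S1 is within 10% of the analytic systolic slope", {
  spec <- small_composite_spec(rotation_deg = 0, torsion_deg = 0, shear = 0,
                               translation = c(0, 0))
  ph <- generate_phantom(spec)
  tw <- track_wall(ph$contours, n_points = 36)
  m_est <- slope_metrics(circumferential_strain(tw, "mid"))
  m_gt <- slope_metrics(analytic_strain(spec, "circumferential", "mid"))
  expect_lt(abs(m_est$S1 - m_gt$S1) / abs(m_gt$S1), 0.1)
})

test_that("a missing frame raises a gap error", {
  f <- list(endo = circle_contour(63, 63, 30, 90),
            epi = circle_contour(63, 63, 48, 90))
  contours <- rep(list(f), 5)
  contours[3] <- list(NULL)
  expect_error(track_wall(contours, n_points = 24, frame_window = c(1, 5)),
               "gap")
})

test_that("reference-frame strain is exactly zero", {
  spec <- small_composite_spec()
  tw <- lvstrain:::exact_tracked_wall(spec, 60)
  for (cv in list(circumferential_strain(tw, "endo"),
                  circumferential_strain(tw, "mid"),
                  radial_strain(tw, "mid-epi"))) {
    expect_identical(cv$values[1], 0)
  }
})
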