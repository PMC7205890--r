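make_disc_stack <- function(radii_px, n = 48, pixel = 0.1, slice = 1) {
  # radii_px[slice, frame] cavity radii; myocardium ring 4 px thick
  S <- nrow(radii_px); Tn <- ncol(radii_px)
  masks <- lapply(seq_len(S), function(s) lapply(seq_len(Tn), function(t) {
    ix <- rep(0:(n - 1), each = n); iy <- rep(0:(n - 1), times = n)
    r <- sqrt((ix - (n - 1) / 2)^2 + (iy - (n - 1) / 2)^2)
    lab <- integer(n * n)
    lab[r <= radii_px[s, t]] <- 1L
    lab[r > radii_px[s, t] & r <= radii_px[s, t] + 4] <- 2L
    matrix(lab, n, n)
  }))
  segmentation_stack(masks, pixel_spacing = pixel, slice_spacing = slice)
}

test_that("cavity volume is the slice-area sum times the spacing", {
  # 3 slices with cavity areas 2, 3, 4 mm^2 at 1 mm spacing -> 9 uL
  mk <- function(npx) {
    m <- matrix(0L, 25, 25); m[seq_len(npx)] <- 1L; m
  }
  st <- segmentation_stack(list(list(mk(200)), list(mk(300)), list(mk(400))),
                           pixel_spacing = 0.1, slice_spacing = 1)
  cv <- lv_volume_curve(st)
  expect_equal(cv$volumes, 9)
  # all-empty masks give a zero curve with a warning
  st0 <- segmentation_stack(array(0L, c(8, 8, 2, 3)))
  expect_warning(cv0 <- lv_volume_curve(st0), "empty cavity")
  expect_identical(cv0$volumes, rep(0, 3))
})

test_that("volumes of a disc phantom match pi r^2 within 2%", {
  radii <- rbind(c(14, 11, 9, 11, 14), c(14, 11, 9, 11, 14))
  st <- make_disc_stack(radii, pixel = 0.05, slice = 0.8)
  cv <- lv_volume_curve(st)
  gt <- 2 * pi * (radii[1, ] * 0.05)^2 * 0.8
  expect_true(all(abs(cv$volumes - gt) / gt < 0.02))
  expect_identical(cv$t_ED, 1L)
  expect_identical(cv$t_ES, 3L)
})

test_that("volume curves are additive over slice subsets", {
  radii <- rbind(c(10, 8, 9), c(12, 9, 10), c(8, 7, 7))
  st <- make_disc_stack(radii)
  st1 <- make_disc_stack(radii[1:2, , drop = FALSE])
  st2 <- make_disc_stack(radii[3, , drop = FALSE])
  expect_equal(lv_volume_curve(st)$volumes,
               lv_volume_curve(st1)$volumes + lv_volume_curve(st2)$volumes)
})

test_that("global indices follow the defining formulas", {
  radii <- rbind(c(14, 9), c(14, 9))
  st <- make_disc_stack(radii, pixel = 0.05)
  gi <- global_indices(st)
  expect_equal(gi$SV, gi$EDV - gi$ESV)
  expect_equal(gi$EF, gi$SV / gi$EDV * 100)
  expect_true(gi$EF >= 0 && gi$EF <= 100)
  # EDV 50 / ESV 20 -> SV 30, EF 60
  cv <- list(volumes = c(50, 20), t_ED = 1L, t_ES = 2L)
  gi2 <- global_indices(st, curve = cv)
  expect_equal(gi2$SV, 30)
  expect_equal(gi2$EF, 60)
  # identical frames -> SV 0, EF 0
  st_id <- make_disc_stack(rbind(c(12, 12)))
  gi3 <- global_indices(st_id)
  expect_equal(gi3$SV, 0)
  expect_equal(gi3$EF, 0)
  # EDV 0 -> EF undefined
  st_e <- segmentation_stack(array(2L, c(8, 8, 1, 1))) # wall, no cavity
  expect_error(suppressWarnings(global_indices(st_e)), "EDV")
})

test_that("LVM scales with density and equals 1.05 g per cm^3 of wall", {
  radii <- rbind(c(14, 9))
  st <- make_disc_stack(radii, pixel = 0.05)
  gi <- global_indices(st)
  myo_mm3 <- sum(st$masks[, , 1, 1] == 2L) * st$pixel_area * st$slice_spacing
  expect_equal(gi$LVM, 1.05 * myo_mm3 / 1000)
  gi2 <- global_indices(st, density = 2.1)
  expect_equal(gi2$LVM, 2 * gi$LVM)
})

test_that("EF is invariant to pixel-size rescaling", {
  radii <- rbind(c(14, 9, 12))
  st_a <- make_disc_stack(radii, pixel = 0.05)
  st_b <- make_disc_stack(radii, pixel = 0.2)
  expect_equal(global_indices(st_a)$EF, global_indices(st_b)$EF)
})

test_that("wall thickness recovers the annulus gap in mm", {
  # circles r = 2 mm and 3 mm at 0.05 mm pixels
  px <- 0.05
  ctr <- 70
  endo <- circle_contour(ctr, ctr, 2 / px, 180)
  epi <- circle_contour(ctr, ctr, 3 / px, 180)
  th <- wall_thickness(endo, epi, n_points = 24, spacing = px)
  expect_true(all(abs(th$thickness - 1) < 0.03))
  # identical contours: zero thickness, degenerate flag
  th0 <- wall_thickness(endo, endo, n_points = 24, spacing = px)
  expect_true(attr(th0, "degenerate"))
  expect_identical(th0$thickness, rep(0, 24))
})

test_that("thickness of a uniformly dilated contour is uniform", {
  # epi = endo dilated by 5 px (radial offset of a convex contour)
  th0 <- seq(0, 2 * pi, length.out = 121)[-121]
  r <- 20 + 3 * cos(2 * th0) # mildly elliptical endo
  endo <- closed_contour(60 + r * cos(th0), 60 + r * sin(th0))
  p <- unclass(endo)
  # offset outward along the vertex normal
  nb <- p[c(2:nrow(p), 1), ] - p[c(nrow(p), 1:(nrow(p) - 1)), ]
  nrm <- cbind(nb[, 2], -nb[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  epi <- closed_contour(p - 5 * nrm) # inward normal sign flips with order
  if (contour_area(epi) < contour_area(endo)) {
    epi <- closed_contour(p + 5 * nrm)
  }
  th <- wall_thickness(endo, epi, n_points = 36, spacing = 1)
  expect_lt(sd(th$thickness) / mean(th$thickness), 0.05)
  expect_lt(abs(mean(th$thickness) - 5) / 5, 0.05)
})

test_that("normalised thickening is (ES - ED)/ED with zero-points excluded", {
  th_ed <- structure(data.frame(point_index = 1:10, x = 1:10, y = 1:10,
                                thickness = rep(2, 10)),
                     class = c("thickness_map", "data.frame"))
  th_es <- th_ed
  expect_equal(wall_thickening(th_ed, th_es)$thickening, rep(0, 10))
  th_es$thickness <- th_ed$thickness * 1.5
  expect_equal(wall_thickening(th_ed, th_es)$thickening, rep(0.5, 10))
  th_ed$thickness[3] <- 0
  expect_warning(w <- wall_thickening(th_ed, th_es), "excluded")
  expect_identical(nrow(w), 9L)
})

test_that("sector assignment bins counterclockwise from the reference", {
  # a point 30 degrees past the reference falls in sector 1
  expect_identical(assign_sectors(cbind(cos(pi / 6), sin(pi / 6)), c(0, 0),
                                  "basal"), 1L)
  # 360 uniform points -> 60 per basal sector, 90 per apical sector
  # (half-degree offset keeps points off the ambiguous bin edges)
  th <- (0:359 + 0.5) * pi / 180
  pts <- cbind(cos(th), sin(th))
  expect_identical(as.integer(table(assign_sectors(pts, c(0, 0), "basal"))),
                   rep(60L, 6))
  ap <- assign_sectors(pts, c(0, 0), "apical")
  expect_identical(sort(unique(ap)), 1:4)
  expect_identical(as.integer(table(ap)), rep(90L, 4))
})

test_that("the thickening table reports 16 segments, apex excluded", {
  model <- sector_model(8)
  expect_identical(model$levels,
                   c(rep("basal", 3), rep("mid-cavity", 3),
                     rep("apical", 2)))
  th <- (0:119) * pi / 60
  pts <- cbind(20 + 10 * cos(th), 20 + 10 * sin(th))
  per_slice <- lapply(1:8, function(s) {
    data.frame(point_index = 1:120, x = pts[, 1], y = pts[, 2],
               thickening = rep(0.3, 120))
  })
  centroids <- rep(list(c(20, 20)), 8)
  tab <- thickening_table(per_slice, centroids, model)
  expect_length(tab, 16)
  expect_identical(names(tab)[1], "segment_1")
  expect_identical(names(tab)[16], "segment_16")
  expect_equal(unname(tab), rep(0.3, 16))
})

test_that("GGMRF smoothing honours its energy", {
  x <- c(rep(1, 5), 4, rep(1, 6)) # spike on a 12-point ring
  # gamma = 0: data term only, unchanged
  expect_identical(as.vector(ggmrf_smooth(x, gamma = 0)), x)
  # constant input unchanged for any gamma
  expect_equal(as.vector(ggmrf_smooth(rep(2, 12), gamma = 1.4)), rep(2, 12))
  # p = 2 agrees with the exact quadratic solve on the ring
  gam <- 0.8
  L <- matrix(0, 12, 12)
  for (i in 1:12) {
    L[i, i] <- 2
    L[i, i %% 12 + 1] <- -1
    L[i, (i - 2) %% 12 + 1] <- -1
  }
  exact <- solve(diag(12) + gam^2 * L, x)
  sm <- ggmrf_smooth(x, p = 2, gamma = gam, iterations = 500)
  expect_equal(as.vector(sm), as.vector(exact), tolerance = 1e-5)
  # spike strictly reduced, flat deviation reduced
  expect_lt(sm[6], 4)
  expect_lt(sum(abs(sm - 1)), sum(abs(x - 1)))
  # objective trace is monotone non-increasing (also for p < 2)
  sm1 <- ggmrf_smooth(x, p = 1.3, gamma = 0.7, iterations = 40)
  expect_true(all(diff(attr(sm1, "objective")) <= 1e-12))
})
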