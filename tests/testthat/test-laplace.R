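test_that("one Jacobi update averages the four neighbours", {
  # 3x3 cross: centre interior, neighbours hold 1, 0, 1, 0
  dom <- matrix(FALSE, 3, 3); dom[2, 2] <- TRUE
  low <- matrix(FALSE, 3, 3); high <- low
  high[1, 2] <- TRUE; high[3, 2] <- TRUE # value 1
  low[2, 1] <- TRUE; low[2, 3] <- TRUE   # value 0
  sol <- solve_laplace(dom, low, high)
  expect_equal(sol$values[2, 2], 0.5)
})

test_that("parallel plates give a linear potential ramp", {
  n <- 24
  dom <- matrix(FALSE, n, n); low <- dom; high <- dom
  low[, 1] <- TRUE; high[, n] <- TRUE; dom[, 2:(n - 1)] <- TRUE
  sol <- solve_laplace(dom, low, high, tol = 1e-8)
  ramp <- (1:(n - 2)) / (n - 1)
  for (r in c(1, n %/% 2, n)) {
    expect_equal(sol$values[r, 2:(n - 1)], ramp, tolerance = 1e-5)
  }
})

test_that("interior obeys the discrete maximum principle and fixed point", {
  am <- annulus_masks(96, 12, 30)
  sol <- solve_laplace(am$domain, am$low, am$high, tol = 1e-7,
                       max_iter = 20000)
  v <- sol$values[am$domain]
  expect_true(all(v > 0 & v < 1))
  # fixed point: value = mean of 4 neighbours within 10 * tol
  V <- sol$values
  V[is.na(V)] <- 0 # neighbours outside the annulus are boundary pixels here
  V[am$low] <- 0; V[am$high] <- 1
  n <- nrow(V)
  avg <- (V[c(1, 1:(n - 1)), ] + V[c(2:n, n), ] +
            V[, c(1, 1:(n - 1))] + V[, c(2:n, n)]) / 4
  expect_lt(max(abs(V - avg)[am$domain]), 10 * 1e-7)
})

test_that("Gauss-Seidel agrees with Jacobi at the fixed point", {
  am <- annulus_masks(64, 8, 20)
  sj <- solve_laplace(am$domain, am$low, am$high, tol = 1e-8,
                      max_iter = 50000)
  sg <- solve_laplace(am$domain, am$low, am$high, tol = 1e-8,
                      max_iter = 50000, method = "gauss-seidel")
  expect_lt(max(abs(sj$values - sg$values)[am$domain]), 1e-5)
  expect_lt(sg$iterations, sj$iterations)
})

test_that("invalid geometries are rejected", {
  m <- matrix(FALSE, 8, 8)
  low <- m; high <- m; dom <- m
  low[, 1] <- TRUE; high[, 1] <- TRUE; dom[, 4] <- TRUE
  expect_error(solve_laplace(dom, low, high), "disjoint")
  low2 <- m; low2[, 1] <- TRUE; high2 <- m; high2[, 8] <- TRUE
  expect_error(solve_laplace(m, low2, high2), "degenerate domain")
})

test_that("annulus potential matches the log-radial closed form", {
  ctr <- 63.5
  c1 <- circle_contour(ctr, ctr, 10, 180)
  c2 <- circle_contour(ctr, ctr, 20, 180)
  g <- solve_between_contours(c1, c2, supersample = 4)
  idx <- which(g$cls == 1L, arr.ind = TRUE)
  x <- (idx[, 2] - 1) / g$supersample + g$offset[1]
  y <- (idx[, 1] - 1) / g$supersample + g$offset[2]
  r <- sqrt((x - ctr)^2 + (y - ctr)^2)
  err <- abs(g$values[idx] - log(r / 10) / log(2))
  expect_lt(mean(err), 0.01)
  expect_lt(max(err), 0.04) # boundary-adjacent pixels carry the staircase
})

test_that("streamlines are radial on the annulus and converge in step", {
  am <- annulus_masks(128, 10, 20)
  sol <- solve_laplace(am$domain, am$low, am$high, tol = 1e-7,
                       max_iter = 30000)
  ctr <- 63.5
  for (th0 in c(0.3, 1.7, 3.9)) {
    seed <- c(ctr + 10.5 * cos(th0), ctr + 10.5 * sin(th0))
    tr <- trace_streamline(sol, seed)
    expect_identical(tr$status, "reached")
    ep <- tr$path[nrow(tr$path), ]
    th1 <- atan2(ep[2] - ctr, ep[1] - ctr)
    dth <- abs(((th1 - th0 + pi) %% (2 * pi)) - pi)
    expect_lt(dth * 20, 1) # endpoint within 1 px of the radial direction
    # halving the step moves the endpoint by < 0.5 px
    tr2 <- trace_streamline(sol, seed, step = 0.125)
    ep2 <- tr2$path[nrow(tr2$path), ]
    expect_lt(sqrt(sum((ep - ep2)^2)), 0.5)
  }
})

test_that("a streamline across a strip is straight with the strip's length", {
  n <- 40
  dom <- matrix(FALSE, n, n); low <- dom; high <- dom
  low[, 1:3] <- TRUE; high[, 38:40] <- TRUE; dom[, 4:37] <- TRUE
  sol <- solve_laplace(dom, low, high, tol = 1e-8)
  tr <- trace_streamline(sol, c(3, 20))
  expect_lt(max(abs(tr$path[, 2] - 20)), 0.1) # perpendicular to the plates
  expect_lt(abs(tr$length - 34) / 34, 0.05)
})

test_that("tracing stalls with an error in a flat field", {
  n <- 16
  dom <- matrix(FALSE, n, n); low <- dom; high <- dom
  low[, 1] <- TRUE; high[, n] <- TRUE; dom[, 2:(n - 1)] <- TRUE
  sol <- solve_laplace(dom, low, high)
  sol$values[] <- 0.5 # flatten
  expect_error(trace_streamline(sol, c(5, 8)), "stalled")
})

test_that("concentric-circle correspondence recovers the wall thickness", {
  ctr <- 63.5
  c1 <- circle_contour(ctr, ctr, 10, 180)
  c2 <- circle_contour(ctr, ctr, 20, 180)
  cm <- correspond_contours(c1, c2, n_points = 36)
  expect_identical(nrow(cm), 36L)
  expect_identical(attr(cm, "mode"), "nested")
  expect_true(all(abs(cm$length - 10) / 10 < 0.03))
  # target points sit on the outer circle, at the seed's angle
  rt <- sqrt((cm$target_x - ctr)^2 + (cm$target_y - ctr)^2)
  expect_true(all(abs(rt - 20) < 0.1))
})

test_that("identical contours give the identity map", {
  cc <- circle_contour(30, 30, 8, 60)
  cm <- correspond_contours(cc, cc, n_points = 24)
  expect_identical(attr(cm, "mode"), "identity")
  expect_identical(cm$length, rep(0, 24))
  expect_equal(cm$target_x, cm$source_x)
})

test_that("crossing contours fall back to angle-matched correspondence", {
  a <- circle_contour(40, 40, 10, 120)
  b <- circle_contour(42, 40, 10, 120)
  expect_warning(cm <- correspond_contours(a, b, n_points = 36),
                 "radial re-sorting")
  expect_identical(attr(cm, "mode"), "fallback")
  expect_identical(nrow(cm), 36L)
  # centroid-aligned angular matching recovers the rigid translation, so
  # every pair displaces by the boundary displacement (2, 0)
  expect_lt(abs(mean(cm$length) - 2) / 2, 0.1)
  expect_lt(max(abs(cm$target_x - cm$source_x - 2)), 0.3)
  expect_lt(max(abs(cm$target_y - cm$source_y)), 0.3)
  # pair ordering monotone in angle: successive targets advance
  # counterclockwise about the target centroid, as the seeds do
  ang_t <- atan2(cm$target_y - 40, cm$target_x - 42)
  dw <- (diff(c(ang_t, ang_t[1])) + 2 * pi) %% (2 * pi)
  expect_true(all(dw > 0 & dw < pi))
})

test_that("correspondence count equals n_points across geometries", {
  ctr <- 40
  for (n_points in c(12, 36, 60)) {
    cm <- correspond_contours(circle_contour(ctr, ctr, 8, 90),
                              circle_contour(ctr, ctr, 16, 90),
                              n_points = n_points)
    expect_identical(nrow(cm), as.integer(n_points))
  }
})
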