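#' Solve the Laplace equation between two boundaries
#'
#' Computes the harmonic potential on the region between two closed
#' boundaries by second-order central differences, iterated with the Jacobi
#' scheme: each interior pixel is replaced by the average of its four
#' neighbours until the largest per-pixel change in a sweep falls below
#' `tol`.  The low boundary is held at 0 and the high boundary at 1
#' (Dirichlet conditions), so equipotential lines fill the wall and
#' streamlines of the gradient connect the two boundaries.
#'
#' A checkerboard Gauss-Seidel sweep (`method = "gauss-seidel"`) converges to
#' the same fixed point in fewer iterations and is offered as an equivalent
#' accelerated option.
#'
#' @param domain_mask logical matrix, `TRUE` on interior pixels to solve.
#' @param boundary_low,boundary_high logical matrices holding the Dirichlet
#'   boundaries at values 0 and 1.  The three masks must be pairwise
#'   disjoint.
#' @param spacing pixel spacing `(dx, dy)` in mm, stored for downstream
#'   conversion (the stencil assumes an isotropic grid).
#' @param tol convergence tolerance on the max per-pixel change per sweep.
#' @param max_iter iteration cap; if reached a warning is issued and
#'   `converged` is `FALSE`.
#' @param method `"jacobi"` (the reference scheme) or `"gauss-seidel"`.
#' @param init optional initial interior values (defaults to 0.5).
#' @return A `potential_grid`: list with `values` (matrix, `NA` outside the
#'   problem), `cls` (pixel class codes), `spacing`, `iterations`,
#'   `converged`, `max_change`.
#' @examples
#' g <- matrix(FALSE, 8, 8)
#' low <- g; high <- g; dom <- g
#' low[, 1] <- TRUE; high[, 8] <- TRUE; dom[, 2:7] <- TRUE
#' sol <- solve_laplace(dom, low, high)
#' round(sol$values[4, ], 3) # linear ramp between parallel plates
#' @export
solve_laplace <- function(domain_mask, boundary_low, boundary_high,
                          spacing = c(1, 1), tol = 1e-6, max_iter = 10000,
                          method = c("jacobi", "gauss-seidel"), init = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(domain_mask), tol > 0)
  if (any(boundary_low & boundary_high) || any(domain_mask & boundary_low) ||
      any(domain_mask & boundary_high)) {
    stop("invalid geometry: domain and boundary masks must be disjoint")
  }
  if (!any(domain_mask)) stop("degenerate domain: no interior pixels")
  cls <- matrix(0L, nrow(domain_mask), ncol(domain_mask))
  cls[domain_mask] <- 1L
  cls[boundary_low] <- 2L
  cls[boundary_high] <- 3L
  for (b in list(boundary_low, boundary_high)) {
    if (!any(domain_mask & neighbor_any(b))) {
      stop("invalid geometry: a boundary does not touch the domain")
    }
  }
  v0 <- matrix(0.5, nrow(cls), ncol(cls))
  if (!is.null(init)) v0[cls == 1L] <- init[cls == 1L]
  v0[cls == 2L] <- 0
  v0[cls == 3L] <- 1
  res <- solve_laplace_cpp(v0, cls, tol, as.integer(max_iter),
                           method == "gauss-seidel")
  if (!res$converged) {
    warning(sprintf("Laplace solve hit max_iter = %d (max change %.3g)",
                    max_iter, res$max_change))
  }
  vals <- res$values
  vals[cls == 0L] <- NA_real_
  structure(list(values = vals, cls = cls, spacing = spacing,
                 iterations = res$iterations, converged = res$converged,
                 max_change = res$max_change),
            class = "potential_grid")
}

# TRUE where a pixel has at least one 4-neighbour inside `m`.
neighbor_any <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[, -nc] <- out[, -nc] | m[, -1]
  out[, -1] <- out[, -1] | m[, -nc]
  out
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("<potential_grid> %d x %d, %s after %d iterations (max change %.2g)\n",
              nrow(x$values), ncol(x$values),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_change))
  invisible(x)
}

#' Trace a streamline through a potential field
#'
#' Follows the normalised gradient of the potential with fixed-step Euler
#' integration and bilinear interpolation, from a seed on one boundary to
#' the other.  Streamlines are orthogonal to the equipotential lines, so a
#' trace started on the low boundary ends at the corresponding point of the
#' high boundary; its arc length is the wall thickness at that point.
#'
#' @param grid a `potential_grid` from [solve_laplace()].
#' @param seed numeric `(x, y)` start position (0-based pixel coordinates).
#' @param step integration step in pixels.
#' @param direction `"up"` towards the high boundary, `"down"` towards the
#'   low boundary.
#' @param stop_level potential level at which to stop; defaults to
#'   `1 - eps` (up) or `eps` (down).  Pass 0.5 to stop on the mid-wall
#'   equipotential.
#' @param eps termination tolerance on the potential.
#' @param max_steps cap on integration steps (default scales with the grid).
#' @return List with `path` (matrix of visited (x, y) positions), `length`
#'   (arc length in pixels) and `status`.
#' @export
trace_streamline <- function(grid, seed, step = 0.25,
                             direction = c("up", "down"), stop_level = NULL,
                             eps = 1e-3, max_steps = NULL) {
  direction <- match.arg(direction)
  dirn <- if (direction == "up") 1L else -1L
  if (is.null(stop_level)) stop_level <- if (dirn > 0) 1 - eps else eps
  vals <- grid$values
  vals[is.na(vals)] <- 0.5
  if (is.null(max_steps)) {
    max_steps <- ceiling(4 * (nrow(vals) + ncol(vals)) / step)
  }
  res <- trace_streamline_cpp(vals, grid$cls, seed[1L], seed[2L], step, dirn,
                              stop_level, as.integer(max_steps))
  if (res$status == "stalled") {
    stop("streamline tracing stalled in a flat region (zero gradient)")
  }
  res
}

#' Correspond two nested contours through the Laplace field
#'
#' Establishes one-to-one point correspondences between a source and a
#' target contour: the band between them is rasterised (optionally
#' super-sampled), the Laplace equation is solved with the inner boundary at
#' 0 and the outer at 1, and one streamline is traced from each (resampled)
#' source point across the band.  Each streamline endpoint is projected onto
#' the target polygon, so corresponded points lie exactly on the target
#' contour.  The streamline arc length is the pairing distance (wall
#' thickness when the contours are the endo- and epicardial borders of one
#' frame; point displacement when they are successive frames of one border).
#'
#' If the two contours cross (as successive-frame contours may), the
#' correspondence falls back to radial re-sorting about the shared centroid:
#' each source point is matched to the target point at the same angle, and a
#' warning is logged.  Identical contours yield the identity map with zero
#' lengths.
#'
#' @param source,target [closed_contour()] objects (either may be the inner
#'   one; they must be nested or nearly so).
#' @param n_points number of correspondence pairs (source resampled equally
#'   by arc length).  Ignored when `seeds` is given.
#' @param grid_margin margin in pixels around the contours' bounding box.
#' @param supersample integer grid refinement factor; values above 1 reduce
#'   staircase bias of rasterised thin walls.
#' @param tol,max_iter,method passed to [solve_laplace()].
#' @param step streamline integration step, in (original) pixels.
#' @param align_angle angle (radians) at which resampling starts.
#' @param seeds optional explicit seed points on the source contour
#'   (n x 2 matrix), e.g. previously tracked positions.
#' @return A `correspondence_map` data frame with columns `point_index`,
#'   `source_x`, `source_y`, `target_x`, `target_y`, `length` (pixels), and
#'   attributes `mode` (`"nested"`, `"fallback"` or `"identity"`) and
#'   `inner` (`"source"` or `"target"`).
#' @export
correspond_contours <- function(source, target, n_points = 60,
                                grid_margin = 4, supersample = 3,
                                tol = 1e-6, max_iter = 20000,
                                method = c("jacobi", "gauss-seidel"),
                                step = 0.25, align_angle = 0, seeds = NULL) {
  method <- match.arg(method)
  if (is.null(seeds)) {
    seeds <- resample_contour(source, n_points, align_angle)
  } else {
    seeds <- rbind(seeds)
    n_points <- nrow(seeds)
  }

  ps <- unclass(source); pt <- unclass(target)
  if (nrow(ps) == nrow(pt) && max(abs(ps - pt)) < 1e-9) {
    return(new_correspondence_map(seeds, seeds, numeric(n_points),
                                  mode = "identity", inner = "source"))
  }

  s_in_t <- all(point_in_contour(ps, target))
  t_in_s <- all(point_in_contour(pt, source))
  if (!s_in_t && !t_in_s) {
    return(correspond_fallback(source, target, seeds))
  }

  inner <- if (s_in_t) source else target
  outer <- if (s_in_t) target else source
  band <- rasterize_band(inner, outer, grid_margin, supersample)
  res <- solve_laplace_cpp(band$values, band$cls, tol,
                           as.integer(max_iter), method == "gauss-seidel")
  if (!res$converged) {
    warning(sprintf("correspondence field unconverged (max change %.3g)",
                    res$max_change))
  }
  grid <- list(values = res$values, cls = band$cls)
  dirn <- if (s_in_t) 1L else -1L
  stop_level <- if (dirn > 0) 1 - 1e-3 else 1e-3
  s <- band$supersample
  max_steps <- ceiling(4 * (nrow(band$cls) + ncol(band$cls)) / (step * s))

  tp <- matrix(0, n_points, 2L)
  lens <- numeric(n_points)
  for (i in seq_len(n_points)) {
    g <- (seeds[i, ] - band$offset) * s
    tr <- trace_streamline_cpp(grid$values, grid$cls, g[1L], g[2L],
                               step * s, dirn, stop_level,
                               as.integer(max_steps))
    path <- sweep(tr$path / s, 2L, -band$offset)
    proj <- project_to_contour(path[nrow(path), , drop = FALSE], target)
    path[nrow(path), ] <- proj$points
    tp[i, ] <- proj$points
    n_p <- nrow(path)
    lens[i] <- if (n_p < 2L) 0 else {
      sum(sqrt(rowSums((path[-1L, , drop = FALSE] -
                          path[-n_p, , drop = FALSE])^2)))
    }
  }
  new_correspondence_map(seeds, tp, lens, mode = "nested",
                         inner = if (s_in_t) "source" else "target")
}

new_correspondence_map <- function(src, tgt, lens, mode, inner) {
  structure(data.frame(point_index = seq_len(nrow(src)),
                       source_x = src[, 1L], source_y = src[, 2L],
                       target_x = tgt[, 1L], target_y = tgt[, 2L],
                       length = lens),
            mode = mode, inner = inner,
            class = c("correspondence_map", "data.frame"))
}

# Angle-indexed correspondence used when frame-to-frame contours cross
# slightly and no clean inter-contour band exists: each seed's angle about
# the source centroid picks the target point at the same angle about the
# target centroid (radial re-sorting).  Centroid alignment makes the map
# exact for rigid translation.
correspond_fallback <- function(source, target, seeds) {
  cs <- contour_centroid(source)
  ct <- contour_centroid(target)
  pt <- resample_arclength(unclass(target), 720L, 0)
  th <- atan2(pt[, 2L] - ct[2L], pt[, 1L] - ct[1L])
  rr <- sqrt((pt[, 1L] - ct[1L])^2 + (pt[, 2L] - ct[2L])^2)
  o <- order(th)
  th <- th[o]; rr <- rr[o]
  thx <- c(th - 2 * pi, th, th + 2 * pi)
  rrx <- c(rr, rr, rr)
  a <- atan2(seeds[, 2L] - cs[2L], seeds[, 1L] - cs[1L])
  r_t <- approx(thx, rrx, xout = a, rule = 2)$y
  tgt <- cbind(ct[1L] + r_t * cos(a), ct[2L] + r_t * sin(a))
  proj <- project_to_contour(tgt, target)
  lens <- sqrt(rowSums((proj$points - seeds)^2))
  warning("contours are not nested; using radial re-sorting fallback")
  new_correspondence_map(seeds, proj$points, lens, mode = "fallback",
                         inner = NA_character_)
}

# Rasterise the band between nested contours on a super-sampled grid.
# Pixel classes: 2 inside the inner polygon, 3 outside the outer polygon,
# 1 in the band.  Returns grid-to-original coordinate offset.
rasterize_band <- function(inner, outer, margin, supersample) {
  po <- unclass(outer)
  x0 <- floor(min(po[, 1L])) - margin
  y0 <- floor(min(po[, 2L])) - margin
  x1 <- ceiling(max(po[, 1L])) + margin
  y1 <- ceiling(max(po[, 2L])) + margin
  s <- as.integer(supersample)
  w <- (x1 - x0) * s + 1L
  h <- (y1 - y0) * s + 1L
  gx <- rep(seq_len(w) - 1L, each = h) / s + x0
  gy <- rep(seq_len(h) - 1L, times = w) / s + y0
  pts <- cbind(gx, gy)
  in_inner <- point_in_contour(pts, inner)
  in_outer <- point_in_contour(pts, outer)
  cls <- matrix(1L, h, w)
  cls[matrix(in_inner, h, w)] <- 2L
  cls[matrix(!in_outer, h, w)] <- 3L
  vals <- matrix(0.5, h, w)
  vals[cls == 2L] <- 0
  vals[cls == 3L] <- 1
  list(cls = cls, values = vals, offset = c(x0, y0), supersample = s)
}

#' Solve the Laplace field between two nested contours
#'
#' Convenience wrapper that rasterises the band between two nested contours
#' (inner boundary at 0, outer at 1) on a super-sampled grid and solves the
#' Laplace equation there.  Super-sampling reduces the staircase bias of
#' the rasterised boundaries, which matters for thin mouse walls.
#'
#' @param inner,outer nested [closed_contour()] objects.
#' @param grid_margin margin in pixels around the outer contour.
#' @param supersample integer grid refinement factor.
#' @param tol,max_iter,method passed to the solver, see [solve_laplace()].
#' @return A `potential_grid` with extra fields `offset` (grid origin in
#'   original pixel coordinates) and `supersample`; original-coordinate
#'   position `p` maps to grid position `(p - offset) * supersample`.
#' @export
solve_between_contours <- function(inner, outer, grid_margin = 4,
                                   supersample = 3, tol = 1e-6,
                                   max_iter = 20000,
                                   method = c("jacobi", "gauss-seidel")) {
  method <- match.arg(method)
  if (!all(point_in_contour(unclass(inner), outer))) {
    stop("invalid geometry: `inner` must lie strictly inside `outer`")
  }
  band <- rasterize_band(inner, outer, grid_margin, supersample)
  res <- solve_laplace_cpp(band$values, band$cls, tol,
                           as.integer(max_iter), method == "gauss-seidel")
  if (!res$converged) {
    warning(sprintf("Laplace solve hit max_iter = %d (max change %.3g)",
                    max_iter, res$max_change))
  }
  structure(list(values = res$values, cls = band$cls, spacing = c(1, 1),
                 iterations = res$iterations, converged = res$converged,
                 max_change = res$max_change, offset = band$offset,
                 supersample = band$supersample),
            class = "potential_grid")
}
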