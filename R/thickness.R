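#' 17-segment sector model
#'
#' The standardised partition of the LV into 6 basal, 6 mid-cavity and 4
#' apical sectors plus the apex tip (segment 17), which is excluded from
#' analysis.  Sector division proceeds counterclockwise from a
#' user-supplied reference angle; no anatomical landmark detection is
#' attempted.
#'
#' @param n_slices number of short-axis slices.
#' @param levels optional character vector assigning each slice to
#'   `"basal"`, `"mid-cavity"` or `"apical"`.  By default the first three
#'   slices are basal, the next three mid-cavity, and the rest apical.
#' @param reference_angle sector origin in radians, counterclockwise from
#'   the +x axis.
#' @return A `sector_model` list with `levels`, `reference_angle` and the
#'   global segment id ranges per level.
#' @export
sector_model <- function(n_slices, levels = NULL, reference_angle = 0) {
  if (is.null(levels)) {
    levels <- rep("apical", n_slices)
    levels[seq_len(min(3L, n_slices))] <- "basal"
    if (n_slices > 3L) {
      levels[4:min(6L, n_slices)] <- "mid-cavity"
    }
  }
  stopifnot(length(levels) == n_slices,
            all(levels %in% c("basal", "mid-cavity", "apical", "apex")))
  structure(list(levels = levels, reference_angle = reference_angle,
                 segment_ids = list("basal" = 1:6, "mid-cavity" = 7:12,
                                    "apical" = 13:16, "apex" = 17L)),
            class = "sector_model")
}

#' Assign points to angular sectors
#'
#' Bins points by their angle about the cavity centroid, counterclockwise
#' from the reference angle: 60-degree bins at the basal and mid-cavity
#' levels (6 sectors), 90-degree bins at the apical level (4 sectors).
#'
#' @param points n x 2 matrix of (x, y) positions.
#' @param cavity_centroid `(x, y)` centre to measure angles about.
#' @param level `"basal"`, `"mid-cavity"` or `"apical"`.
#' @param reference_angle sector origin in radians.
#' @return Integer vector of local sector ids (1-6 or 1-4).
#' @export
assign_sectors <- function(points, cavity_centroid,
                           level = c("mid-cavity", "basal", "apical"),
                           reference_angle = 0) {
  level <- match.arg(level)
  n_sec <- if (level == "apical") 4L else 6L
  points <- rbind(points)
  ang <- atan2(points[, 2L] - cavity_centroid[2L],
               points[, 1L] - cavity_centroid[1L])
  rel <- (ang - reference_angle) %% (2 * pi)
  as.integer(pmin(floor(rel / (2 * pi / n_sec)) + 1, n_sec))
}

#' Wall thickness by Laplace point correspondence
#'
#' Thickness at each endocardial point is the arc length of the streamline
#' connecting it to the epicardial border through the Laplace field between
#' the two contours ([correspond_contours()]), converted to mm.
#'
#' @param endo,epi nested [closed_contour()] borders of one slice/frame.
#' @param n_points number of measurement points.
#' @param spacing pixel size in mm.
#' @param ... passed to [correspond_contours()].
#' @return A `thickness_map` data frame with columns `point_index`, `x`,
#'   `y` (endocardial point, pixels), `thickness` (mm); attribute
#'   `degenerate` is `TRUE` when the contours coincide.
#' @export
wall_thickness <- function(endo, epi, n_points = 60, spacing = 1, ...) {
  cm <- correspond_contours(endo, epi, n_points = n_points, ...)
  structure(data.frame(point_index = cm$point_index, x = cm$source_x,
                       y = cm$source_y, thickness = cm$length * spacing),
            degenerate = attr(cm, "mode") == "identity",
            class = c("thickness_map", "data.frame"))
}

#' Pointwise normalised wall thickening
#'
#' Thickening between end diastole and end systole, normalised to the
#' end-diastolic thickness: `(th_ES - th_ED) / th_ED`.  Points with zero
#' end-diastolic thickness are excluded with a warning.
#'
#' @param th_ED,th_ES [wall_thickness()] maps sharing point count and
#'   ordering.
#' @return Data frame `point_index`, `x`, `y`, `thickening`.
#' @export
wall_thickening <- function(th_ED, th_ES) {
  stopifnot(nrow(th_ED) == nrow(th_ES))
  ok <- th_ED$thickness > 0
  if (!all(ok)) {
    warning(sprintf("%d points with zero end-diastolic thickness excluded",
                    sum(!ok)))
  }
  data.frame(point_index = th_ED$point_index[ok], x = th_ED$x[ok],
             y = th_ED$y[ok],
             thickening = (th_ES$thickness[ok] - th_ED$thickness[ok]) /
               th_ED$thickness[ok])
}

#' Per-sector aggregation of a pointwise map
#'
#' Averages a pointwise value (thickening, thickness, strain) over the
#' angular sectors of one slice level.
#'
#' @param values numeric vector of pointwise values.
#' @param points matching n x 2 matrix of positions.
#' @param cavity_centroid,level,reference_angle as in [assign_sectors()].
#' @return Named numeric vector, one mean per local sector (`NA` for empty
#'   sectors).
#' @export
sector_aggregate <- function(values, points, cavity_centroid,
                             level = c("mid-cavity", "basal", "apical"),
                             reference_angle = 0) {
  level <- match.arg(level)
  ids <- assign_sectors(points, cavity_centroid, level, reference_angle)
  n_sec <- if (level == "apical") 4L else 6L
  out <- vapply(seq_len(n_sec), function(k) {
    if (any(ids == k)) mean(values[ids == k]) else NA_real_
  }, numeric(1L))
  names(out) <- paste0("sector_", seq_len(n_sec))
  out
}

#' Assemble the 16-segment thickening table
#'
#' Combines per-slice pointwise thickening into the standard 16 reported
#' values (segments 1-16; the apex-tip segment 17 is dropped).  Slices
#' sharing a level contribute the average of their sector means.
#'
#' @param thickening_per_slice list (one element per slice) of data frames
#'   from [wall_thickening()].
#' @param centroids list of cavity centroids, one `(x, y)` per slice.
#' @param model a [sector_model()] for these slices.
#' @return Named numeric vector `segment_1` .. `segment_16`.
#' @export
thickening_table <- function(thickening_per_slice, centroids, model) {
  acc <- matrix(NA_real_, length(thickening_per_slice), 16L)
  for (s in seq_along(thickening_per_slice)) {
    lev <- model$levels[s]
    if (lev == "apex") next
    th <- thickening_per_slice[[s]]
    sec <- sector_aggregate(th$thickening, cbind(th$x, th$y),
                            centroids[[s]], lev, model$reference_angle)
    ids <- model$segment_ids[[lev]]
    acc[s, ids] <- sec
  }
  out <- colMeans(acc, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  names(out) <- paste0("segment_", 1:16)
  out
}

#' GGMRF smoothing of a pointwise map
#'
#' Regularises a noisy pointwise estimate (wall thickness or thickening)
#' with a generalised Gauss-Markov random field energy
#' `sum |x_s - d_s|^p + gamma^p * sum_{s~r} |x_s - x_r|^p`
#' over the contour-neighbour graph: circular adjacency along each
#' contour, plus matched-point adjacency between adjacent slices when a
#' matrix is supplied.  The energy is minimised by cyclic coordinate
#' descent (exact per-coordinate update for `p = 2`, line search
#' otherwise), so the objective is monotone non-increasing.
#'
#' @param x numeric vector (one contour ring) or matrix (slices x points,
#'   rings stacked across slices).
#' @param p norm exponent in `[1, 2]`; 2 is quadratic smoothing, values
#'   towards 1 preserve edges.
#' @param gamma regularisation weight (0 returns the data unchanged).
#' @param iterations sweep cap.
#' @param tol stop when the objective improves by less than `tol`.
#' @return Smoothed object of the same shape, with attributes `objective`
#'   (trace) and `converged`.
#' @export
ggmrf_smooth <- function(x, p = 2, gamma = 1, iterations = 100,
                         tol = 1e-10) {
  stopifnot(p >= 1, p <= 2, gamma >= 0)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  D <- X
  if (gamma == 0) {
    return(structure(if (vec) as.vector(X) else X, objective = 0,
                     converged = TRUE))
  }
  S <- nrow(X); N <- ncol(X)
  kp <- c(2:N, 1L); km <- c(N, seq_len(N - 1L))
  nb <- function(s, k) {
    v <- c(X[s, kp[k]], X[s, km[k]])
    if (s > 1L) v <- c(v, X[s - 1L, k])
    if (s < S) v <- c(v, X[s + 1L, k])
    v
  }
  energy <- function() {
    pr <- sum(abs(X[, kp, drop = FALSE] - X)^p)
    if (S > 1L) {
      pr <- pr + sum(abs(X[-1L, , drop = FALSE] - X[-S, , drop = FALSE])^p)
    }
    sum(abs(X - D)^p) + gamma^p * pr
  }
  obj <- energy()
  trace <- obj
  converged <- FALSE
  for (it in seq_len(iterations)) {
    for (s in seq_len(S)) {
      for (k in seq_len(N)) {
        v <- nb(s, k)
        if (p == 2) {
          X[s, k] <- (D[s, k] + gamma^2 * sum(v)) /
            (1 + gamma^2 * length(v))
        } else {
          f <- function(z) abs(z - D[s, k])^p + gamma^p * sum(abs(z - v)^p)
          lo <- min(D[s, k], v); hi <- max(D[s, k], v)
          if (hi - lo < 1e-15) {
            X[s, k] <- D[s, k]
          } else {
            X[s, k] <- optimize(f, c(lo, hi))$minimum
          }
        }
      }
    }
    new_obj <- energy()
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol) { converged <- TRUE; obj <- new_obj; break }
    obj <- new_obj
  }
  if (!converged) warning("GGMRF smoothing hit the iteration cap")
  structure(if (vec) as.vector(X) else X, objective = trace,
            converged = converged)
}
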