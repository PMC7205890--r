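#' Track LV wall points over the cardiac cycle
#'
#' Chains Laplace-field correspondences between the contours of successive
#' frames to follow material points on the endocardial and epicardial
#' borders through the cycle.  The mid-wall layer is carried as the
#' midpoint of corresponding endo/epi point pairs (`mid_method =
#' "midpoint"`, the default) or initialised on the 0.5 equipotential of the
#' frame-1 endo-epi field (`"equipotential"`) and carried as pair midpoints
#' thereafter.
#'
#' @param contours list indexed by frame; each element a list with
#'   [closed_contour()] entries `endo` and `epi`.  A `NULL` frame is a gap
#'   and raises an error (no interpolation is attempted).
#' @param n_points number of tracked points per layer.
#' @param frame_window `(first, last)` analysis frames; the default window
#'   covers frames 1-17, over which the strain cycle completes, clamped to
#'   the available frames.
#' @param spacing pixel size in mm (isotropic).
#' @param align_angle angle (radians) at which point 1 is placed on every
#'   layer, so indices agree across layers.
#' @param mid_method mid-wall definition, see Details.
#' @param ... further arguments passed to [correspond_contours()].
#' @return A `tracked_wall`: list with `positions` (array
#'   `[layer, frame, point, xy]`, layers `endo`, `mid`, `epi`), `spacing`,
#'   `frame_window`, `n_points`, and the per-step correspondence `modes`.
#' @export
track_wall <- function(contours, n_points = 60, frame_window = c(1, 17),
                       spacing = 1, align_angle = 0,
                       mid_method = c("midpoint", "equipotential"), ...) {
  mid_method <- match.arg(mid_method)
  if (length(contours) < 2L) stop("tracking needs at least 2 frames")
  frame_window <- c(max(1L, frame_window[1L]),
                    min(length(contours), frame_window[2L]))
  frames <- seq(frame_window[1L], frame_window[2L])
  for (t in frames) {
    if (is.null(contours[[t]]) || is.null(contours[[t]]$endo) ||
        is.null(contours[[t]]$epi)) {
      stop(sprintf("gap in contour sequence at frame %d", t))
    }
  }
  Tn <- length(frames)
  pos <- array(NA_real_, dim = c(3L, Tn, n_points, 2L),
               dimnames = list(c("endo", "mid", "epi"), NULL, NULL,
                               c("x", "y")))
  f1 <- contours[[frames[1L]]]
  pos["endo", 1L, , ] <- resample_contour(f1$endo, n_points, align_angle)
  pos["epi", 1L, , ] <- resample_contour(f1$epi, n_points, align_angle)
  if (mid_method == "midpoint") {
    pos["mid", 1L, , ] <- (pos["endo", 1L, , ] + pos["epi", 1L, , ]) / 2
  } else {
    pos["mid", 1L, , ] <- equipotential_points(f1$endo, f1$epi,
                                               pos["endo", 1L, , ], ...)
  }
  modes <- matrix(NA_character_, Tn - 1L, 2L,
                  dimnames = list(NULL, c("endo", "epi")))
  for (i in seq_len(Tn - 1L)) {
    t0 <- frames[i]; t1 <- frames[i + 1L]
    for (layer in c("endo", "epi")) {
      cm <- withCallingHandlers(
        correspond_contours(contours[[t0]][[layer]],
                            contours[[t1]][[layer]],
                            seeds = pos[layer, i, , ], ...),
        warning = function(w) {
          if (grepl("radial re-sorting", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      pos[layer, i + 1L, , ] <- cbind(cm$target_x, cm$target_y)
      modes[i, layer] <- attr(cm, "mode")
    }
    pos["mid", i + 1L, , ] <- (pos["endo", i + 1L, , ] +
                                 pos["epi", i + 1L, , ]) / 2
  }
  structure(list(positions = pos, spacing = spacing,
                 frame_window = frame_window, frames = frames,
                 n_points = n_points, mid_method = mid_method,
                 modes = modes),
            class = "tracked_wall")
}

# Mid-wall points on the 0.5 equipotential of the endo-epi Laplace field,
# one per endocardial seed.
equipotential_points <- function(endo, epi, seeds, grid_margin = 4,
                                 supersample = 3, tol = 1e-6,
                                 max_iter = 20000, step = 0.25, ...) {
  band <- rasterize_band(endo, epi, grid_margin, supersample)
  res <- solve_laplace_cpp(band$values, band$cls, tol, as.integer(max_iter),
                           FALSE)
  s <- band$supersample
  out <- matrix(0, nrow(seeds), 2L)
  max_steps <- ceiling(4 * (nrow(band$cls) + ncol(band$cls)) / (step * s))
  for (i in seq_len(nrow(seeds))) {
    g <- (seeds[i, ] - band$offset) * s
    tr <- trace_streamline_cpp(res$values, band$cls, g[1L], g[2L], step * s,
                               1L, 0.5, as.integer(max_steps))
    out[i, ] <- tr$path[nrow(tr$path), ] / s + band$offset
  }
  out
}

#' @export
print.tracked_wall <- function(x, ...) {
  cat(sprintf("<tracked_wall> %d points x %d frames (window %d-%d), mid = %s\n",
              x$n_points, length(x$frames), x$frame_window[1L],
              x$frame_window[2L], x$mid_method))
  invisible(x)
}
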