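#' Tagged-MRI frame sequence
#'
#' Container for a grayscale tagged-MRI image stack.  Tagging imprints a
#' saturation grid on the myocardium whose deformation over the cycle
#' reveals tissue motion, which is recovered here by window-correlation
#' template matching.
#'
#' @param frames list of numeric matrices (identical dimensions), or a 3D
#'   array with the third dimension indexing frames.
#' @param spacing pixel size in mm.
#' @return A `tagged_sequence` list with `frames`, `spacing`, `n_frames`.
#' @export
tagged_sequence <- function(frames, spacing = 1) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(t) frames[, , t])
  }
  stopifnot(length(frames) >= 2L)
  d <- dim(frames[[1L]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("all frames must share dimensions")
  }
  structure(list(frames = frames, spacing = spacing,
                 n_frames = length(frames)),
            class = "tagged_sequence")
}

#' Read a tagged stack from a multi-page TIFF or NIfTI file
#' @param path file ending in `.tif`/`.tiff` or `.nii`/`.nii.gz`.
#' @param spacing pixel size in mm (overrides any header value).
#' @return A [tagged_sequence()].
#' @export
read_tagged_stack <- function(path, spacing = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.null(spacing)) spacing <- 1
    tagged_sequence(pages, spacing)
  } else {
    img <- RNifti::readNifti(path)
    if (is.null(spacing)) spacing <- RNifti::pixdim(img)[1L]
    arr <- as.array(img)
    tagged_sequence(aperm(arr, c(2L, 1L, 3L)), spacing)
  }
}

#' Track one point through a tagged sequence by maximum correlation
#'
#' Standard tagged-MRI point tracking: at each step the `template_size` x
#' `template_size` patch centred on the current position in frame `n` is
#' compared, by Pearson (normalised cross-) correlation, against every
#' template-sized patch inside the `search_size` x `search_size` window of
#' frame `n + 1`; the point moves to the best-matching offset.  Ties are
#' broken towards the smallest displacement magnitude, then row-major
#' order, so a flat region yields zero motion.  Tracking is integer-pixel;
#' `subpixel = TRUE` adds parabolic refinement of the correlation peak.
#'
#' @param seq a [tagged_sequence()].
#' @param start `(x, y)` start position (0-based pixels) in frame 1, at
#'   least `search_size %/% 2` pixels from every border.
#' @param template_size,search_size odd window sizes; the defaults (3 in 5)
#'   bound the per-frame displacement to +/- 1 pixel per axis.
#' @param subpixel logical; parabolic sub-pixel refinement (off by
#'   default).
#' @return A `point_track` data frame with columns `frame`, `x`, `y`,
#'   `corr` and attribute `truncated` if the point drifted too close to the
#'   border before the last frame.
#' @export
track_point <- function(seq, start, template_size = 3, search_size = 5,
                        subpixel = FALSE) {
  stopifnot(template_size %% 2 == 1, search_size %% 2 == 1,
            template_size < search_size)
  ht <- template_size %/% 2
  hs <- search_size %/% 2
  d <- dim(seq$frames[[1L]])
  if (start[1L] < hs || start[2L] < hs || start[1L] > d[2L] - 1L - hs ||
      start[2L] > d[1L] - 1L - hs) {
    stop("start point must be at least search_size/2 pixels from the border")
  }
  maxd <- hs - ht
  offs <- expand.grid(dy = -maxd:maxd, dx = -maxd:maxd) # row-major order
  o <- order(offs$dy^2 + offs$dx^2, offs$dy, offs$dx)
  offs <- offs[o, ]

  # continuous position (equal to the integer anchor unless subpixel)
  xc <- round(start[1L]); yc <- round(start[2L])
  x <- xc; y <- yc
  n <- seq$n_frames
  out <- data.frame(frame = seq_len(n), x = NA_real_, y = NA_real_,
                    corr = NA_real_)
  out$x[1L] <- xc; out$y[1L] <- yc
  truncated <- FALSE
  warned_flat <- FALSE
  for (t in seq_len(n - 1L)) {
    tpl <- patch(seq$frames[[t]], x, y, ht)
    if (sd(tpl) < 1e-12) {
      if (!warned_flat) {
        warning("zero-variance template; keeping zero displacement")
        warned_flat <- TRUE
      }
      best <- c(0, 0); bc <- NA_real_
    } else {
      scores <- vapply(seq_len(nrow(offs)), function(i) {
        cand <- patch(seq$frames[[t + 1L]], x + offs$dx[i], y + offs$dy[i],
                      ht)
        if (sd(cand) < 1e-12) return(-Inf)
        cor(as.vector(tpl), as.vector(cand))
      }, numeric(1L))
      if (all(!is.finite(scores))) {
        best <- c(0, 0); bc <- NA_real_
      } else {
        k <- which.max(scores) # first max; offsets pre-sorted by |d|, row-major
        best <- c(offs$dx[k], offs$dy[k])
        bc <- scores[k]
        if (subpixel) best <- best + subpixel_refine(scores, offs, k, maxd)
      }
    }
    # the template is centred on the integer anchor, so the measured
    # displacement applies to the continuous position as well
    xc <- xc + best[1L]; yc <- yc + best[2L]
    x <- round(xc); y <- round(yc)
    out$x[t + 1L] <- xc; out$y[t + 1L] <- yc
    out$corr[t + 1L] <- bc
    if (x < hs || y < hs || x > d[2L] - 1L - hs || y > d[1L] - 1L - hs) {
      truncated <- TRUE
      out <- out[seq_len(t + 1L), ]
      warning(sprintf("track truncated at frame %d (reached border)", t + 1L))
      break
    }
  }
  structure(out, truncated = truncated,
            class = c("point_track", "data.frame"))
}

patch <- function(img, x, y, h) {
  img[(y - h):(y + h) + 1L, (x - h):(x + h) + 1L]
}

# 1D parabolic interpolation of the correlation peak along each axis.
subpixel_refine <- function(scores, offs, k, maxd) {
  ref <- function(dd, axis) {
    lo <- which(offs$dx == dd[1L] - axis[1L] & offs$dy == dd[2L] - axis[2L])
    hi <- which(offs$dx == dd[1L] + axis[1L] & offs$dy == dd[2L] + axis[2L])
    if (!length(lo) || !length(hi)) return(0)
    c0 <- scores[k]; cl <- scores[lo]; ch <- scores[hi]
    if (!is.finite(cl) || !is.finite(ch)) return(0)
    den <- cl - 2 * c0 + ch
    if (abs(den) < 1e-12) return(0)
    max(min(0.5 * (cl - ch) / den, 0.5), -0.5)
  }
  dd <- c(offs$dx[k], offs$dy[k])
  c(ref(dd, c(1L, 0L)), ref(dd, c(0L, 1L)))
}

#' Track several seed points
#' @param seq a [tagged_sequence()].
#' @param starts n x 2 matrix of `(x, y)` seeds (e.g. read from a CSV with
#'   columns `point_id,x,y`).
#' @param ... passed to [track_point()].
#' @return List of `point_track` objects.
#' @export
track_points <- function(seq, starts, ...) {
  starts <- rbind(starts)
  lapply(seq_len(nrow(starts)), function(i) {
    track_point(seq, as.numeric(starts[i, 1:2]), ...)
  })
}

#' Strain curves from tagged point tracks
#'
#' Applies the same Lagrangian strain formulas as the cine pipeline to
#' tracked tagged points.  For circumferential strain the tracks are taken
#' as an ordered ring and each point's segment length is the distance
#' between its two neighbours; for radial strain, `pairs` names the
#' track index pairs whose separation is measured.
#'
#' @param tracks list of `point_track` objects ([track_point()]).
#' @param topology `"circumferential"` (ordered ring, >= 3 tracks) or
#'   `"radial"` (>= 1 pair).
#' @param pairs for radial topology: 2-column matrix of track indices.
#' @param convention strain convention as in [circumferential_strain()].
#' @param normalize divide by the maximum absolute value.
#' @return A `strain_curve`; truncated tracks truncate the curve at the
#'   earliest truncation.
#' @export
strain_from_tracks <- function(tracks,
                               topology = c("circumferential", "radial"),
                               pairs = NULL,
                               convention = c("green-lagrange",
                                              "engineering"),
                               normalize = FALSE) {
  topology <- match.arg(topology)
  convention <- match.arg(convention)
  Tn <- min(vapply(tracks, nrow, integer(1L)))
  n <- length(tracks)
  P <- array(NA_real_, c(1L, Tn, n, 2L),
             dimnames = list("pts", NULL, NULL, c("x", "y")))
  for (i in seq_len(n)) {
    P[1L, , i, 1L] <- tracks[[i]]$x[seq_len(Tn)]
    P[1L, , i, 2L] <- tracks[[i]]$y[seq_len(Tn)]
  }
  fake <- list(positions = P, frames = seq_len(Tn))
  if (topology == "circumferential") {
    if (n < 3L) stop("circumferential topology needs at least 3 tracks")
    S <- pointwise_circ_strain_pos(P, convention)
    finalize_curve(S, fake, "circumferential", "tagged", convention,
                   normalize)
  } else {
    if (is.null(pairs)) {
      if (n < 2L) stop("radial topology needs at least 2 tracks")
      pairs <- cbind(seq_len(n %/% 2), seq_len(n %/% 2) + n %/% 2)
    }
    pairs <- rbind(pairs)
    d <- sapply(seq_len(nrow(pairs)), function(i) {
      sqrt((P[1L, , pairs[i, 1L], 1L] - P[1L, , pairs[i, 2L], 1L])^2 +
             (P[1L, , pairs[i, 1L], 2L] - P[1L, , pairs[i, 2L], 2L])^2)
    })
    d <- rbind(d)
    d0 <- matrix(d[1L, ], nrow(d), ncol(d), byrow = TRUE)
    S <- strain_from_lengths(d, d0, convention)
    finalize_curve(S, fake, "radial", "tagged", convention, normalize)
  }
}

# circumferential pointwise strain for a bare [1, T, N, 2] position array
pointwise_circ_strain_pos <- function(P, convention) {
  Tn <- dim(P)[2L]; N <- dim(P)[3L]
  km <- c(N, seq_len(N - 1L)); kp <- c(2:N, 1L)
  X <- P[1L, , , 1L]; Y <- P[1L, , , 2L]
  if (Tn == 1L) { X <- rbind(X); Y <- rbind(Y) }
  L <- sqrt((X[, kp] - X[, km])^2 + (Y[, kp] - Y[, km])^2)
  L0 <- matrix(L[1L, ], Tn, N, byrow = TRUE)
  strain_from_lengths(L, L0, convention)
}

#' Write point tracks to CSV
#' @param tracks list of `point_track` objects.
#' @param path output CSV (`point_id,frame,x,y,corr`).
#' @return The path, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(seq_along(tracks), function(i) {
    cbind(point_id = i, as.data.frame(tracks[[i]]))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
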