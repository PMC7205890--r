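#' Lagrangian strain tensor from a local point triple
#'
#' Builds the 2D deformation gradient `F` mapping the reference edge
#' vectors of a local point triple (centre, circumferential neighbour,
#' radial neighbour) onto their deformed counterparts and returns the
#' Green-Lagrange tensor `E = (F'F - I)/2`.  `E` is symmetric and vanishes
#' for any rigid motion.
#'
#' @param ref,def 3 x 2 matrices of (x, y) positions: row 1 the centre
#'   point, row 2 its circumferential neighbour, row 3 its radial
#'   neighbour, in the reference and deformed configurations.
#' @return List with normal components `e_x1`, `e_x2` and shear components
#'   `e_x1x2`, `e_x2x1` (equal by symmetry).
#' @examples
#' ref <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' lagrangian_tensor(ref, ref * 1.1)  # 10% biaxial stretch
#' @export
lagrangian_tensor <- function(ref, def) {
  ref <- rbind(ref); def <- rbind(def)
  stopifnot(nrow(ref) == 3L, nrow(def) == 3L)
  R <- cbind(ref[2L, ] - ref[1L, ], ref[3L, ] - ref[1L, ])
  D <- cbind(def[2L, ] - def[1L, ], def[3L, ] - def[1L, ])
  scale2 <- max(sum(R^2), 1e-300)
  if (abs(det(R)) < 1e-12 * scale2) {
    stop("degenerate configuration: reference triple is collinear")
  }
  FF <- D %*% solve(R)
  E <- (t(FF) %*% FF - diag(2)) / 2
  list(e_x1 = E[1L, 1L], e_x2 = E[2L, 2L],
       e_x1x2 = E[1L, 2L], e_x2x1 = E[2L, 1L])
}

new_strain_curve <- function(values, frames, direction, layer,
                             convention, sector = 0L, n_points = NA_integer_) {
  structure(list(values = as.numeric(values), frames = frames,
                 direction = direction, layer = layer,
                 convention = convention, sector = sector,
                 n_points = n_points),
            class = "strain_curve")
}

#' @export
print.strain_curve <- function(x, ...) {
  cat(sprintf("<strain_curve> %s, %s, %s%s: ", x$direction, x$layer,
              x$convention,
              if (x$sector > 0L) paste0(", sector ", x$sector) else ""))
  cat(sprintf("peak %.4f over frames %d-%d\n",
              x$values[which.max(abs(x$values))],
              x$frames[1L], x$frames[length(x$frames)]))
  invisible(x)
}

#' @export
as.data.frame.strain_curve <- function(x, ...) {
  data.frame(frame = x$frames, strain = x$values, direction = x$direction,
             layer = x$layer, sector = x$sector, convention = x$convention)
}

# Strain of a per-frame length measure against the reference frame.
strain_from_lengths <- function(L, L0, convention) {
  if (convention == "green-lagrange") (L^2 - L0^2) / (2 * L0^2)
  else (L - L0) / L0
}

# Pointwise circumferential strain matrix [frame, point]: segment length at
# point k is the distance between tracked neighbours k-1 and k+1.
pointwise_circ_strain <- function(tracked, layer, convention) {
  P <- tracked$positions[layer, , , , drop = FALSE]
  dim(P) <- dim(P)[2:4]
  Tn <- dim(P)[1L]; N <- dim(P)[2L]
  km <- c(N, seq_len(N - 1L)); kp <- c(2:N, 1L)
  L <- sqrt((P[, kp, 1L] - P[, km, 1L])^2 + (P[, kp, 2L] - P[, km, 2L])^2)
  if (Tn == 1L) L <- rbind(L)
  L0 <- matrix(L[1L, ], Tn, N, byrow = TRUE)
  strain_from_lengths(L, L0, convention)
}

# Pointwise radial strain matrix from distances between paired points of
# two layers.
pointwise_radial_strain <- function(tracked, layers, convention) {
  A <- tracked$positions[layers[1L], , , , drop = FALSE]
  B <- tracked$positions[layers[2L], , , , drop = FALSE]
  dim(A) <- dim(A)[2:4]; dim(B) <- dim(B)[2:4]
  Tn <- dim(A)[1L]; N <- dim(A)[2L]
  d <- sqrt((A[, , 1L] - B[, , 1L])^2 + (A[, , 2L] - B[, , 2L])^2)
  if (Tn == 1L) d <- rbind(d)
  d0 <- matrix(d[1L, ], Tn, N, byrow = TRUE)
  strain_from_lengths(d, d0, convention)
}

finalize_curve <- function(S, tracked, direction, layer, convention,
                           normalize) {
  v <- rowMeans(S)
  v[1L] <- 0 # reference frame, exactly
  if (normalize) {
    m <- max(abs(v))
    if (m > 0) v <- v / m
  }
  new_strain_curve(v, tracked$frames, direction, layer, convention,
                   n_points = ncol(S))
}

#' Circumferential strain curve
#'
#' Computes Lagrangian circumferential strain per tracked point from the
#' change in distance between its ring neighbours, referenced to the first
#' analysis frame, and averages over points.  With the default
#' Green-Lagrange convention the pointwise strain is
#' `(L_t^2 - L_0^2) / (2 L_0^2)`; the engineering option uses
#' `(L_t - L_0)/L_0`.  Circumferential strain is negative during systole as
#' the perimeter shortens.
#'
#' @param tracked a [track_wall()] result.
#' @param layer `"endo"`, `"mid"` or `"epi"`.
#' @param convention strain convention.
#' @param normalize divide the curve by its maximum absolute value
#'   (used when comparing curve shapes).
#' @return A `strain_curve`.
#' @export
circumferential_strain <- function(tracked, layer = c("mid", "endo", "epi"),
                                   convention = c("green-lagrange",
                                                  "engineering"),
                                   normalize = FALSE) {
  layer <- match.arg(layer)
  convention <- match.arg(convention)
  S <- pointwise_circ_strain(tracked, layer, convention)
  finalize_curve(S, tracked, "circumferential", layer, convention, normalize)
}

#' Radial strain curve
#'
#' Computes Lagrangian radial strain from the distance between paired
#' points of two wall layers (inner radial strain between endo and mid, or
#' outer radial strain between mid and epi).  Radial strain is positive
#' during systolic wall thickening.
#'
#' @param tracked a [track_wall()] result.
#' @param layer_pair `"endo-mid"` or `"mid-epi"`.
#' @inheritParams circumferential_strain
#' @return A `strain_curve`.
#' @export
radial_strain <- function(tracked, layer_pair = c("endo-mid", "mid-epi"),
                          convention = c("green-lagrange", "engineering"),
                          normalize = FALSE) {
  layer_pair <- match.arg(layer_pair)
  convention <- match.arg(convention)
  layers <- strsplit(layer_pair, "-", fixed = TRUE)[[1L]]
  S <- pointwise_radial_strain(tracked, layers, convention)
  finalize_curve(S, tracked, "radial", layer_pair, convention, normalize)
}

#' Per-sector strain curves
#'
#' Bins tracked points by angle about the cavity centroid at the reference
#' frame (bin membership is fixed at frame 1) and returns one strain curve
#' per sector: six sectors at the basal and mid-cavity levels, four at the
#' apical level, counted counterclockwise from `reference_angle`.
#'
#' @inheritParams circumferential_strain
#' @param direction `"circumferential"` or `"radial"`.
#' @param layer layer (circumferential) or layer pair (radial).
#' @param level slice level, which sets the number of sectors.
#' @param reference_angle sector origin in radians (the anatomical
#'   reference must be supplied; it is not detected).
#' @return List of `strain_curve` objects, one per sector; sectors with no
#'   points carry `NA` values and an `undefined` attribute.
#' @export
sector_strain <- function(tracked, direction = c("circumferential", "radial"),
                          layer = NULL,
                          level = c("mid-cavity", "basal", "apical"),
                          reference_angle = 0,
                          convention = c("green-lagrange", "engineering"),
                          normalize = FALSE) {
  direction <- match.arg(direction)
  level <- match.arg(level)
  convention <- match.arg(convention)
  if (direction == "circumferential") {
    if (is.null(layer)) layer <- "mid"
    S <- pointwise_circ_strain(tracked, layer, convention)
    ref_layer <- layer
  } else {
    if (is.null(layer)) layer <- "endo-mid"
    layers <- strsplit(layer, "-", fixed = TRUE)[[1L]]
    S <- pointwise_radial_strain(tracked, layers, convention)
    ref_layer <- layers[1L]
  }
  ref_pts <- tracked$positions[ref_layer, 1L, , ]
  ctr <- colMeans(tracked$positions["endo", 1L, , ])
  ids <- assign_sectors(ref_pts, ctr, level, reference_angle)
  n_sec <- if (level == "apical") 4L else 6L
  out <- vector("list", n_sec)
  for (k in seq_len(n_sec)) {
    sel <- ids == k
    if (!any(sel)) {
      warning(sprintf("sector %d has no points; curve undefined", k))
      cv <- new_strain_curve(rep(NA_real_, nrow(S)), tracked$frames,
                             direction, layer, convention, sector = k)
      attr(cv, "undefined") <- TRUE
    } else {
      cv <- finalize_curve(S[, sel, drop = FALSE], tracked, direction,
                           layer, convention, normalize)
      cv$sector <- k
      cv$n_points <- sum(sel)
    }
    out[[k]] <- cv
  }
  out
}

#' Systolic and diastolic slope metrics of a strain curve
#'
#' The peak is the extremum of absolute strain (so the same definition
#' serves negative circumferential and positive radial curves).  `S1` is
#' the secant slope from the first analysis frame to the peak frame, `S2`
#' the secant slope from the peak frame to the last frame; a least-squares
#' variant fits straight lines to the two limbs instead.
#'
#' @param curve a `strain_curve`.
#' @param method `"secant"` (two-point slopes) or `"lsfit"` (least-squares
#'   line per limb).
#' @return List with `S1`, `S2` (strain per frame), `peak`, `peak_frame`,
#'   and `monotone` (`TRUE` when the peak falls on the window edge, leaving
#'   `S2` undefined).
#' @export
slope_metrics <- function(curve, method = c("secant", "lsfit")) {
  method <- match.arg(method)
  v <- curve$values; f <- curve$frames
  if (length(v) < 3L) stop("slope metrics need at least 3 frames")
  ip <- which.max(abs(v))
  peak <- v[ip]
  monotone <- ip == length(v)
  if (method == "secant") {
    S1 <- if (ip > 1L) (peak - v[1L]) / (f[ip] - f[1L]) else NA_real_
    S2 <- if (!monotone) (v[length(v)] - peak) / (f[length(f)] - f[ip])
          else NA_real_
  } else {
    S1 <- if (ip > 1L) stats::coef(stats::lm(v[1:ip] ~ f[1:ip]))[[2L]]
          else NA_real_
    S2 <- if (!monotone) {
      stats::coef(stats::lm(v[ip:length(v)] ~ f[ip:length(f)]))[[2L]]
    } else NA_real_
  }
  list(S1 = S1, S2 = S2, peak = peak, peak_frame = f[ip],
       monotone = monotone)
}
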