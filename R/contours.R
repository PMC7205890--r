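#' Closed wall contour
#'
#' Construct an ordered closed contour (a simple polygon) describing one
#' myocardial boundary on a short-axis slice.  Coordinates are 0-based pixel
#' positions with `x` along columns and `y` along rows; the vertex order is
#' normalised to counterclockwise (positive shoelace area in the (x, y)
#' frame).  A duplicated closing vertex is dropped.
#'
#' @param x numeric vector of x coordinates, or a two-column matrix/data
#'   frame of (x, y) points.
#' @param y numeric vector of y coordinates when `x` is a vector.
#' @return A `closed_contour`: a numeric matrix with columns `x`, `y`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' cc <- closed_contour(10 + 5 * cos(th), 10 + 5 * sin(th))
#' contour_area(cc)
#' @export
closed_contour <- function(x, y = NULL) {
  if (is.null(y)) {
    p <- as.matrix(x)
    if (ncol(p) != 2L) stop("contour input must have two columns (x, y)")
  } else {
    p <- cbind(x, y)
  }
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  n <- nrow(p)
  if (n >= 2L && all(abs(p[1L, ] - p[n, ]) < 1e-12)) p <- p[-n, , drop = FALSE]
  d <- sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2))
  if (any(d < 1e-12)) {
    p <- p[d >= 1e-12, , drop = FALSE]
  }
  if (nrow(p) < 8L) stop("a closed contour needs at least 8 distinct points")
  if (shoelace(p) < 0) p <- p[nrow(p):1L, , drop = FALSE]
  structure(p, class = c("closed_contour", "matrix", "array"))
}

# Signed polygon area (positive = counterclockwise in the (x, y) frame).
shoelace <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(2:nrow(p), 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area of a contour
#' @param contour a [closed_contour()].
#' @return Area in squared pixel units.
#' @export
contour_area <- function(contour) abs(shoelace(unclass(contour)))

#' Polygon centroid of a contour
#' @param contour a [closed_contour()].
#' @return Length-2 vector (x, y), area-weighted polygon centroid.
#' @export
contour_centroid <- function(contour) {
  p <- unclass(contour)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(2:nrow(p), 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Test whether points lie inside a contour
#'
#' @param points two-column matrix of (x, y) points.
#' @param contour a [closed_contour()].
#' @return Logical vector, `TRUE` for points strictly inside.
#' @export
point_in_contour <- function(points, contour) {
  points <- rbind(points)
  mgcv::in.out(rbind(unclass(contour), unclass(contour)[1L, ]),
               cbind(points[, 1L], points[, 2L]))
}

#' Resample a contour uniformly by arc length
#'
#' Produces `n` points equally spaced along the polygon perimeter.  The
#' starting point is placed where the ray from the contour centroid at
#' `align_angle` (counterclockwise from the +x axis) crosses the contour, so
#' that index `k` refers to comparable angular positions across layers and
#' frames.
#'
#' @param contour a [closed_contour()].
#' @param n number of output points.
#' @param align_angle reference angle in radians for the first point.
#' @return `n` x 2 matrix of (x, y) points in contour order.
#' @export
resample_contour <- function(contour, n, align_angle = 0) {
  p <- unclass(contour)
  # dense uniform resampling, then rotate the start to the alignment ray
  m <- max(8L * n, 512L)
  q <- resample_arclength(p, m, 0)
  ctr <- contour_centroid(contour)
  ang <- atan2(q[, 2L] - ctr[2L], q[, 1L] - ctr[1L])
  dang <- (ang - align_angle) %% (2 * pi)
  start <- which.min(pmin(dang, 2 * pi - dang))
  q <- q[c(start:m, seq_len(start - 1L)), , drop = FALSE]
  resample_arclength(q, n, 0)
}

# Arc-length-uniform resampling starting at vertex 1 + offset (fraction of
# total perimeter).
resample_arclength <- function(p, n, offset) {
  pc <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- (offset + seq(0, total, length.out = n + 1L)[-(n + 1L)]) %% total
  ix <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[ix]) / pmax(seg[ix], 1e-300)
  pc[ix, , drop = FALSE] + frac * (pc[ix + 1L, , drop = FALSE] -
                                     pc[ix, , drop = FALSE])
}

# Nearest point on the closed polyline of `contour` to each row of `points`.
# Returns list(points = projected coordinates, dist = distances).
project_to_contour <- function(points, contour) {
  p <- unclass(contour)
  a <- p
  b <- p[c(2:nrow(p), 1L), , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  points <- rbind(points)
  out <- matrix(0, nrow(points), 2L)
  dd <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    t <- pmin(pmax(((points[i, 1L] - a[, 1L]) * ab[, 1L] +
                      (points[i, 2L] - a[, 2L]) * ab[, 2L]) / len2, 0), 1)
    proj <- a + t * ab
    d2 <- (proj[, 1L] - points[i, 1L])^2 + (proj[, 2L] - points[i, 2L])^2
    k <- which.min(d2)
    out[i, ] <- proj[k, ]
    dd[i] <- sqrt(d2[k])
  }
  list(points = out, dist = dd)
}

#' Read and write contour tables
#'
#' Contours are exchanged as CSV with columns
#' `slice,frame,layer,point_index,x,y` (`layer` one of `endo`, `mid`, `epi`).
#' `read_contours_csv()` returns a nested list `res[[slice]][[frame]]$layer`
#' of [closed_contour()] objects.
#'
#' @param path CSV file path.
#' @param contours for writing: nested list as returned by
#'   `read_contours_csv()`, i.e. `contours[[slice]][[frame]]$<layer>`.
#' @return `read_contours_csv()`: nested list of contours;
#'   `write_contours_csv()`: the path, invisibly.
#' @export
read_contours_csv <- function(path) {
  d <- read.csv(path)
  need <- c("slice", "frame", "layer", "point_index", "x", "y")
  if (!all(need %in% names(d))) {
    stop("contour CSV must have columns ", paste(need, collapse = ","))
  }
  out <- list()
  for (s in sort(unique(d$slice))) {
    ds <- d[d$slice == s, ]
    fr <- list()
    for (t in sort(unique(ds$frame))) {
      dt <- ds[ds$frame == t, ]
      layers <- list()
      for (l in unique(dt$layer)) {
        dl <- dt[dt$layer == l, ]
        dl <- dl[order(dl$point_index), ]
        layers[[l]] <- closed_contour(dl$x, dl$y)
      }
      fr[[t]] <- layers
    }
    out[[s]] <- fr
  }
  out
}

#' @rdname read_contours_csv
#' @export
write_contours_csv <- function(contours, path) {
  rows <- list()
  for (s in seq_along(contours)) {
    for (t in seq_along(contours[[s]])) {
      layers <- contours[[s]][[t]]
      for (l in names(layers)) {
        p <- unclass(layers[[l]])
        rows[[length(rows) + 1L]] <- data.frame(
          slice = s, frame = t, layer = l,
          point_index = seq_len(nrow(p)), x = p[, 1L], y = p[, 2L])
      }
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
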