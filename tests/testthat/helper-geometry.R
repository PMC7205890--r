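# Shared geometric fixtures, generated in code.

circle_contour <- function(cx, cy, r, n = 120) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  closed_contour(cx + r * cos(th), cy + r * sin(th))
}

# Binary annulus masks on an n x n grid (0-based pixel centres).
annulus_masks <- function(n, r_in, r_out, cx = (n - 1) / 2,
                          cy = (n - 1) / 2) {
  ix <- rep(0:(n - 1), each = n)
  iy <- rep(0:(n - 1), times = n)
  r <- sqrt((ix - cx)^2 + (iy - cy)^2)
  list(domain = matrix(r > r_in & r < r_out, n, n),
       low = matrix(r <= r_in, n, n),
       high = matrix(r >= r_out, n, n),
       radius = matrix(r, n, n))
}

# Shift image content by an integer vector (zero fill).
shift_image <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  ys <- (1 + max(0, dy)):(nrow(m) + min(0, dy))
  xs <- (1 + max(0, dx)):(ncol(m) + min(0, dx))
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Tag-crossing seed points (px) of a phantom spec within a radius window.
tag_crossing_seeds <- function(spec, pitch = spec$tag_spacing,
                               rmin = spec$r_endo + 0.05,
                               rmax = spec$r_epi - 0.05) {
  k <- seq(-ceiling(rmax / pitch), ceiling(rmax / pitch))
  g <- as.matrix(expand.grid(x = k * pitch, y = k * pitch))
  r <- sqrt(rowSums(g^2))
  g <- g[r >= rmin & r <= rmax, , drop = FALSE]
  round(sweep(g, 2, spec$center, `+`) / spec$spacing)
}

# Exact per-frame positions of reference points under the phantom map, px.
phantom_truth_px <- function(spec, seeds_px) {
  ref <- seeds_px * spec$spacing
  lapply(seq_len(nrow(ref)), function(i) {
    t(vapply(seq_len(spec$n_frames), function(t) {
      phantom_forward(spec, ref[i, , drop = FALSE], t)[1L, ]
    }, numeric(2L))) / spec$spacing
  })
}

# A small, fast composite-motion phantom for module-level tests.
small_composite_spec <- function(...) {
  phantom_spec(size = 128, spacing = 0.03, ...)
}
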