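#' Specification of the synthetic deforming-LV phantom
#'
#' Defines a mid-ventricular annular myocardium (endo/epi circles) that
#' undergoes the five motion classes of a beating LV over one cycle:
#' translation, rigid rotation, torsion (differential rotation across the
#' wall), simple shear, and radial compression of the cavity with wall
#' thickening.  The composite map has a closed-form inverse, so tracked
#' quantities can be compared against exact ground truth.
#'
#' The deformation at frame `t` scales with a temporal profile `w(t)`:
#' a raised cosine rising from 0 at frame 1 to 1 at the systolic frame
#' `t_sys` and returning to 0 at the last frame, or a linear ramp
#' (`profile = "linear"`, useful for constant-rate test motions).
#'
#' The default geometry and amplitudes are sized to a mouse mid-ventricular
#' slice: endo radius 1.0 mm, epi 1.6 mm, 0.015 mm pixels on a 256^2 grid,
#' 17 frames, cavity compression to `lambda_min = 0.8` of the end-diastolic
#' endocardial radius with wall thickening `mu_max = 1.3`, 5 degrees rigid
#' rotation, 8 degrees torsion across the wall, shear factor 0.05 and
#' ~0.1 mm translation at peak systole.
#'
#' @param size image side in pixels.
#' @param spacing pixel size in mm.
#' @param r_endo,r_epi end-diastolic endo/epi radii in mm.
#' @param n_frames number of frames (the cycle completes in the window).
#' @param t_sys frame of peak systole.
#' @param translation `(dx, dy)` peak translation in mm.
#' @param rotation_deg peak rigid rotation in degrees.
#' @param torsion_deg peak endo-to-epi differential rotation in degrees.
#' @param shear peak simple-shear factor.
#' @param lambda_min endocardial radius ratio at peak systole (< 1
#'   compresses the cavity).
#' @param mu_max wall-thickness ratio at peak systole (> 1 thickens).
#' @param profile temporal profile, `"raised-cosine"` or `"linear"`.
#' @param wedge optional angular motion modulation for sector tests:
#'   `list(start, width, factor, taper)` (radians; compression, rotation
#'   and torsion amplitudes are multiplied by `factor` for material angles
#'   inside the wedge, returning smoothly to 1 over the `taper` width,
#'   default 10 degrees, outside its edges).
#' @param center LV centre in mm; defaults to the image centre.
#' @param tag_spacing tag-line separation in mm for [render_tagged()].
#' @param seed RNG seed for rendered texture noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 256, spacing = 0.015, r_endo = 1.0,
                         r_epi = 1.6, n_frames = 17, t_sys = 8,
                         translation = c(0.07, -0.07), rotation_deg = 5,
                         torsion_deg = 8, shear = 0.05, lambda_min = 0.8,
                         mu_max = 1.3,
                         profile = c("raised-cosine", "linear"),
                         wedge = NULL, center = NULL, tag_spacing = 0.6,
                         seed = 1) {
  profile <- match.arg(profile)
  stopifnot(lambda_min > 0, lambda_min <= 1, mu_max >= 1,
            r_endo > 0, r_epi > r_endo, n_frames >= 3,
            t_sys > 1, t_sys <= n_frames)
  if (is.null(center)) center <- rep((size - 1) / 2 * spacing, 2L)
  structure(list(size = as.integer(size), spacing = spacing,
                 r_endo = r_endo, r_epi = r_epi,
                 n_frames = as.integer(n_frames), t_sys = t_sys,
                 translation = translation,
                 rotation = rotation_deg * pi / 180,
                 torsion = torsion_deg * pi / 180, shear = shear,
                 lambda_min = lambda_min, mu_max = mu_max,
                 profile = profile, wedge = wedge, center = center,
                 tag_spacing = tag_spacing, seed = seed),
            class = "phantom_spec")
}

# Temporal amplitude profile w(t) in [0, 1]; 0 at frame 1.
phantom_profile <- function(spec, t) {
  if (spec$profile == "linear") return((t - 1) / (spec$n_frames - 1))
  ifelse(t <= spec$t_sys,
         (1 - cos(pi * (t - 1) / (spec$t_sys - 1))) / 2,
         (1 + cos(pi * (t - spec$t_sys) / (spec$n_frames - spec$t_sys))) / 2)
}

# Wedge modulation factor per material angle.  The stated wedge is fully
# modulated; a raised-cosine taper (default 10 degrees) outside its edges
# returns to 1 so the deformation stays continuous (tissue cannot deform
# discontinuously, and chord-based strain would blow up at a sharp edge).
wedge_factor <- function(spec, theta) {
  if (is.null(spec$wedge)) return(rep(1, length(theta)))
  taper <- if (is.null(spec$wedge$taper)) pi / 18 else spec$wedge$taper
  rel <- (theta - spec$wedge$start) %% (2 * pi)
  d <- pmin(pmax(rel - spec$wedge$width, 0), pmax(2 * pi - rel, 0))
  ramp <- pmin(d / taper, 1)
  s <- (1 - cos(pi * ramp)) / 2
  spec$wedge$factor + (1 - spec$wedge$factor) * s
}

#' Forward and inverse phantom motion maps
#'
#' `phantom_forward()` maps reference (frame-1) positions to their
#' location at frame `t`; `phantom_inverse()` is its exact inverse (an
#' iterative refinement is used only when a wedge modulation combines with
#' rotation or torsion).  Positions are in mm.
#'
#' The composite map, about the LV centre, is: (i) radial scaling, linear
#' across the wall so that the endo radius scales by `lambda(t)` and the
#' wall thickness by `mu(t)`; (ii) rotation plus torsion growing linearly
#' from endo to epi; (iii) simple shear; (iv) translation.
#'
#' @param spec a [phantom_spec()].
#' @param p n x 2 matrix of (x, y) positions in mm.
#' @param t frame number (1-based; frame 1 is the identity).
#' @return n x 2 matrix of mapped positions in mm.
#' @export
phantom_forward <- function(spec, p, t) {
  p <- rbind(p)
  w <- phantom_profile(spec, t)
  ux <- p[, 1L] - spec$center[1L]
  uy <- p[, 2L] - spec$center[2L]
  r <- sqrt(ux^2 + uy^2)
  th <- atan2(uy, ux)
  m <- wedge_factor(spec, th)
  lam <- 1 + (spec$lambda_min - 1) * w * m
  mu <- 1 + (spec$mu_max - 1) * w * m
  R1 <- spec$r_endo; R2 <- spec$r_epi; W0 <- R2 - R1
  rp <- ifelse(r < R1, lam * r,
               ifelse(r <= R2, lam * R1 + mu * (r - R1),
                      lam * R1 + mu * W0 + (r - R2)))
  frac <- pmin(pmax((r - R1) / W0, 0), 1)
  thp <- th + (spec$rotation + spec$torsion * frac) * w * m
  xp <- rp * cos(thp)
  yp <- rp * sin(thp)
  xs <- xp + spec$shear * w * yp
  cbind(spec$center[1L] + xs + spec$translation[1L] * w,
        spec$center[2L] + yp + spec$translation[2L] * w)
}

#' @rdname phantom_forward
#' @export
phantom_inverse <- function(spec, p, t) {
  p <- rbind(p)
  w <- phantom_profile(spec, t)
  xs <- p[, 1L] - spec$center[1L] - spec$translation[1L] * w
  ys <- p[, 2L] - spec$center[2L] - spec$translation[2L] * w
  xp <- xs - spec$shear * w * ys
  yp <- ys
  rp <- sqrt(xp^2 + yp^2)
  thp <- atan2(yp, xp)
  R1 <- spec$r_endo; R2 <- spec$r_epi; W0 <- R2 - R1
  invert_with <- function(m) {
    lam <- 1 + (spec$lambda_min - 1) * w * m
    mu <- 1 + (spec$mu_max - 1) * w * m
    r <- ifelse(rp < lam * R1, rp / lam,
                ifelse(rp <= lam * R1 + mu * W0,
                       R1 + (rp - lam * R1) / mu,
                       R2 + (rp - lam * R1 - mu * W0)))
    frac <- pmin(pmax((r - R1) / W0, 0), 1)
    th <- thp - (spec$rotation + spec$torsion * frac) * w * m
    list(r = r, th = th)
  }
  if (is.null(spec$wedge)) {
    s <- invert_with(1)
  } else {
    # the modulation depends on the material angle; fixed-point refinement
    th_est <- thp
    for (i in 1:8) {
      s <- invert_with(wedge_factor(spec, th_est))
      th_est <- s$th
    }
  }
  cbind(spec$center[1L] + s$r * cos(s$th),
        spec$center[2L] + s$r * sin(s$th))
}

#' Generate the phantom sequence
#'
#' Renders the phantom as per-frame wall contours (in pixels, ready for
#' [track_wall()]) and label masks (0 background, 1 cavity, 2 myocardium),
#' rasterised exactly through the inverse motion map.
#'
#' @param spec a [phantom_spec()].
#' @param contour_points vertices per rendered contour.
#' @return A `phantom_sequence` list with `spec`, `contours`
#'   (`[[t]]$endo` / `$epi`, [closed_contour()] in pixel coordinates) and
#'   `masks` (list of label matrices).
#' @export
generate_phantom <- function(spec, contour_points = 360) {
  th <- seq(0, 2 * pi, length.out = contour_points + 1L)[-(contour_points + 1L)]
  ref_endo <- cbind(spec$center[1L] + spec$r_endo * cos(th),
                    spec$center[2L] + spec$r_endo * sin(th))
  ref_epi <- cbind(spec$center[1L] + spec$r_epi * cos(th),
                   spec$center[2L] + spec$r_epi * sin(th))
  n <- spec$size
  gx <- (rep(seq_len(n), each = n) - 1) * spec$spacing   # column-major
  gy <- (rep(seq_len(n), times = n) - 1) * spec$spacing
  grid <- cbind(gx, gy)
  contours <- vector("list", spec$n_frames)
  masks <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    e <- phantom_forward(spec, ref_endo, t) / spec$spacing
    o <- phantom_forward(spec, ref_epi, t) / spec$spacing
    if (min(o) < 1 || max(o) > n - 2) {
      stop("geometry overflow: phantom motion leaves the image")
    }
    contours[[t]] <- list(endo = closed_contour(e), epi = closed_contour(o))
    q <- phantom_inverse(spec, grid, t)
    rq <- sqrt((q[, 1L] - spec$center[1L])^2 + (q[, 2L] - spec$center[2L])^2)
    lab <- integer(n * n)
    lab[rq < spec$r_endo] <- 1L
    lab[rq >= spec$r_endo & rq <= spec$r_epi] <- 2L
    masks[[t]] <- matrix(lab, n, n)
  }
  structure(list(spec = spec, contours = contours, masks = masks),
            class = "phantom_sequence")
}

#' Ground-truth strain of the phantom
#'
#' Evaluates the strain curve that an ideal tracker would measure: the
#' reference layer points are mapped through the exact motion map at every
#' frame and the same Lagrangian strain formulas as the cine pipeline are
#' applied to the exact positions.
#'
#' @param spec a [phantom_spec()].
#' @param direction `"circumferential"` or `"radial"`.
#' @param layer layer for circumferential strain (`"endo"`, `"mid"`,
#'   `"epi"`); for radial strain a layer pair (`"endo-mid"`, `"mid-epi"`).
#' @param convention strain convention.
#' @param n_points reference points per layer.
#' @param normalize divide by the maximum absolute value.
#' @return A `strain_curve` (ground truth).
#' @export
analytic_strain <- function(spec,
                            direction = c("circumferential", "radial"),
                            layer = "mid",
                            convention = c("green-lagrange", "engineering"),
                            n_points = 360, normalize = FALSE) {
  direction <- match.arg(direction)
  convention <- match.arg(convention)
  tracked <- exact_tracked_wall(spec, n_points)
  if (direction == "circumferential") {
    circumferential_strain(tracked, layer, convention, normalize)
  } else {
    radial_strain(tracked, layer, convention, normalize)
  }
}

# tracked_wall whose positions come from the exact motion map (mm units;
# strain is dimensionless so units cancel).
exact_tracked_wall <- function(spec, n_points = 360) {
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  radii <- c(endo = spec$r_endo, mid = (spec$r_endo + spec$r_epi) / 2,
             epi = spec$r_epi)
  Tn <- spec$n_frames
  pos <- array(NA_real_, c(3L, Tn, n_points, 2L),
               dimnames = list(c("endo", "mid", "epi"), NULL, NULL,
                               c("x", "y")))
  for (l in names(radii)) {
    ref <- cbind(spec$center[1L] + radii[[l]] * cos(th),
                 spec$center[2L] + radii[[l]] * sin(th))
    for (t in seq_len(Tn)) pos[l, t, , ] <- phantom_forward(spec, ref, t)
  }
  structure(list(positions = pos, spacing = 1,
                 frame_window = c(1L, Tn), frames = seq_len(Tn),
                 n_points = n_points, mid_method = "analytic",
                 modes = NULL),
            class = "tracked_wall")
}

#' Render tagged-MRI images of the phantom
#'
#' Produces a tagged frame sequence: a grid pattern (product of two
#' orthogonal sinusoids in the reference frame) advected by the phantom
#' motion, evaluated by pulling each pixel back through the inverse map,
#' restricted to the myocardium, plus optional Gaussian noise.
#'
#' @param phantom a `phantom_sequence` from [generate_phantom()].
#' @param tag_spacing tag period in mm (default from the spec; must exceed
#'   two pixels).
#' @param contrast peak intensity of the pattern.
#' @param noise_sd standard deviation of added Gaussian noise (seeded from
#'   the spec).
#' @param sharpness exponent applied to the sinusoid product; 1 gives pure
#'   sinusoids, larger values concentrate intensity near the tag-line
#'   crossings, mimicking the sharp saturation profile of SPAMM-style
#'   tagging (template matching needs this local structure).
#' @return A [tagged_sequence()].
#' @export
render_tagged <- function(phantom, tag_spacing = NULL, contrast = 1,
                          noise_sd = 0, sharpness = 4) {
  spec <- phantom$spec
  if (is.null(tag_spacing)) tag_spacing <- spec$tag_spacing
  if (tag_spacing <= 2 * spec$spacing) {
    stop("tag spacing must exceed two pixels")
  }
  n <- spec$size
  gx <- (rep(seq_len(n), each = n) - 1) * spec$spacing
  gy <- (rep(seq_len(n), times = n) - 1) * spec$spacing
  grid <- cbind(gx, gy)
  set.seed(spec$seed)
  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    q <- phantom_inverse(spec, grid, t)
    ux <- q[, 1L] - spec$center[1L]
    uy <- q[, 2L] - spec$center[2L]
    rq <- sqrt(ux^2 + uy^2)
    inside <- rq >= spec$r_endo & rq <= spec$r_epi
    val <- contrast * ((0.5 + 0.5 * cos(2 * pi * ux / tag_spacing)) *
                         (0.5 + 0.5 * cos(2 * pi * uy / tag_spacing)))^sharpness
    val[!inside] <- 0
    if (noise_sd > 0) val <- val + rnorm(length(val), 0, noise_sd)
    frames[[t]] <- matrix(val, n, n)
  }
  tagged_sequence(frames, spec$spacing)
}
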