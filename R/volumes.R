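#' Segmentation mask stack
#'
#' Container for per-slice, per-frame LV label masks: 0 = background,
#' 1 = cavity (blood pool), 2 = myocardium.  This is the main input of the
#' functional pipeline.
#'
#' @param masks a 4D integer array `[row, col, slice, frame]`, or a nested
#'   list `masks[[slice]][[frame]]` of matrices with identical dimensions.
#' @param pixel_spacing in-plane pixel size `(dx, dy)` in mm.
#' @param slice_spacing slice-to-slice distance (thickness + gap) in mm.
#' @return A `segmentation_stack` with fields `masks` (4D array),
#'   `pixel_spacing`, `pixel_area` (mm^2), `slice_spacing`, `n_slices`,
#'   `n_frames`.
#' @export
segmentation_stack <- function(masks, pixel_spacing = c(1, 1),
                               slice_spacing = 1) {
  if (is.list(masks)) {
    S <- length(masks)
    Tn <- length(masks[[1L]])
    d <- dim(masks[[1L]][[1L]])
    if (is.null(d)) stop("masks must be matrices")
    arr <- array(0L, c(d[1L], d[2L], S, Tn))
    for (s in seq_len(S)) {
      if (length(masks[[s]]) != Tn) stop("all slices need the same frame count")
      for (t in seq_len(Tn)) {
        m <- masks[[s]][[t]]
        if (!identical(dim(m), d)) stop("all masks must share dimensions")
        arr[, , s, t] <- m
      }
    }
    masks <- arr
  }
  stopifnot(length(dim(masks)) == 4L)
  bad <- setdiff(unique(as.integer(masks)), c(0L, 1L, 2L))
  if (length(bad)) {
    stop("masks contain labels outside {0, 1, 2}: ",
         paste(bad, collapse = ", "))
  }
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  structure(list(masks = masks, pixel_spacing = pixel_spacing,
                 pixel_area = prod(pixel_spacing),
                 slice_spacing = slice_spacing,
                 n_slices = dim(masks)[3L], n_frames = dim(masks)[4L]),
            class = "segmentation_stack")
}

#' @export
print.segmentation_stack <- function(x, ...) {
  cat(sprintf("<segmentation_stack> %d x %d px, %d slices x %d frames, pixel %.3g x %.3g mm, slice %.3g mm\n",
              dim(x$masks)[1L], dim(x$masks)[2L], x$n_slices, x$n_frames,
              x$pixel_spacing[1L], x$pixel_spacing[2L], x$slice_spacing))
  invisible(x)
}

#' LV cavity volume curve (Simpson-style slice summation)
#'
#' Computes the cavity volume per frame as the sum over slices of the
#' cavity pixel area times the slice spacing (the multi-slice discrete form
#' of Simpson's rule), then locates the end-diastolic frame `t_ED`
#' (maximum volume) and end-systolic frame `t_ES` (minimum volume); the
#' earliest frame wins ties.
#'
#' @param stack a [segmentation_stack()].
#' @return A `volume_curve` list with `volumes` (per frame, in microlitres
#'   = mm^3), `t_ED`, `t_ES`.
#' @export
lv_volume_curve <- function(stack) {
  Tn <- stack$n_frames
  vols <- vapply(seq_len(Tn), function(t) {
    sum(stack$masks[, , , t, drop = FALSE] == 1L) * stack$pixel_area *
      stack$slice_spacing
  }, numeric(1L))
  if (any(vols == 0)) {
    warning("empty cavity in all slices of at least one frame")
  }
  structure(list(volumes = vols, t_ED = which.max(vols),
                 t_ES = which.min(vols)),
            class = "volume_curve")
}

#' Global ventriculometrics
#'
#' End-diastolic and end-systolic volume (EDV, ESV), stroke volume
#' `SV = EDV - ESV`, ejection fraction `EF = SV / EDV * 100%`, and LV mass
#' `LVM = density * V_m` where the myocardial volume `V_m` is the
#' epicardial (cavity + myocardium) volume minus the cavity volume at end
#' diastole.  Mouse-scale volumes are in microlitres; LVM converts to
#' grams via mm^3 -> cm^3.  When a body mass or surface area is supplied,
#' the stroke volume index `SVI` and normalised LVM are added for
#' inter-subject comparison.
#'
#' @param stack a [segmentation_stack()].
#' @param curve optional precomputed [lv_volume_curve()].
#' @param body_mass body mass in g (normalises LVM).
#' @param surface_area body surface area (normalises SV to SVI and LVM).
#' @param density myocardial tissue density in g/cm^3 (1.05 by default).
#' @return A `global_indices` list: `EDV`, `ESV`, `SV` (uL), `EF` (%),
#'   `LVM` (g), `t_ED`, `t_ES`, plus `SVI`, `LVM_per_mass`, `LVM_per_area`
#'   when denominators are given.
#' @examples
#' m <- array(0L, c(20, 20, 1, 2))
#' m[6:15, 6:15, 1, 1] <- 1L; m[8:13, 8:13, 1, 2] <- 1L
#' m[4:17, 4:17, 1, 1][m[4:17, 4:17, 1, 1] == 0] <- 2L
#' m[6:15, 6:15, 1, 2][m[6:15, 6:15, 1, 2] == 0] <- 2L
#' st <- segmentation_stack(m, pixel_spacing = 0.1, slice_spacing = 1)
#' global_indices(st)
#' @export
global_indices <- function(stack, curve = NULL, body_mass = NULL,
                           surface_area = NULL, density = 1.05) {
  if (is.null(curve)) curve <- lv_volume_curve(stack)
  EDV <- curve$volumes[curve$t_ED]
  ESV <- curve$volumes[curve$t_ES]
  if (EDV == 0) stop("EDV is zero; ejection fraction undefined")
  SV <- EDV - ESV
  EF <- SV / EDV * 100
  ed <- stack$masks[, , , curve$t_ED, drop = FALSE]
  myo_vol <- sum(ed == 2L) * stack$pixel_area * stack$slice_spacing # mm^3
  if (myo_vol == 0) warning("no myocardium at end diastole; LVM is zero")
  LVM <- density * myo_vol / 1000 # g, via mm^3 -> cm^3
  out <- list(EDV = EDV, ESV = ESV, SV = SV, EF = EF, LVM = LVM,
              t_ED = curve$t_ED, t_ES = curve$t_ES, density = density)
  if (!is.null(surface_area)) {
    out$SVI <- SV / surface_area
    out$LVM_per_area <- LVM / surface_area
  }
  if (!is.null(body_mass)) out$LVM_per_mass <- LVM / body_mass
  structure(out, class = "global_indices")
}

#' @export
print.global_indices <- function(x, ...) {
  cat(sprintf("<global_indices> EDV %.1f uL, ESV %.1f uL, SV %.1f uL, EF %.1f%%, LVM %.4f g\n",
              x$EDV, x$ESV, x$SV, x$EF, x$LVM))
  invisible(x)
}
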