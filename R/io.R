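#' Read a segmentation mask stack
#'
#' Two on-disk layouts are supported: one NIfTI volume per slice with the
#' third dimension indexing frames (in-plane pixel size and slice spacing
#' taken from the header `pixdim` unless overridden), or an image series
#' with a manifest CSV of columns `slice,frame,path` pointing to PNG or
#' TIFF label images.
#'
#' @param path character vector of NIfTI paths (one per slice, basal
#'   first), or a single manifest CSV path.
#' @param pixel_spacing,slice_spacing optional overrides in mm.
#' @return A [segmentation_stack()].
#' @export
read_mask_stack <- function(path, pixel_spacing = NULL,
                            slice_spacing = NULL) {
  if (length(path) == 1L && grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(read_mask_manifest(path, pixel_spacing, slice_spacing))
  }
  slices <- list()
  for (s in seq_along(path)) {
    if (!file.exists(path[s])) stop("mask file not found: ", path[s])
    img <- RNifti::readNifti(path[s])
    pd <- RNifti::pixdim(img)
    if (is.null(pixel_spacing)) pixel_spacing <- pd[1:2]
    if (is.null(slice_spacing)) slice_spacing <- pd[3L]
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    # NIfTI stores x fastest; transpose to [row = y, col = x]
    slices[[s]] <- lapply(seq_len(dim(arr)[3L]),
                          function(t) t(arr[, , t]))
  }
  segmentation_stack(slices, pixel_spacing, slice_spacing)
}

read_mask_manifest <- function(path, pixel_spacing, slice_spacing) {
  man <- read.csv(path)
  if (!all(c("slice", "frame", "path") %in% names(man))) {
    stop("manifest must have columns slice,frame,path")
  }
  if (is.null(pixel_spacing)) pixel_spacing <- c(1, 1)
  if (is.null(slice_spacing)) slice_spacing <- 1
  base <- dirname(path)
  slices <- list()
  for (s in sort(unique(man$slice))) {
    ms <- man[man$slice == s, ]
    ms <- ms[order(ms$frame), ]
    slices[[s]] <- lapply(ms$path, function(f) {
      fp <- if (file.exists(f)) f else file.path(base, f)
      if (!file.exists(fp)) stop("mask file not found: ", f)
      read_label_image(fp)
    })
  }
  segmentation_stack(slices, pixel_spacing, slice_spacing)
}

read_label_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG masks requires the png package")
    }
    round(png::readPNG(path) * 255)
  } else {
    round(tiff::readTIFF(path) * 255)
  }
}

#' Write a segmentation mask stack
#'
#' Writes one NIfTI volume per slice (dimensions x, y, frame) with the
#' stack's spacings in the header.  Reading the files back with
#' [read_mask_stack()] reproduces the masks bit-exactly.
#'
#' @param stack a [segmentation_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_mask_stack <- function(stack, dir, prefix = "slice") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(stack$n_slices)
  for (s in seq_len(stack$n_slices)) {
    arr <- aperm(stack$masks[, , s, , drop = FALSE][, , 1L, ],
                 c(2L, 1L, 3L)) # [x, y, frame]
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(stack$pixel_spacing, stack$slice_spacing)
    paths[s] <- file.path(dir, sprintf("%s_%02d.nii.gz", prefix, s))
    RNifti::writeNifti(img, paths[s])
  }
  invisible(paths)
}

#' Write analysis reports
#'
#' Serialises the standard outputs of a run next to each other: global
#' indices as JSON, strain curves as CSV
#' (`slice,level,direction,layer,sector,frame,strain`), slope metrics as
#' CSV (`slice,level,direction,layer,sector,S1,S2,peak,peak_frame`), and
#' the resolved run configuration as YAML.
#'
#' @param dir output directory.
#' @param indices optional [global_indices()] result.
#' @param curves optional list of `strain_curve` objects.
#' @param metrics optional list of [slope_metrics()] results, parallel to
#'   `curves`.
#' @param config optional list; written as `config.yaml`.
#' @param slice,level annotations recycled over curves.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(dir, indices = NULL, curves = NULL,
                          metrics = NULL, config = NULL, slice = 1,
                          level = "mid-cavity") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(indices)) {
    p <- file.path(dir, "indices.json")
    keep <- intersect(c("EDV", "ESV", "SV", "EF", "LVM", "SVI",
                        "LVM_per_mass", "LVM_per_area"), names(indices))
    jsonlite::write_json(indices[keep], p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if (!is.null(curves)) {
    p <- file.path(dir, "strain.csv")
    rows <- lapply(curves, function(cv) {
      data.frame(slice = slice, level = level, direction = cv$direction,
                 layer = cv$layer, sector = cv$sector, frame = cv$frames,
                 strain = cv$values)
    })
    write.csv(do.call(rbind, rows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(metrics)) {
    p <- file.path(dir, "metrics.csv")
    rows <- lapply(seq_along(metrics), function(i) {
      cv <- curves[[i]]; m <- metrics[[i]]
      data.frame(slice = slice, level = level, direction = cv$direction,
                 layer = cv$layer, sector = cv$sector, S1 = m$S1,
                 S2 = m$S2, peak = m$peak, peak_frame = m$peak_frame)
    })
    write.csv(do.call(rbind, rows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(config)) {
    p <- file.path(dir, "config.yaml")
    yaml::write_yaml(config, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Assemble a run configuration
#'
#' Collects the tunable parameters of an analysis run into one list with
#' defaults, so the resolved configuration can be serialised beside the
#' outputs ([write_reports()]) and a run reproduced from its YAML.
#'
#' @param ... named overrides of the defaults.
#' @return A named list.
#' @export
run_config <- function(...) {
  cfg <- list(n_points = 60, frame_window = c(1, 17),
              convention = "green-lagrange", reference_angle = 0,
              supersample = 2, tol = 1e-6, max_iter = 20000,
              step = 0.25, alpha = 0.2, beta = 0.8, density = 1.05,
              seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}
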