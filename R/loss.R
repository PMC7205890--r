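#' Binary cross-entropy segmentation loss
#'
#' The pixel-summed BCE loss
#' `sum_i -(y_oi log(yhat_oi) + y_bi log(yhat_bi))`, where `yhat_b = 1 -
#' yhat_o` and `y_b = 1 - y_o`.  Probabilities are clipped to
#' `[eps, 1 - eps]` for log stability.  The conventional sum reduction is
#' the default; `reduction = "mean"` divides by the pixel count for
#' training-scale comparability.
#'
#' @param pred numeric array of object probabilities in `[0, 1]`.
#' @param truth binary array (same shape) of true object labels.
#' @param reduction `"sum"` or `"mean"`.
#' @param eps probability clipping constant.
#' @return Scalar loss (non-negative).
#' @export
bce_loss <- function(pred, truth, reduction = c("sum", "mean"),
                     eps = 1e-7) {
  reduction <- match.arg(reduction)
  check_prob_pair(pred, truth)
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  y <- as.numeric(truth)
  l <- -(y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "sum") sum(l) else mean(l)
}

#' Sensitivity-specificity segmentation loss
#'
#' The class-imbalance loss `L_ss = 2 - (Sensitivity + Specificity)` with
#' soft (probabilistic) counts: sensitivity is the probability mass placed
#' on true object pixels relative to all mass assigned to them, and
#' specificity likewise for background.  Unlike BCE, each class contributes
#' through its own ratio, so the loss does not reward ignoring the minority
#' class.  Range `[0, 2]`.
#'
#' @inheritParams bce_loss
#' @return Scalar loss in `[0, 2]`.
#' @examples
#' bce_loss(matrix(0.5), matrix(1)) # -log(0.5)
#' ss_loss(matrix(c(0.8, 0.4), 1), matrix(c(1, 0), 1)) # 0.6
#' @export
ss_loss <- function(pred, truth) {
  check_prob_pair(pred, truth)
  p <- as.numeric(pred)
  y <- as.numeric(truth)
  if (all(y == 1) || all(y == 0)) {
    stop("ss_loss undefined: ground truth has a single class ",
         "(division by zero in sensitivity or specificity)")
  }
  sens <- sum(p * y) / (sum(p * y) + sum((1 - p) * y))
  spec <- sum((1 - p) * (1 - y)) / (sum((1 - p) * (1 - y)) +
                                      sum(p * (1 - y)))
  2 - (sens + spec)
}

#' Combined class-imbalance segmentation loss
#'
#' `L = alpha * L_BCE + beta * L_ss` with `alpha + beta = 1`.  The default
#' weights `alpha = 0.2`, `beta = 0.8` down-weight BCE in favour of the
#' sensitivity-specificity term, countering the dominance of background
#' pixels in LV segmentation.
#'
#' @inheritParams bce_loss
#' @param alpha,beta non-negative weights summing to 1.
#' @return Scalar loss; 0 exactly when the prediction is perfect (up to
#'   the clipping constant).
#' @export
combined_loss <- function(pred, truth, alpha = 0.2, beta = 0.8,
                          eps = 1e-7) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-8) {
    stop("invalid weights: alpha and beta must be non-negative and sum to 1")
  }
  bce <- if (alpha > 0) bce_loss(pred, truth, eps = eps) else 0
  ss <- if (beta > 0) ss_loss(pred, truth) else 0
  alpha * bce + beta * ss
}

check_prob_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) ||
      length(pred) != length(truth)) {
    stop("prediction and ground truth must share shape")
  }
  if (any(pred < 0) || any(pred > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  if (!all(truth %in% c(0, 1))) stop("ground truth must be binary")
  invisible(TRUE)
}

#' Binarise a probability map and post-process
#'
#' Inference-time post-processing: Otsu thresholding of the probability
#' map, retention of the largest 4-connected component (removing
#' false-positive islands), and interior gap filling.  The chain is
#' deterministic and idempotent on its own output.
#'
#' @param pred numeric matrix of object probabilities.
#' @return Binary integer matrix (0/1).
#' @export
binarize_and_postprocess <- function(pred) {
  stopifnot(is.matrix(pred))
  if (max(pred) - min(pred) < 1e-12) {
    warning("constant probability map; threshold undefined, returning background")
    return(matrix(0L, nrow(pred), ncol(pred)))
  }
  thr <- EBImage::otsu(pred, range = range(pred))
  bin <- pred > thr
  lab <- EBImage::bwlabel(bin) # 4-connected components
  if (max(lab) >= 1L) {
    sizes <- tabulate(lab[lab > 0L])
    bin <- lab == which.max(sizes)
  }
  filled <- EBImage::fillHull(matrix(as.integer(bin), nrow(bin)))
  matrix(as.integer(filled > 0), nrow(bin))
}

#' Dice similarity coefficient
#'
#' Spatial overlap `2|A n B| / (|A| + |B|)` in percent.  Two empty masks
#' are defined to agree perfectly (DSC 100).
#'
#' @param pred,truth binary masks of equal shape.
#' @return DSC in percent.
#' @export
dsc <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  a <- pred > 0; b <- truth > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(100)
  200 * sum(a & b) / denom
}

#' Hausdorff distance between binary masks
#'
#' Maximum over both directions of the max-min distance between the masks'
#' boundary pixels (pixels with a 4-neighbour outside the mask), scaled to
#' mm.  Two empty masks have distance 0 by convention.
#'
#' @param pred,truth binary masks of equal shape.
#' @param spacing pixel size `(dx, dy)` in mm.
#' @return Hausdorff distance in mm.
#' @export
hausdorff <- function(pred, truth, spacing = c(1, 1)) {
  stopifnot(identical(dim(pred), dim(truth)))
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  a <- boundary_points(pred > 0)
  b <- boundary_points(truth > 0)
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  a <- sweep(a, 2L, spacing, `*`)
  b <- sweep(b, 2L, spacing, `*`)
  directed <- function(p, q) {
    max(vapply(seq_len(nrow(p)), function(i) {
      sqrt(min((q[, 1L] - p[i, 1L])^2 + (q[, 2L] - p[i, 2L])^2))
    }, numeric(1L)))
  }
  max(directed(a, b), directed(b, a))
}

# (x, y) coordinates of mask pixels having a 4-neighbour outside the mask
# (or lying on the image edge).
boundary_points <- function(m) {
  er <- m
  er[-1, ] <- er[-1, ] & m[-nrow(m), ]
  er[-nrow(m), ] <- er[-nrow(m), ] & m[-1, ]
  er[, -1] <- er[, -1] & m[, -ncol(m)]
  er[, -ncol(m)] <- er[, -ncol(m)] & m[, -1]
  er[1, ] <- FALSE; er[nrow(m), ] <- FALSE
  er[, 1] <- FALSE; er[, ncol(m)] <- FALSE
  w <- which(m & !er, arr.ind = TRUE)
  cbind(x = w[, 2L] - 1L, y = w[, 1L] - 1L)
}
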