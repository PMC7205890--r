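#' Agreement between two curves
#'
#' Quantifies the agreement between two equal-length curves (for example a
#' tracked strain curve against ground truth, or cine- against
#' tagged-derived strain) with the Pearson correlation coefficient, the
#' mean squared error, and Bland-Altman statistics: the bias (mean
#' difference `a - b`) and the 95% limits of agreement
#' `bias +/- 1.96 * SD` of the differences.
#'
#' With `normalize = TRUE` each curve is first divided by its own maximum
#' absolute value, so only shapes are compared; the MSE of the normalised
#' curves is additionally reported in percent (`mse_pct = 100 * MSE`), the
#' customary scale for normalised strain curves.
#'
#' @param a,b numeric vectors or `strain_curve` objects of equal length
#'   (n >= 3).
#' @param normalize compare max-normalised curves.
#' @return An `agreement_report` list: `corcoef`, `mse`, `mse_pct` (only
#'   when normalising), `bias`, `loa_low`, `loa_high`, `n`, and the
#'   `differences` vector for downstream testing.
#' @examples
#' curve_agreement(c(1, 2, 3, 4), c(1.1, 2.1, 3.1, 4.1))
#' @export
curve_agreement <- function(a, b, normalize = FALSE) {
  if (inherits(a, "strain_curve")) a <- a$values
  if (inherits(b, "strain_curve")) b <- b$values
  if (length(a) != length(b)) stop("curves must have equal length")
  if (length(a) < 3L) stop("agreement needs at least 3 points")
  if (sd(a) < 1e-300 || sd(b) < 1e-300) {
    stop("correlation undefined for a zero-variance curve")
  }
  cc <- cor(a, b)
  if (normalize) {
    a <- a / max(abs(a))
    b <- b / max(abs(b))
  }
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  out <- list(corcoef = cc, mse = mean(d^2), bias = bias,
              loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
              n = length(a), differences = d)
  if (normalize) out$mse_pct <- 100 * out$mse
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d, CorCoef = %.3f, MSE = %.4g%s, bias = %.4g [%.4g, %.4g]\n",
              x$n, x$corcoef, x$mse,
              if (!is.null(x$mse_pct)) sprintf(" (%.2f%% normalised)",
                                               x$mse_pct) else "",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
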