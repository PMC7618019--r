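#' Normalized root-mean-square error between two spectra
#'
#' `NRMSE = sqrt(mean((s - r)^2)) / sqrt(mean(r^2))`: RMS error normalized
#' by the RMS value of the reference. Scale-equivariant: multiplying both
#' spectra by a positive constant leaves it unchanged.
#'
#' @param model_values Modelled values `s`.
#' @param reference_values Reference values `r` (not identically zero).
#' @return Non-negative scalar.
#' @export
nrmse <- function(model_values, reference_values) {
  s <- as.numeric(model_values); r <- as.numeric(reference_values)
  if (length(s) != length(r) || length(r) < 1L) {
    drs_stop("nrmse requires two equal-length, non-empty vectors", "undefined_metric")
  }
  denom <- sqrt(mean(r^2))
  if (denom == 0) drs_stop("nrmse undefined for an all-zero reference", "undefined_metric")
  sqrt(mean((s - r)^2)) / denom
}

#' Absolute percentage error
#'
#' `APE = |e - g| / |g| * 100`, in percent. Undefined at a zero ground
#' truth; the error surfaces rather than being skipped.
#'
#' @param extracted Extracted (fitted) value(s) `e`.
#' @param ground_truth Ground-truth value(s) `g`, nonzero.
#' @return APE in percent (vectorized).
#' @export
ape <- function(extracted, ground_truth) {
  if (any(ground_truth == 0)) {
    drs_stop("APE undefined for zero ground truth", "undefined_metric")
  }
  abs(extracted - ground_truth) / abs(ground_truth) * 100
}

#' Mean-normalize a spectrum (relative mode)
#'
#' Divides the values by their mean over a wavelength window, producing a
#' relative spectrum with recorded normalization window. Scale-invariant:
#' any positive rescaling of the input yields the identical output.
#'
#' @param sp A [spectrum()].
#' @param window Length-2 nm range; defaults to 450--575 nm (the phantom
#'   convention).
#' @return A relative [spectrum()].
#' @export
mean_normalize <- function(sp, window = c(450, 575)) {
  stopifnot(inherits(sp, "spectrum"))
  idx <- window_indices(sp$grid, window)
  m <- mean(sp$values[idx])
  if (m == 0) drs_stop("cannot normalize by a zero window mean", "undefined_metric")
  spectrum(sp$grid, sp$values / m, mode = "relative",
           normalization_window = window)
}

#' Ordinary least-squares line with Pearson correlation
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, Pearson `r` and
#' the two-sided p-value under the no-correlation null.
#'
#' @param x,y Numeric vectors, length >= 3; `x` non-constant.
#' @return A list: `slope`, `intercept`, `r`, `p`, `n`.
#' @export
regression_summary <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    drs_stop("regression requires equal-length vectors, n >= 3", "degenerate_regression")
  }
  if (stats::sd(x) == 0) {
    drs_stop("regression undefined for constant x", "degenerate_regression")
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Median and interquartile range of APEs
#'
#' Summary convention used throughout the evaluation reports: medians and
#' IQRs use the standard linear-interpolation quantile definition.
#'
#' @param apes Numeric vector of APEs (percent).
#' @return Named vector `c(median, iqr)`.
#' @export
ape_summary <- function(apes) {
  c(median = stats::median(apes),
    iqr = unname(diff(stats::quantile(apes, c(0.25, 0.75), type = 7))))
}
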