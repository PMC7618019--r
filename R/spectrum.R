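#' Reflectance spectrum
#'
#' Wavelengths plus reflectance values. Quantitative spectra are fractions
#' of incident light (non-negative); relative spectra are mean-normalized
#' over a recorded wavelength window (mean 1 over that window).
#'
#' @param grid Wavelength grid (nm).
#' @param values Reflectance per wavelength.
#' @param mode `"quantitative"` or `"relative"`.
#' @param normalization_window Length-2 nm range; required when relative.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(grid, values, mode = c("quantitative", "relative"),
                     normalization_window = NULL) {
  assert_grid(grid)
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) != length(grid) || anyNA(values) || any(!is.finite(values))) {
    drs_stop("spectrum values must be finite and conform to the grid", "invalid_spectrum")
  }
  if (mode == "quantitative" && any(values < 0)) {
    drs_stop("quantitative reflectance must be non-negative", "invalid_spectrum")
  }
  if (mode == "relative") {
    if (is.null(normalization_window)) {
      drs_stop("relative spectra must record their normalization window",
               "invalid_spectrum")
    }
    idx <- window_indices(grid, normalization_window)
    if (abs(mean(values[idx]) - 1) > 1e-8) {
      drs_stop("relative spectra must have mean 1 over the normalization window",
               "invalid_spectrum")
    }
  }
  structure(list(grid = as.numeric(grid), values = values, mode = mode,
                 normalization_window = normalization_window),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d wavelengths %g-%g nm, values %.4g-%.4g\n",
              x$mode, length(x$grid), min(x$grid), max(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}
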