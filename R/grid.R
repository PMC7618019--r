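#' Wavelength grid
#'
#' Construct and validate the wavelength grid (nm) on which all spectra and
#' optical properties are evaluated. The package works in the visible range
#' where the analytical reflectance models are defined; grids must lie
#' within 400--700 nm, contain at least two points and be strictly
#' increasing.
#'
#' @param from,to Range endpoints in nm.
#' @param by Step in nm.
#' @param wavelengths Optionally, an explicit vector of wavelengths (nm);
#'   overrides `from`/`to`/`by`.
#' @return A numeric vector of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()         # 450-650 nm in 5 nm steps (41 points)
#' length(g)
#' @export
wavelength_grid <- function(from = 450, to = 650, by = 5, wavelengths = NULL) {
  w <- if (is.null(wavelengths)) seq(from, to, by = by) else as.numeric(wavelengths)
  assert_grid(w)
  structure(w, class = c("wavelength_grid", "numeric"))
}

#' Validate a wavelength grid
#'
#' @param w Numeric vector of wavelengths in nm.
#' @return `w`, invisibly, if valid; otherwise an `invalid_grid` error.
#' @export
assert_grid <- function(w) {
  if (!is.numeric(w) || length(w) < 2L) {
    drs_stop("wavelength grid must be numeric with length >= 2", "invalid_grid")
  }
  if (anyNA(w) || any(w < 400) || any(w > 700)) {
    drs_stop("wavelengths must lie within [400, 700] nm", "invalid_grid")
  }
  if (any(diff(w) <= 0)) {
    drs_stop("wavelengths must be strictly increasing", "invalid_grid")
  }
  invisible(w)
}

#' Indices of grid points inside a wavelength window
#' @param grid Wavelength grid (nm).
#' @param window Length-2 numeric, inclusive window in nm.
#' @return Integer indices of `grid` within `window`.
#' @export
window_indices <- function(grid, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  idx <- which(grid >= window[1] & grid <= window[2])
  if (length(idx) == 0L) {
    drs_stop("window does not intersect the wavelength grid", "empty_window")
  }
  idx
}
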