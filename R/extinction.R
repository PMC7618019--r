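#' Chromophore extinction table
#'
#' A tabulated molar (or effective) extinction coefficient curve. Lookups on
#' a wavelength grid use linear interpolation and refuse to extrapolate:
#' the table must cover the grid.
#'
#' @param name Chromophore identifier.
#' @param wavelengths Tabulation wavelengths, nm, strictly increasing.
#' @param epsilon Extinction coefficient at each wavelength (L mol-1 cm-1
#'   for the hemoglobins; effective units for phantom dyes). Non-negative.
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(name, wavelengths, epsilon) {
  wavelengths <- as.numeric(wavelengths)
  epsilon <- as.numeric(epsilon)
  if (length(wavelengths) != length(epsilon) || length(wavelengths) < 2L) {
    drs_stop("extinction table needs matching wavelength/epsilon vectors (length >= 2)",
             "invalid_extinction_table")
  }
  if (any(diff(wavelengths) <= 0)) {
    drs_stop("extinction table wavelengths must be strictly increasing",
             "invalid_extinction_table")
  }
  if (anyNA(epsilon) || any(epsilon < 0)) {
    drs_stop("extinction coefficients must be non-negative", "invalid_extinction_table")
  }
  structure(list(name = name, wavelengths = wavelengths, epsilon = epsilon),
            class = "extinction_table")
}

#' Interpolate an extinction table onto a wavelength grid
#'
#' @param table An [extinction_table()].
#' @param grid Wavelength grid (nm). Must be covered by the table; lookups
#'   never extrapolate.
#' @return Numeric vector of extinction coefficients on `grid`.
#' @export
extinction_at <- function(table, grid) {
  stopifnot(inherits(table, "extinction_table"))
  assert_grid(grid)
  if (min(grid) < min(table$wavelengths) || max(grid) > max(table$wavelengths)) {
    drs_stop(sprintf(
      "extinction table '%s' covers %g-%g nm; grid requires %g-%g nm (no extrapolation)",
      table$name, min(table$wavelengths), max(table$wavelengths),
      min(grid), max(grid)), "extinction_out_of_range")
  }
  stats::approx(table$wavelengths, table$epsilon, xout = as.numeric(grid),
                method = "linear", rule = 1)$y
}

#' Bundled hemoglobin extinction curves
#'
#' Loads the packaged oxy-/deoxyhemoglobin molar extinction tabulation
#' (compiled literature values, 445--665 nm at 5 nm).
#'
#' @return A list with `extinction_table` elements `hbo2` and `hb`.
#' @export
load_hemoglobin_extinction <- function() {
  path <- system.file("extdata", "hemoglobin_extinction.tsv",
                      package = "drspectra", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(
    hbo2 = extinction_table("HbO2", tab$wavelength_nm, tab$eps_hbo2),
    hb   = extinction_table("Hb",   tab$wavelength_nm, tab$eps_hb)
  )
}
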