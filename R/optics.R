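#' Tissue generative parameters
#'
#' The parameters that generate one tissue spectrum: oxygen saturation,
#' blood volume fraction, the Mie scattering power-law amplitude and
#' exponent, scattering anisotropy and refractive index.
#'
#' The constructor enforces physical sanity (fractions in \[0,1\], positive
#' amplitude, `0 <= g < 1`); the narrower study sampling bounds live in
#' [tissue_bounds()] and are enforced by the sampler and the inversion
#' routines, not here, so that limiting cases (e.g. `f_blood = 0`) remain
#' expressible.
#'
#' @param sto2 Oxygen saturation, fraction in \[0,1\].
#' @param f_blood Blood volume fraction of tissue, fraction.
#' @param a Mie amplitude: reduced scattering at 500 nm, cm-1. Positive.
#' @param b Mie power-law exponent, dimensionless.
#' @param g Scattering anisotropy (mean cosine), `0 <= g < 1`.
#' @param n Refractive index of the medium.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(sto2, f_blood, a, b, g = 0.8, n = 1.44) {
  if (!is.finite(sto2) || sto2 < 0 || sto2 > 1) {
    drs_stop("sto2 must lie in [0, 1]", "invalid_parameter")
  }
  if (!is.finite(f_blood) || f_blood < 0 || f_blood > 1) {
    drs_stop("f_blood must lie in [0, 1]", "invalid_parameter")
  }
  if (!is.finite(a) || a <= 0) drs_stop("Mie amplitude a must be positive", "invalid_parameter")
  if (!is.finite(b)) drs_stop("Mie exponent b must be finite", "invalid_parameter")
  if (!is.finite(g) || g < 0 || g >= 1) drs_stop("anisotropy g must satisfy 0 <= g < 1", "invalid_parameter")
  structure(list(sto2 = sto2, f_blood = f_blood, a = a, b = b, g = g, n = n),
            class = "tissue_params")
}

#' Study sampling bounds for tissue parameters
#'
#' The parameter box used both to sample random tissue spectra and to
#' constrain the tissue inverse fits: `a` in 8--70 cm-1, `b` in 0.1--3.3,
#' StO2 in 0--1, `f_blood` in 0.002--0.07, with anisotropy drawn from
#' 0.7--0.9.
#'
#' @return A named list of `c(lower, upper)` pairs.
#' @export
tissue_bounds <- function() {
  list(sto2 = c(0, 1), f_blood = c(0.002, 0.07),
       a = c(8, 70), b = c(0.1, 3.3), g = c(0.7, 0.9))
}

#' Blood absorption constants
#'
#' @param c_hbt Total hemoglobin concentration in whole blood, g L-1.
#' @param molar_mass Hemoglobin molar mass, g mol-1.
#' @param back_amp Background absorption power-law amplitude (cm-1 nm^exp).
#' @param back_exp Background absorption power-law exponent.
#' @return An object of class `blood_constants`.
#' @export
blood_constants <- function(c_hbt = 150, molar_mass = 64500,
                            back_amp = 7.84e8, back_exp = 3.255) {
  vals <- c(c_hbt = c_hbt, molar_mass = molar_mass,
            back_amp = back_amp, back_exp = back_exp)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    drs_stop("blood constants must all be strictly positive", "invalid_parameter")
  }
  structure(as.list(vals), class = "blood_constants")
}

#' Per-wavelength optical properties
#'
#' Container for absorption and reduced scattering coefficients on a
#' wavelength grid, both in cm-1 and elementwise non-negative.
#'
#' @param grid Wavelength grid (nm).
#' @param mu_a Absorption coefficient per wavelength, cm-1.
#' @param mu_s_reduced Reduced scattering coefficient per wavelength, cm-1.
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(grid, mu_a, mu_s_reduced) {
  assert_grid(grid)
  mu_a <- as.numeric(mu_a); mu_s_reduced <- as.numeric(mu_s_reduced)
  if (length(mu_a) != length(grid) || length(mu_s_reduced) != length(grid)) {
    drs_stop("mu_a and mu_s_reduced must conform to the grid length", "invalid_parameter")
  }
  if (anyNA(mu_a) || anyNA(mu_s_reduced) || any(mu_a < 0) || any(mu_s_reduced < 0)) {
    drs_stop("optical coefficients must be non-negative", "invalid_parameter")
  }
  structure(list(grid = as.numeric(grid), mu_a = mu_a, mu_s_reduced = mu_s_reduced),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> %d wavelengths, %g-%g nm\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  mu_a:  %.3g-%.3g cm-1 | mu_s': %.3g-%.3g cm-1\n",
              min(x$mu_a), max(x$mu_a), min(x$mu_s_reduced), max(x$mu_s_reduced)))
  invisible(x)
}

#' Mie power-law reduced scattering
#'
#' `mu_s'(lambda) = a * (lambda / 500)^(-b)` with `lambda` in nm and the
#' amplitude `a` equal to the reduced scattering coefficient at 500 nm.
#'
#' @param a Amplitude at 500 nm, cm-1, positive.
#' @param b Power-law exponent, dimensionless.
#' @param grid Wavelength grid (nm).
#' @return Reduced scattering per wavelength, cm-1.
#' @examples
#' reduced_scattering_mie(10, 1, wavelength_grid(450, 650, 50))
#' @export
reduced_scattering_mie <- function(a, b, grid) {
  if (!is.finite(a) || a <= 0) drs_stop("Mie amplitude a must be positive", "invalid_parameter")
  assert_grid(grid)
  a * (as.numeric(grid) / 500)^(-b)
}

#' Scattering coefficient from its reduced form
#'
#' Inverts the similarity relation `mu_s' = mu_s * (1 - g)`.
#'
#' @param mu_s_reduced Reduced scattering, cm-1.
#' @param g Anisotropy, `0 <= g < 1`.
#' @return `mu_s = mu_s' / (1 - g)`, cm-1.
#' @export
full_scattering_from_reduced <- function(mu_s_reduced, g) {
  if (!is.finite(g) || g < 0 || g >= 1) {
    drs_stop("anisotropy g must satisfy 0 <= g < 1", "invalid_parameter")
  }
  as.numeric(mu_s_reduced) / (1 - g)
}

#' Background (bloodless tissue) absorption
#'
#' Power-law background `mu_a,back(lambda) = amp * lambda^(-exp)` with
#' lambda in nm, result in cm-1.
#'
#' @param grid Wavelength grid (nm).
#' @param constants A [blood_constants()] object supplying `back_amp`
#'   and `back_exp`.
#' @return Background absorption per wavelength, cm-1.
#' @export
background_absorption <- function(grid, constants = blood_constants()) {
  assert_grid(grid)
  constants$back_amp * as.numeric(grid)^(-constants$back_exp)
}

#' Whole-blood absorption
#'
#' `mu_a,blood(lambda) = c_HbT ln(10) / M * [StO2 eps_HbO2 + (1 - StO2) eps_Hb]`
#' in cm-1, with the hemoglobin concentration `c_HbT` in g L-1 and molar
#' mass `M` in g mol-1.
#'
#' @param sto2 Oxygen saturation fraction in \[0,1\].
#' @param grid Wavelength grid (nm).
#' @param hb_tables List with `extinction_table` elements `hbo2` and `hb`
#'   (see [load_hemoglobin_extinction()]).
#' @param constants A [blood_constants()] object.
#' @return Blood absorption per wavelength, cm-1.
#' @export
blood_absorption <- function(sto2, grid, hb_tables = load_hemoglobin_extinction(),
                             constants = blood_constants()) {
  if (!is.finite(sto2) || sto2 < 0 || sto2 > 1) {
    drs_stop("sto2 must lie in [0, 1]", "invalid_parameter")
  }
  eps_hbo2 <- extinction_at(hb_tables$hbo2, grid)
  eps_hb <- extinction_at(hb_tables$hb, grid)
  scale <- constants$c_hbt * log(10) / constants$molar_mass
  scale * (sto2 * eps_hbo2 + (1 - sto2) * eps_hb)
}

#' Bulk tissue optical properties
#'
#' Combines the blood/background absorption mixture with the Mie scattering
#' power law:
#' `mu_a = f_blood * mu_a,blood + (1 - f_blood) * mu_a,back`,
#' `mu_s' = a (lambda/500)^(-b)`.
#'
#' @param params A [tissue_params()] object.
#' @param grid Wavelength grid (nm).
#' @param hb_tables Hemoglobin extinction tables.
#' @param constants A [blood_constants()] object.
#' @return An [optical_properties()] object.
#' @export
tissue_optical_properties <- function(params, grid,
                                      hb_tables = load_hemoglobin_extinction(),
                                      constants = blood_constants()) {
  stopifnot(inherits(params, "tissue_params"))
  mu_a <- params$f_blood * blood_absorption(params$sto2, grid, hb_tables, constants) +
    (1 - params$f_blood) * background_absorption(grid, constants)
  mu_sp <- reduced_scattering_mie(params$a, params$b, grid)
  optical_properties(grid, mu_a, mu_sp)
}

#' Phantom generative parameters
#'
#' Dye composition and intralipid content of one gelatin phantom. Dye
#' fractions must sum to one (a two-dye phantom has `frac_cv = 0`).
#'
#' @param c_tot Total dye scaled concentration, arbitrary units (the study
#'   uses 1, 10 and 20).
#' @param frac_ar1,frac_ar14,frac_cv Relative fractions of acid red 1,
#'   acid red 14 and crystal violet; each in \[0,1\], summing to 1.
#' @param intralipid_pct Intralipid volume concentration, % v/v.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(c_tot, frac_ar1, frac_ar14, frac_cv = 0,
                           intralipid_pct = 1) {
  fr <- c(frac_ar1, frac_ar14, frac_cv)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) ||
      abs(sum(fr) - 1) > 1e-9) {
    drs_stop("dye fractions must lie in [0,1] and sum to 1", "invalid_parameter")
  }
  if (!is.finite(c_tot) || c_tot <= 0) drs_stop("c_tot must be positive", "invalid_parameter")
  if (!is.finite(intralipid_pct) || intralipid_pct <= 0) {
    drs_stop("intralipid_pct must be positive", "invalid_parameter")
  }
  structure(list(c_tot = c_tot, frac_ar1 = frac_ar1, frac_ar14 = frac_ar14,
                 frac_cv = frac_cv, intralipid_pct = intralipid_pct),
            class = "phantom_params")
}

#' Phantom absorption from dye composition
#'
#' `mu_a = 8e-6 * c_tot * ln(10) * [AR1 eps_AR1,eff + AR14 eps_AR14,eff +
#' CV eps_CV,eff] + mu_a,background`. The tables are *effective* extinction
#' curves: the per-dye impact-equalisation factors are already applied.
#' The two-dye configuration is the special case `frac_cv = 0`.
#'
#' @param params A [phantom_params()] object.
#' @param dye_tables Named list of `extinction_table`s: `ar1`, `ar14`, `cv`.
#' @param background Per-wavelength background absorption (gelatin), cm-1,
#'   conforming to `grid`.
#' @param grid Wavelength grid (nm).
#' @return Absorption per wavelength, cm-1.
#' @export
phantom_absorption <- function(params, dye_tables, background, grid) {
  stopifnot(inherits(params, "phantom_params"))
  assert_grid(grid)
  background <- as.numeric(background)
  if (length(background) != length(grid)) {
    drs_stop("background must conform to the grid", "invalid_parameter")
  }
  eps <- params$frac_ar1 * extinction_at(dye_tables$ar1, grid) +
    params$frac_ar14 * extinction_at(dye_tables$ar14, grid) +
    params$frac_cv * extinction_at(dye_tables$cv, grid)
  8e-6 * params$c_tot * log(10) * eps + background
}

#' Intralipid scattering model
#'
#' Affine calibration of the Mie amplitude against intralipid concentration,
#' `a = slope * (I / I0) + intercept`, with a fixed median Mie exponent.
#'
#' @param slope cm-1 per unit `I/I0`.
#' @param intercept cm-1.
#' @param i0 Reference concentration, % v/v.
#' @param b_median Mie exponent used for all intralipid scattering curves.
#' @return An object of class `intralipid_model`.
#' @export
intralipid_model <- function(slope = 6.66, intercept = 2.55, i0 = 1,
                             b_median = 0.98) {
  if (!is.finite(slope) || slope <= 0) drs_stop("slope must be positive", "invalid_parameter")
  structure(list(slope = slope, intercept = intercept, i0 = i0,
                 b_median = b_median), class = "intralipid_model")
}

#' Reduced scattering of an intralipid phantom
#'
#' @param intralipid_pct Intralipid concentration, % v/v, positive.
#' @param model An [intralipid_model()].
#' @param grid Wavelength grid (nm).
#' @return Reduced scattering per wavelength, cm-1.
#' @examples
#' intralipid_scattering(3.5, intralipid_model(), wavelength_grid())[1]
#' @export
intralipid_scattering <- function(intralipid_pct, model = intralipid_model(),
                                  grid = wavelength_grid()) {
  if (!is.finite(intralipid_pct) || intralipid_pct <= 0) {
    drs_stop("intralipid_pct must be positive", "invalid_parameter")
  }
  a <- model$slope * (intralipid_pct / model$i0) + model$intercept
  reduced_scattering_mie(a, model$b_median, grid)
}

#' Optical properties of a gelatin phantom
#'
#' @inheritParams phantom_absorption
#' @param il_model An [intralipid_model()].
#' @return An [optical_properties()] object.
#' @export
phantom_optical_properties <- function(params, dye_tables, background, grid,
                                       il_model = intralipid_model()) {
  mu_a <- phantom_absorption(params, dye_tables, background, grid)
  mu_sp <- intralipid_scattering(params$intralipid_pct, il_model, grid)
  optical_properties(grid, mu_a, mu_sp)
}
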