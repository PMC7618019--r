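#' Sample a random tissue parameter dataset
#'
#' Independent uniform draws of the Mie amplitude and exponent, oxygen
#' saturation and blood fraction within the study bounds, plus anisotropy
#' uniform in 0.7--0.9. Reproducible: a pure function of `(n_spectra, seed)`.
#'
#' @param n_spectra Number of parameter sets.
#' @param n Refractive index recorded on each parameter set.
#' @param seed Integer seed.
#' @param bounds Bounds list as from [tissue_bounds()].
#' @return List of [tissue_params()].
#' @export
sample_tissue_dataset <- function(n_spectra, n = 1.44, seed = 1L,
                                  bounds = tissue_bounds()) {
  stopifnot(n_spectra >= 1)
  set.seed(seed)
  draw <- function(rng) stats::runif(n_spectra, rng[1], rng[2])
  a <- draw(bounds$a); b <- draw(bounds$b); sto2 <- draw(bounds$sto2)
  f_blood <- draw(bounds$f_blood); g <- draw(bounds$g)
  lapply(seq_len(n_spectra), function(i) {
    tissue_params(sto2 = sto2[i], f_blood = f_blood[i], a = a[i], b = b[i],
                  g = g[i], n = n)
  })
}

#' The phantom design matrix
#'
#' The 14 dye configurations of the study design (three total-concentration
#' levels 1/10/20 with two- and three-dye ratios) crossed with 5 intralipid
#' concentrations between 1 and 6 % v/v: 70 phantoms.
#'
#' @param intralipid_levels Intralipid concentrations, % v/v.
#' @return List of 70 [phantom_params()].
#' @export
phantom_design_matrix <- function(intralipid_levels = c(1, 2, 3.5, 5, 6)) {
  dye <- rbind(
    c(1,  50, 50,  0),
    c(1,  50, 25, 25),
    c(1,  25, 25, 50),
    c(10, 100,  0,  0),
    c(10, 75, 25,  0),
    c(10, 50, 50,  0),
    c(10, 25, 75,  0),
    c(10,  0, 100, 0),
    c(10, 25, 50, 25),
    c(10, 50, 25, 25),
    c(10, 25, 25, 50),
    c(20, 50, 50,  0),
    c(20, 50, 25, 25),
    c(20, 25, 25, 50))
  out <- list()
  for (i in seq_len(nrow(dye))) {
    for (il in intralipid_levels) {
      out[[length(out) + 1L]] <- phantom_params(
        c_tot = dye[i, 1], frac_ar1 = dye[i, 2] / 100,
        frac_ar14 = dye[i, 3] / 100, frac_cv = dye[i, 4] / 100,
        intralipid_pct = il)
    }
  }
  out
}

#' Synthetic dye fixture
#'
#' Parametric description of one synthetic dye extinction curve: a sum of
#' Gaussian peaks, displaced by a systematic gelatin peak shift and scaled
#' by the dye's impact-equalisation factor. Stands in for measured
#' effective extinction curves, which are only published as figures.
#'
#' @param name Dye identifier.
#' @param centers Peak centers, nm.
#' @param widths Peak standard deviations, nm. Positive.
#' @param amplitudes Peak amplitudes (pre-scale extinction units). Positive.
#' @param effective_scale Impact-equalisation factor (53 for AR14, 12 for
#'   CV, 1 for AR1).
#' @param gelatin_shift Systematic peak displacement in gelatin, nm.
#' @return An object of class `dye_fixture`.
#' @export
dye_fixture <- function(name, centers, widths, amplitudes,
                        effective_scale = 1, gelatin_shift = 0) {
  if (any(widths <= 0) || any(amplitudes <= 0) || effective_scale <= 0) {
    drs_stop("dye fixture widths, amplitudes and scale must be positive",
             "invalid_parameter")
  }
  stopifnot(length(centers) == length(widths),
            length(centers) == length(amplitudes))
  structure(list(name = name, centers = centers, widths = widths,
                 amplitudes = amplitudes, effective_scale = effective_scale,
                 gelatin_shift = gelatin_shift), class = "dye_fixture")
}

#' Default synthetic dye fixtures
#'
#' Defaults place the two red-dye maxima near 505 and 515 nm (about 45 nm
#' below the corresponding hemoglobin features, as for the real dyes) and
#' the crystal violet maximum near 590 nm, including the systematic +5 nm
#' gelatin shift. Amplitudes put the *effective* curves on the order of
#' 1e4--5e4 so that the design's concentration levels produce tissue-like
#' absorption; the AR14 and CV raw amplitudes are 53 and 12 times smaller
#' than their effective impact.
#'
#' @return Named list of three [dye_fixture()]s (`ar1`, `ar14`, `cv`).
#' @export
default_dye_fixtures <- function() {
  list(
    ar1 = dye_fixture("AR1", centers = c(500, 530), widths = c(16, 24),
                      amplitudes = c(3.6e4, 1.1e4),
                      effective_scale = 1, gelatin_shift = 5),
    ar14 = dye_fixture("AR14", centers = c(510, 478), widths = c(18, 16),
                       amplitudes = c(3.4e4 / 53, 1.0e4 / 53),
                       effective_scale = 53, gelatin_shift = 5),
    cv = dye_fixture("CV", centers = c(585, 545), widths = c(14, 18),
                     amplitudes = c(4.2e4 / 12, 0.8e4 / 12),
                     effective_scale = 12, gelatin_shift = 5)
  )
}

#' Evaluate synthetic dye extinction curves on a grid
#'
#' Each effective extinction curve is a sum of Gaussian peaks displaced by
#' the fixture's gelatin shift and multiplied by its effective scale.
#' An optional extra shift emulates medium-interaction peak displacement
#' (used by the measurement generator for crystal violet).
#'
#' @param fixtures Named list of [dye_fixture()]s.
#' @param grid Wavelength grid (nm).
#' @param extra_shift Named numeric of additional per-dye shifts, nm.
#' @return Named list of [extinction_table()]s on a tabulation covering
#'   `grid`.
#' @export
synth_dye_extinctions <- function(fixtures = default_dye_fixtures(),
                                  grid = wavelength_grid(),
                                  extra_shift = c()) {
  # tabulate on a 1 nm mesh extending past the grid so interpolation and
  # subsequent shifts stay in range
  wl <- seq(min(grid) - 25, max(grid) + 25, by = 1)
  lapply(fixtures, function(fx) {
    shift <- fx$gelatin_shift
    if (!is.null(extra_shift) && fx$name %in% names(extra_shift)) {
      shift <- shift + extra_shift[[fx$name]]
    }
    eps <- rep(0, length(wl))
    for (k in seq_along(fx$centers)) {
      eps <- eps + fx$amplitudes[k] *
        exp(-0.5 * ((wl - (fx$centers[k] + shift)) / fx$widths[k])^2)
    }
    extinction_table(fx$name, wl, fx$effective_scale * eps)
  })
}

#' Synthetic gelatin background absorption
#'
#' Weak, smooth, blue-rising background standing in for the measured
#' absorbance of pure gelatin (a fraction of a cm-1 across the visible
#' range).
#'
#' @param grid Wavelength grid (nm).
#' @return Background absorption per wavelength, cm-1.
#' @export
synth_gelatin_background <- function(grid = wavelength_grid()) {
  assert_grid(grid)
  0.2 * (as.numeric(grid) / 500)^(-2)
}

#' Measurement noise model for synthetic phantom spectra
#'
#' Emulates spectrophotometer-scale artefacts: multiplicative relative
#' noise, a constant baseline offset and a random systematic shift of the
#' crystal violet absorption peak (medium interaction).
#'
#' @param relative_noise_sd SD of the multiplicative noise, fraction.
#' @param baseline_offset Additive reflectance offset, fraction.
#' @param peak_shift_sd SD of the CV peak displacement, nm.
#' @param seed Integer seed.
#' @return An object of class `measurement_noise_model`.
#' @export
measurement_noise_model <- function(relative_noise_sd = 0.01,
                                    baseline_offset = 0.02,
                                    peak_shift_sd = 3, seed = 1L) {
  if (relative_noise_sd < 0 || baseline_offset < 0 || peak_shift_sd < 0) {
    drs_stop("noise magnitudes must be non-negative", "invalid_parameter")
  }
  structure(list(relative_noise_sd = relative_noise_sd,
                 baseline_offset = baseline_offset,
                 peak_shift_sd = peak_shift_sd, seed = as.integer(seed)),
            class = "measurement_noise_model")
}

#' Synthesize a pseudo-measured phantom spectrum
#'
#' Generates the clean reflectance of a phantom at refractive index 1.35
#' with the chosen reference engine (slab Monte Carlo, or the Yudovsky
#' forward model as a fast stand-in), then applies the measurement noise
#' model: a seeded wavelength shift of the crystal violet component,
#' multiplicative noise `1 + N(0, sd)` and the additive baseline offset,
#' clipped to \[0, 1\].
#'
#' @param params A [phantom_params()].
#' @param fixtures Dye fixtures (see [default_dye_fixtures()]).
#' @param il_model An [intralipid_model()].
#' @param noise A [measurement_noise_model()].
#' @param engine `"yudovsky"` or `"mc"`.
#' @param grid Wavelength grid (nm).
#' @param background Gelatin background absorption on `grid`.
#' @param hp Hyperparameters for the Yudovsky engine (defaults to the
#'   bundled refit values at n = 1.35).
#' @param mc_cfg [mc_config()] for the MC engine (index forced to 1.35 by
#'   default configuration).
#' @param entry_seed Integer distinguishing phantoms drawn from one noise
#'   model (mixed into the noise seed).
#' @return A quantitative [spectrum()].
#' @export
synth_phantom_measurement <- function(params,
                                      fixtures = default_dye_fixtures(),
                                      il_model = intralipid_model(),
                                      noise = measurement_noise_model(),
                                      engine = c("yudovsky", "mc"),
                                      grid = wavelength_grid(),
                                      background = synth_gelatin_background(grid),
                                      hp = reference_hyperparameters("yudovsky", 1.35, "refit"),
                                      mc_cfg = mc_config(n_inside = 1.35),
                                      entry_seed = 0L) {
  stopifnot(inherits(params, "phantom_params"))
  engine <- match.arg(engine)
  set.seed(noise$seed + 1000003L * as.integer(entry_seed))

  extra <- c()
  if (noise$peak_shift_sd > 0 && params$frac_cv > 0) {
    extra <- c(CV = stats::rnorm(1, 0, noise$peak_shift_sd))
  }
  tables <- synth_dye_extinctions(fixtures, grid, extra_shift = extra)
  props <- phantom_optical_properties(params, tables, background, grid, il_model)

  clean <- if (engine == "yudovsky") {
    yudovsky_forward(props, hp)
  } else {
    # one MC seed per phantom keeps spectra independent across the design
    cfg <- mc_cfg
    cfg$seed <- as.integer((mc_cfg$seed + 7919L * as.integer(entry_seed)) %% .Machine$integer.max)
    simulate_spectrum(props, g = 0.8, cfg)
  }

  v <- clean$values
  if (noise$relative_noise_sd > 0) {
    v <- v * (1 + stats::rnorm(length(v), 0, noise$relative_noise_sd))
  }
  v <- v + noise$baseline_offset
  v <- pmin(pmax(v, 0), 1)
  spectrum(grid, v, mode = "quantitative")
}
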