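#' Analytical model hyperparameters
#'
#' The ordered coefficient set of one analytical reflectance model at one
#' refractive index: 3 coefficients for the modified Beer-Lambert (`mbl`)
#' and Jacques (`jacques`) models, 6 for the simplified Yudovsky model
#' (`yudovsky`). The refractive index is not a model input; it is baked
#' into the coefficients by calibration.
#'
#' @param model_id One of `"mbl"`, `"jacques"`, `"yudovsky"`.
#' @param n Refractive index the coefficients were fitted at.
#' @param m Numeric coefficient vector of the required length.
#' @return An object of class `model_hyperparameters`.
#' @export
model_hyperparameters <- function(model_id = c("mbl", "jacques", "yudovsky"),
                                  n, m) {
  model_id <- match.arg(model_id)
  need <- model_coef_count(model_id)
  m <- as.numeric(m)
  if (length(m) != need || anyNA(m)) {
    drs_stop(sprintf("model '%s' requires %d finite coefficients", model_id, need),
             "invalid_hyperparameters")
  }
  structure(list(model_id = model_id, n = n, m = m),
            class = "model_hyperparameters")
}

#' Number of coefficients of each analytical model
#' @param model_id Model identifier.
#' @return Integer coefficient count.
#' @export
model_coef_count <- function(model_id) {
  switch(model_id, mbl = 3L, jacques = 3L, yudovsky = 6L,
         drs_stop("unknown model_id", "invalid_hyperparameters"))
}

# Bundled coefficient sets: "literature" are the original publications'
# values (Jacques' Adding-Doubling fit; Yudovsky's erratum coefficients,
# quoted for n = 1.44); "refit" are representative MC-calibrated values at
# each refractive index. The modified Beer-Lambert has no literature set.
.reference_hp <- list(
  yudovsky = list(
    literature = list("1.44" = c(-0.0247, 0.0137, 2.873, 1.64, 0.0116, 1.02)),
    refit = list(
      "1.33" = c(-0.0253, 0.0166, 2.873, 1.64, 0.0123, 1.02),
      "1.35" = c(-0.0257, 0.0159, 2.873, 1.64, 0.0124, 1.02),
      "1.44" = c(-0.0254, 0.0135, 2.873, 1.64, 0.0120, 1.02))
  ),
  jacques = list(
    literature = list("1.33" = c(6.3744, 0.35688, 3.4739),
                      "1.35" = c(6.3744, 0.35688, 3.4739),
                      "1.44" = c(6.3744, 0.35688, 3.4739)),
    refit = list(
      "1.33" = c(7.0188, 0.2464, 4.2241),
      "1.35" = c(7.1185, 0.2750, 4.2571),
      "1.44" = c(7.0438, 0.6902, 4.1449))
  ),
  mbl = list(
    literature = list(),
    refit = list(
      "1.33" = c(0.283, 0.009, 0.203),
      "1.35" = c(0.308, 0.008, 0.311),
      "1.44" = c(0.256, 0.014, 0.274))
  )
)

#' Bundled reference hyperparameters
#'
#' Returns the packaged coefficient sets for an analytical model:
#' `source = "literature"` gives the original publications' coefficients
#' (Yudovsky's erratum values at n = 1.44; Jacques' Adding-Doubling fit,
#' which is refractive-index independent), `source = "refit"` gives
#' representative values calibrated against slab Monte Carlo datasets at
#' n = 1.33, 1.35 or 1.44.
#'
#' @param model_id Model identifier.
#' @param n Refractive index (1.33, 1.35 or 1.44).
#' @param source `"refit"` or `"literature"`.
#' @return A [model_hyperparameters()] object.
#' @export
reference_hyperparameters <- function(model_id = c("mbl", "jacques", "yudovsky"),
                                      n = 1.44,
                                      source = c("refit", "literature")) {
  model_id <- match.arg(model_id)
  source <- match.arg(source)
  key <- sprintf("%.2f", n)
  m <- .reference_hp[[model_id]][[source]][[key]]
  if (is.null(m)) {
    drs_stop(sprintf("no bundled %s hyperparameters for model '%s' at n = %s",
                     source, model_id, key), "invalid_hyperparameters")
  }
  model_hyperparameters(model_id, n, m)
}

.check_props_hp <- function(props, hp, model_id) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(hp, "model_hyperparameters"))
  if (hp$model_id != model_id) {
    drs_stop(sprintf("hyperparameters are for model '%s', not '%s'",
                     hp$model_id, model_id), "invalid_hyperparameters")
  }
}

#' Modified Beer-Lambert forward model
#'
#' Hyperparameterised Beer-Lambert attenuation:
#' `A = M1 mu_a + M2 mu_s' + M3`, `R = exp(-A / 100)` (the divisor converts
#' the cm-1 coefficients to the mm-1 scale the original model assumes).
#' The classical unit-path-length form is the special case
#' `M1 = M2 = L, M3 = 0`.
#'
#' @param props An [optical_properties()] object.
#' @param hp Hyperparameters with `model_id = "mbl"`.
#' @return A quantitative [spectrum()].
#' @export
mbl_forward <- function(props, hp) {
  .check_props_hp(props, hp, "mbl")
  a_att <- hp$m[1] * props$mu_a + hp$m[2] * props$mu_s_reduced + hp$m[3]
  spectrum(props$grid, exp(-a_att / 100), mode = "quantitative")
}

#' Jacques (1999) forward model
#'
#' Single effective path-length model:
#' `N' = mu_s'/mu_a`, `delta = 1/sqrt(3 mu_a (mu_a + mu_s'))` (cm),
#' `A = M1 + M2 N'^(1/M3)`, `R = exp(-A delta mu_a)`. Undefined for
#' non-absorbing media (`mu_a = 0` raises an error).
#'
#' @inheritParams mbl_forward
#' @param hp Hyperparameters with `model_id = "jacques"`.
#' @return A quantitative [spectrum()].
#' @export
jacques_forward <- function(props, hp) {
  .check_props_hp(props, hp, "jacques")
  if (any(props$mu_a <= 0)) {
    drs_stop("Jacques model is undefined for mu_a = 0", "division_by_zero")
  }
  np <- props$mu_s_reduced / props$mu_a
  delta <- 1 / sqrt(3 * props$mu_a * (props$mu_a + props$mu_s_reduced))
  a_att <- hp$m[1] + hp$m[2] * exp(log(np) / hp$m[3])
  spectrum(props$grid, exp(-a_att * delta * props$mu_a), mode = "quantitative")
}

#' Simplified Yudovsky (2009) forward model
#'
#' Semi-empirical Kubelka-Munk-type model taking only the reduced albedo
#' `w' = mu_s'/(mu_a + mu_s')` as optical input:
#' `R = M1 + M2 exp(M3 w'^M4) + M5 (1.02 - w')^(-M6)`,
#' clipped below at zero.
#'
#' @inheritParams mbl_forward
#' @param hp Hyperparameters with `model_id = "yudovsky"`.
#' @return A quantitative [spectrum()].
#' @export
yudovsky_forward <- function(props, hp) {
  .check_props_hp(props, hp, "yudovsky")
  if (any(props$mu_a + props$mu_s_reduced <= 0)) {
    drs_stop("Yudovsky model requires mu_a + mu_s' > 0", "invalid_parameter")
  }
  w <- props$mu_s_reduced / (props$mu_a + props$mu_s_reduced)
  r <- yudovsky_albedo(w, hp$m)
  spectrum(props$grid, pmax(r, 0), mode = "quantitative")
}

#' Yudovsky reflectance as a function of reduced albedo
#'
#' The raw (unclipped) model curve; exposed for coefficient sanity checks.
#' @param w Reduced albedo values in \[0, 1\].
#' @param m Coefficient vector of length 6.
#' @return Reflectance values (may be slightly negative near `w = 0`).
#' @export
yudovsky_albedo <- function(w, m) {
  m[1] + m[2] * exp(m[3] * w^m[4]) + m[5] * (1.02 - w)^(-m[6])
}

#' Evaluate an analytical forward model by id
#'
#' @param model_id One of `"mbl"`, `"jacques"`, `"yudovsky"`.
#' @param props An [optical_properties()] object.
#' @param hp Matching [model_hyperparameters()].
#' @return A quantitative [spectrum()].
#' @export
forward_model <- function(model_id, props, hp) {
  switch(model_id,
         mbl = mbl_forward(props, hp),
         jacques = jacques_forward(props, hp),
         yudovsky = yudovsky_forward(props, hp),
         drs_stop("unknown model_id", "invalid_hyperparameters"))
}
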