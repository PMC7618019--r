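#' Bounded inverse fit result
#'
#' @description Returned by [invert_tissue()] and [invert_phantom()]:
#' `recovered` (a [tissue_params()] or [phantom_params()]), `residual_norm`,
#' `n_iterations`, `converged`, `mode`, `fit_window`, `residual_norms`
#' (one per start when multi-start is used). The optimizer is
#' bound-constrained, so recovered parameters respect their bounds exactly.
#' @name fit_result
NULL

.run_bounded_lm <- function(residual_fn, starts, lower, upper) {
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    minpack.lm::nls.lm(
      par = starts[i, ], fn = residual_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, gtol = 1e-10, maxiter = 300))
  })
  norms <- vapply(fits, function(f) sqrt(sum(f$fvec^2)), numeric(1))
  list(best = fits[[which.min(norms)]], norms = norms)
}

.make_starts <- function(lower, upper, n_starts, seed) {
  mid <- (lower + upper) / 2
  starts <- matrix(mid, nrow = 1)
  if (n_starts > 1) {
    k <- n_starts - 1L
    u <- if (requireNamespace("lhs", quietly = TRUE)) {
      set.seed(seed); lhs::randomLHS(k, length(lower))
    } else {
      set.seed(seed); matrix(stats::runif(k * length(lower)), nrow = k)
    }
    extra <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
    starts <- rbind(starts, extra)
  }
  starts
}

.prepare_reference <- function(sp, mode, norm_window) {
  if (mode == "relative") {
    if (sp$mode == "relative") sp else mean_normalize(sp, norm_window)
  } else {
    if (sp$mode == "relative") {
      drs_stop("cannot fit a relative spectrum in quantitative mode", "invalid_spectrum")
    }
    sp
  }
}

#' Recover tissue parameters from a reflectance spectrum
#'
#' Bounded nonlinear least squares over
#' `theta = (StO2, f_blood, a, b)`: minimizes
#' `sum_lambda (R_ref - M(mu_a(theta), mu_s'(theta)))^2` within the study
#' bounds, over the fit window. Anisotropy and refractive index are never
#' fitted: the analytical models consume only `mu_a` and `mu_s'`, with the
#' index baked into the hyperparameters. In relative mode both reference
#' and model spectra are mean-normalized over the normalization window
#' before residuals are taken.
#'
#' Initialization is at the midpoint of each bound interval; `n_starts > 1`
#' adds seeded Latin-hypercube starts and keeps the best-residual solution.
#'
#' @param sp Reference [spectrum()] (its grid must cover the fit window).
#' @param model_id One of `"mbl"`, `"jacques"`, `"yudovsky"`.
#' @param hp Matching [model_hyperparameters()] for the medium's index.
#' @param hb_tables Hemoglobin extinction tables.
#' @param constants A [blood_constants()] object.
#' @param bounds Named list of `c(lower, upper)` for `sto2`, `f_blood`,
#'   `a`, `b` (default [tissue_bounds()]).
#' @param mode `"quantitative"` or `"relative"`.
#' @param fit_window Length-2 nm range (default 450--600 nm).
#' @param norm_window Normalization window for relative mode; defaults to
#'   the fit window.
#' @param n_starts Number of optimizer starts.
#' @param seed Seed for the extra starts.
#' @return A `fit_result` list (see [fit_result]).
#' @export
invert_tissue <- function(sp, model_id, hp,
                          hb_tables = load_hemoglobin_extinction(),
                          constants = blood_constants(),
                          bounds = tissue_bounds(),
                          mode = c("quantitative", "relative"),
                          fit_window = c(450, 600), norm_window = NULL,
                          n_starts = 1L, seed = 1L) {
  stopifnot(inherits(sp, "spectrum"))
  mode <- match.arg(mode)
  if (is.null(norm_window)) norm_window <- fit_window
  idx <- window_indices(sp$grid, fit_window)
  ref_sp <- .prepare_reference(sp, mode, norm_window)
  ref <- ref_sp$values[idx]
  grid <- sp$grid

  # precompute per-wavelength absorption basis: mu_a is affine in sto2 and
  # f_blood, so cache the extinction lookups once
  eps_hbo2 <- extinction_at(hb_tables$hbo2, grid)
  eps_hb <- extinction_at(hb_tables$hb, grid)
  back <- background_absorption(grid, constants)
  hb_scale <- constants$c_hbt * log(10) / constants$molar_mass

  model_values <- function(theta) {
    mu_blood <- hb_scale * (theta[1] * eps_hbo2 + (1 - theta[1]) * eps_hb)
    mu_a <- theta[2] * mu_blood + (1 - theta[2]) * back
    mu_sp <- theta[3] * (grid / 500)^(-theta[4])
    props <- optical_properties(grid, mu_a, mu_sp)
    v <- forward_model(model_id, props, hp)$values
    if (mode == "relative") v / mean(v[window_indices(grid, norm_window)]) else v
  }
  residual_fn <- function(theta) model_values(theta)[idx] - ref

  lower <- c(bounds$sto2[1], bounds$f_blood[1], bounds$a[1], bounds$b[1])
  upper <- c(bounds$sto2[2], bounds$f_blood[2], bounds$a[2], bounds$b[2])
  starts <- .make_starts(lower, upper, n_starts, seed)
  res <- .run_bounded_lm(residual_fn, starts, lower, upper)
  fit <- res$best

  recovered <- tissue_params(sto2 = fit$par[1], f_blood = fit$par[2],
                             a = fit$par[3], b = fit$par[4],
                             g = 0.8, n = hp$n)
  structure(list(recovered = recovered,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 residual_norms = res$norms,
                 n_iterations = fit$niter,
                 converged = fit$info %in% 1:4,
                 mode = mode, fit_window = fit_window),
            class = "fit_result")
}

#' Recover phantom composition from a reflectance spectrum
#'
#' Bounded nonlinear least squares over the phantom generative parameters:
#' dye fraction(s), total dye concentration `c_tot` and intralipid
#' concentration `I`. Absorption comes from [phantom_absorption()],
#' scattering from [intralipid_scattering()]. The simplex constraint on
#' fractions is enforced by a stick-breaking parameterization of the free
#' fractions (2-dye: `AR1 = t1`, `AR14 = 1 - t1`; 3-dye: `AR1 = t1`,
#' `AR14 = (1 - t1) t2`, `CV` the remainder), each stick in \[0, 1\].
#'
#' @inheritParams invert_tissue
#' @param dye_tables Named list of effective dye extinction tables
#'   (`ar1`, `ar14`, `cv`).
#' @param background Per-wavelength gelatin background absorption, cm-1.
#' @param il_model An [intralipid_model()].
#' @param n_dyes 2 or 3.
#' @param bounds Named list with `c_tot` and `intralipid` ranges. Defaults
#'   cover the design levels with margin: `c_tot` 0.5--40, intralipid
#'   0.5--8 %.
#' @param fit_window Default 450--575 nm, the phantom convention.
#' @return A `fit_result` list (see [fit_result]).
#' @export
invert_phantom <- function(sp, model_id, hp, dye_tables, background,
                           il_model = intralipid_model(), n_dyes = 2,
                           bounds = list(c_tot = c(0.5, 40),
                                         intralipid = c(0.5, 8)),
                           mode = c("quantitative", "relative"),
                           fit_window = c(450, 575), norm_window = NULL,
                           n_starts = 1L, seed = 1L) {
  stopifnot(inherits(sp, "spectrum"), n_dyes %in% c(2, 3))
  mode <- match.arg(mode)
  if (is.null(norm_window)) norm_window <- fit_window
  idx <- window_indices(sp$grid, fit_window)
  ref_sp <- .prepare_reference(sp, mode, norm_window)
  ref <- ref_sp$values[idx]
  grid <- sp$grid

  eps <- list(ar1 = extinction_at(dye_tables$ar1, grid),
              ar14 = extinction_at(dye_tables$ar14, grid),
              cv = extinction_at(dye_tables$cv, grid))
  background <- as.numeric(background)

  theta_to_params <- function(theta) {
    if (n_dyes == 2) {
      list(ar1 = theta[1], ar14 = 1 - theta[1], cv = 0,
           c_tot = theta[2], il = theta[3])
    } else {
      ar1 <- theta[1]; ar14 <- (1 - theta[1]) * theta[2]
      list(ar1 = ar1, ar14 = ar14, cv = 1 - ar1 - ar14,
           c_tot = theta[3], il = theta[4])
    }
  }
  model_values <- function(theta) {
    p <- theta_to_params(theta)
    mu_a <- 8e-6 * p$c_tot * log(10) *
      (p$ar1 * eps$ar1 + p$ar14 * eps$ar14 + p$cv * eps$cv) + background
    mu_sp <- (il_model$slope * p$il / il_model$i0 + il_model$intercept) *
      (grid / 500)^(-il_model$b_median)
    props <- optical_properties(grid, mu_a, mu_sp)
    v <- forward_model(model_id, props, hp)$values
    if (mode == "relative") v / mean(v[window_indices(grid, norm_window)]) else v
  }
  residual_fn <- function(theta) model_values(theta)[idx] - ref

  n_sticks <- n_dyes - 1L
  lower <- c(rep(0, n_sticks), bounds$c_tot[1], bounds$intralipid[1])
  upper <- c(rep(1, n_sticks), bounds$c_tot[2], bounds$intralipid[2])
  starts <- .make_starts(lower, upper, n_starts, seed)
  res <- .run_bounded_lm(residual_fn, starts, lower, upper)
  fit <- res$best

  p <- theta_to_params(fit$par)
  recovered <- phantom_params(c_tot = p$c_tot, frac_ar1 = p$ar1,
                              frac_ar14 = p$ar14, frac_cv = p$cv,
                              intralipid_pct = p$il)
  structure(list(recovered = recovered,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 residual_norms = res$norms,
                 n_iterations = fit$niter,
                 converged = fit$info %in% 1:4,
                 mode = mode, fit_window = fit_window),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s fit, residual norm %.4g%s\n", x$mode,
              x$residual_norm, if (x$converged) "" else " [NOT CONVERGED]"))
  p <- x$recovered
  cat(" ", paste(sprintf("%s = %.4g", names(unclass(p)),
                         unlist(unclass(p))), collapse = ", "), "\n")
  invisible(x)
}
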