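#' Reference dataset of spectra with known ground truth
#'
#' Couples generative parameters, their optical properties and a reference
#' reflectance spectrum (Monte Carlo simulated or synthetic-measured) for
#' calibration and evaluation. All entries must share one wavelength grid.
#'
#' @param n Refractive index of the dataset medium.
#' @param entries List of entries, each a list with elements `params`,
#'   `props` ([optical_properties()]) and `spectrum` ([spectrum()]).
#' @param provenance `"mc"` or `"synthetic-measured"`.
#' @return An object of class `reference_dataset`.
#' @export
reference_dataset <- function(n, entries,
                              provenance = c("mc", "synthetic-measured")) {
  provenance <- match.arg(provenance)
  if (length(entries) < 2L) {
    drs_stop("a reference dataset needs at least 2 entries", "invalid_dataset")
  }
  grid0 <- entries[[1]]$props$grid
  for (e in entries) {
    if (!inherits(e$props, "optical_properties") || !inherits(e$spectrum, "spectrum")) {
      drs_stop("each entry needs optical_properties and a spectrum", "invalid_dataset")
    }
    if (!identical(e$props$grid, grid0) || !identical(e$spectrum$grid, grid0)) {
      drs_stop("all dataset entries must share one wavelength grid", "invalid_dataset")
    }
  }
  structure(list(n = n, entries = entries, provenance = provenance,
                 grid = grid0), class = "reference_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat(sprintf("<reference_dataset> %d entries, n = %s, provenance = %s\n",
              length(x$entries), format(x$n), x$provenance))
  invisible(x)
}

.default_init <- function(model_id, n) {
  if (model_id == "yudovsky") {
    reference_hyperparameters("yudovsky", 1.44, "literature")
  } else if (model_id == "jacques") {
    reference_hyperparameters("jacques", 1.44, "literature")
  } else {
    model_hyperparameters("mbl", n, c(1, 1, 1))
  }
}

#' Calibrate model hyperparameters against a reference dataset
#'
#' Fits a single coefficient set for one analytical model by minimizing the
#' stacked squared residuals between the model's forward spectra (computed
#' from each entry's ground-truth optical properties) and the reference
#' spectra, over all dataset entries, restricted to the fit window.
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm]), unbounded,
#' warm-started from the original publications' coefficients where they
#' exist (unit vector for the modified Beer-Lambert). Deterministic given
#' `(dataset, init)`.
#'
#' @param model_id One of `"mbl"`, `"jacques"`, `"yudovsky"`.
#' @param dataset A [reference_dataset()].
#' @param init Optional initial [model_hyperparameters()].
#' @param fit_window Length-2 nm range of wavelengths entering the residual
#'   (default 450--600 nm, the region the models are reliable in).
#' @param freeze_m6 Yudovsky only: hold the sixth coefficient at 1.02 (its
#'   value in every known calibration) and fit the remaining five.
#' @return An object of class `hyperparameter_fit`: `hp` (the fitted
#'   [model_hyperparameters()]), `residual_norm`, `converged`, `iterations`,
#'   `message`, and the dataset-mean NRMSE before (`pre_nrmse`) and after
#'   (`post_nrmse`) refitting. Non-convergence is flagged, not an error.
#' @export
fit_hyperparameters <- function(model_id, dataset, init = NULL,
                                fit_window = c(450, 600), freeze_m6 = FALSE) {
  stopifnot(inherits(dataset, "reference_dataset"))
  if (is.null(init)) init <- .default_init(model_id, dataset$n)
  stopifnot(inherits(init, "model_hyperparameters"), init$model_id == model_id)
  idx <- window_indices(dataset$grid, fit_window)
  ref <- unlist(lapply(dataset$entries, function(e) e$spectrum$values[idx]))

  make_hp <- function(par) {
    m <- if (freeze_m6 && model_id == "yudovsky") c(par, 1.02) else par
    model_hyperparameters(model_id, dataset$n, m)
  }
  residual_fn <- function(par) {
    hp <- make_hp(par)
    pred <- unlist(lapply(dataset$entries, function(e) {
      forward_model(model_id, e$props, hp)$values[idx]
    }))
    pred - ref
  }
  par0 <- if (freeze_m6 && model_id == "yudovsky") init$m[1:5] else init$m
  fit <- minpack.lm::nls.lm(
    par = par0, fn = residual_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, gtol = 1e-10, maxiter = 500))

  hp <- make_hp(fit$par)
  per_entry_nrmse <- function(h) {
    vapply(dataset$entries, function(e) {
      nrmse(forward_model(model_id, e$props, h)$values[idx],
            e$spectrum$values[idx])
    }, numeric(1))
  }
  structure(list(
    hp = hp,
    residual_norm = sqrt(sum(fit$fvec^2)),
    converged = fit$info %in% 1:4,
    iterations = fit$niter,
    message = fit$message,
    pre_nrmse = mean(per_entry_nrmse(init)),
    post_nrmse = mean(per_entry_nrmse(hp))
  ), class = "hyperparameter_fit")
}

#' @export
print.hyperparameter_fit <- function(x, ...) {
  cat(sprintf("<hyperparameter_fit> %s (n = %s): mean NRMSE %.4f -> %.4f%s\n",
              x$hp$model_id, format(x$hp$n), x$pre_nrmse, x$post_nrmse,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat("  m =", paste(signif(x$hp$m, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Forward-model evaluation against a reference dataset
#'
#' Per-spectrum NRMSE (mean and SD over entries) plus the pooled Pearson
#' correlation between all modelled and reference wavelength points in the
#' window.
#'
#' @param model_id Model identifier.
#' @param hp Hyperparameters to evaluate.
#' @param dataset A [reference_dataset()].
#' @param fit_window Length-2 nm evaluation window.
#' @return A list: `nrmse` (per-entry vector), `nrmse_mean`, `nrmse_sd`,
#'   `r`, `p` (pooled correlation).
#' @export
evaluate_forward <- function(model_id, hp, dataset, fit_window = c(450, 600)) {
  stopifnot(inherits(dataset, "reference_dataset"))
  idx <- window_indices(dataset$grid, fit_window)
  preds <- lapply(dataset$entries, function(e) {
    forward_model(model_id, e$props, hp)$values[idx]
  })
  refs <- lapply(dataset$entries, function(e) e$spectrum$values[idx])
  per <- mapply(function(s, r) nrmse(s, r), preds, refs)
  reg <- regression_summary(unlist(refs), unlist(preds))
  list(nrmse = per, nrmse_mean = mean(per), nrmse_sd = stats::sd(per),
       r = reg$r, p = reg$p)
}
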