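#' Build a Monte Carlo reference dataset from tissue parameter sets
#'
#' Simulates one reference spectrum per parameter set with the slab Monte
#' Carlo engine. Per-spectrum RNG streams derive deterministically from
#' `(seed, entry index)`, and per-wavelength substreams from the entry
#' stream, so the dataset is reproducible independent of execution order.
#'
#' @param params_list List of [tissue_params()] (sharing one refractive
#'   index).
#' @param grid Wavelength grid (nm).
#' @param n_photons Photon packets per wavelength.
#' @param thickness Slab thickness, cm.
#' @param seed Integer seed.
#' @param hb_tables,constants Chromophore model.
#' @return A [reference_dataset()] with provenance `"mc"`.
#' @export
mc_reference_dataset <- function(params_list, grid = wavelength_grid(),
                                 n_photons = 1e5, thickness = 3, seed = 1L,
                                 hb_tables = load_hemoglobin_extinction(),
                                 constants = blood_constants()) {
  n <- params_list[[1]]$n
  entries <- lapply(seq_along(params_list), function(j) {
    p <- params_list[[j]]
    props <- tissue_optical_properties(p, grid, hb_tables, constants)
    cfg <- mc_config(n_photons = n_photons, thickness = thickness,
                     n_inside = p$n, seed = as.integer(seed))
    # distinct per-entry substreams: offset the wavelength index block
    sp <- {
      mu_s <- full_scattering_from_reduced(props$mu_s_reduced, p$g)
      results <- lapply(seq_along(grid), function(i) {
        simulate_single(props$mu_a[i], mu_s[i], p$g, cfg,
                        wl_index = (j - 1L) * length(grid) + (i - 1L))
      })
      v <- vapply(results, `[[`, numeric(1), "r_diffuse")
      out <- spectrum(props$grid, v, mode = "quantitative")
      attr(out, "se") <- vapply(results, `[[`, numeric(1), "se_r_diffuse")
      out
    }
    list(params = p, props = props, spectrum = sp)
  })
  reference_dataset(n, entries, provenance = "mc")
}

#' Invert every spectrum of a tissue dataset and summarise recovery
#'
#' Runs [invert_tissue()] on each entry and reports recovered-vs-truth
#' values, the per-parameter median and IQR of absolute percentage errors,
#' and the Pearson correlation of recovered against truth.
#'
#' @param dataset A [reference_dataset()].
#' @param model_id Model identifier.
#' @param hp Hyperparameters for the dataset's refractive index.
#' @param fit_window,mode,n_starts,seed Passed to [invert_tissue()].
#' @param hb_tables,constants Chromophore model.
#' @return A list: `results` (data.frame of truth/recovered per entry and
#'   parameter), `summary` (data.frame with `parameter`, `median_ape`,
#'   `iqr_ape`, `r`, `p`).
#' @export
tissue_inversion_report <- function(dataset, model_id, hp,
                                    fit_window = c(450, 600),
                                    mode = "quantitative", n_starts = 1L,
                                    seed = 1L,
                                    hb_tables = load_hemoglobin_extinction(),
                                    constants = blood_constants()) {
  pars <- c("sto2", "f_blood", "a", "b")
  rows <- lapply(seq_along(dataset$entries), function(i) {
    e <- dataset$entries[[i]]
    fit <- invert_tissue(e$spectrum, model_id, hp, hb_tables, constants,
                         mode = mode, fit_window = fit_window,
                         n_starts = n_starts, seed = seed + i)
    data.frame(entry = i, parameter = pars,
               truth = unlist(e$params[pars]),
               recovered = unlist(fit$recovered[pars]),
               converged = fit$converged, row.names = NULL)
  })
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(pars, function(pn) {
    sub <- results[results$parameter == pn, ]
    s <- ape_summary(ape(sub$recovered, sub$truth))
    reg <- regression_summary(sub$truth, sub$recovered)
    data.frame(parameter = pn, median_ape = s[["median"]],
               iqr_ape = s[["iqr"]], r = reg$r, p = reg$p)
  }))
  list(results = results, summary = summary)
}

#' Configuration for the Monte Carlo model-comparison study
#'
#' @param refractive_indices Media to simulate.
#' @param n_spectra Spectra per refractive index.
#' @param n_photons Photon packets per wavelength.
#' @param thickness Slab thickness, cm.
#' @param grid Wavelength grid.
#' @param models Analytical models to evaluate.
#' @param fit_window Fit/evaluation window, nm.
#' @param include_literature Also evaluate the bundled literature
#'   hyperparameters (where they exist) before refitting.
#' @param seed Master seed; every random draw in the study derives from it.
#' @param out_dir Optional directory for persisted datasets and reports.
#' @return An `mc_study_config` list.
#' @export
mc_study_config <- function(refractive_indices = c(1.33, 1.35, 1.44),
                            n_spectra = 100, n_photons = 1e5, thickness = 3,
                            grid = wavelength_grid(),
                            models = c("yudovsky", "jacques", "mbl"),
                            fit_window = c(450, 600),
                            include_literature = TRUE,
                            seed = 1L, out_dir = NULL) {
  window_indices(grid, fit_window)  # validate early
  structure(list(refractive_indices = refractive_indices,
                 n_spectra = n_spectra, n_photons = n_photons,
                 thickness = thickness, grid = grid, models = models,
                 fit_window = fit_window,
                 include_literature = include_literature,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "mc_study_config")
}

#' Run the Monte Carlo model-comparison study
#'
#' End-to-end reproduction of the MC-facing comparison: sample tissue
#' parameters, simulate MC reference spectra, calibrate each analytical
#' model's hyperparameters, evaluate forward NRMSE and pooled correlation,
#' then solve the bounded inverse problem per spectrum and summarise
#' parameter recovery (median/IQR APE, correlation) --- per refractive
#' index. Fully deterministic given the configuration.
#'
#' @param config An [mc_study_config()].
#' @return An `mc_study` list with one element per refractive index, each
#'   holding `dataset`, `hyperparameters`, `forward` and `inversion`
#'   data.frames; plus `forward` / `inversion` tables pooled across
#'   indices.
#' @export
run_mc_study <- function(config = mc_study_config()) {
  hb <- load_hemoglobin_extinction()
  consts <- blood_constants()
  per_index <- list()
  for (k in seq_along(config$refractive_indices)) {
    n <- config$refractive_indices[k]
    params <- sample_tissue_dataset(config$n_spectra, n = n,
                                    seed = config$seed + 1000L * k)
    dataset <- mc_reference_dataset(params, config$grid,
                                    n_photons = config$n_photons,
                                    thickness = config$thickness,
                                    seed = config$seed + 1000L * k,
                                    hb_tables = hb, constants = consts)
    fwd_rows <- list(); inv_rows <- list(); hps <- list()
    for (m in config$models) {
      if (config$include_literature &&
          length(.reference_hp[[m]]$literature) > 0) {
        lit_n <- if (m == "yudovsky") 1.44 else n
        lit <- reference_hyperparameters(m, lit_n, "literature")
        ev <- evaluate_forward(m, lit, dataset, config$fit_window)
        fwd_rows[[paste0(m, "_lit")]] <- data.frame(
          model = m, n = n, source = "literature",
          nrmse_mean = ev$nrmse_mean, nrmse_sd = ev$nrmse_sd,
          r = ev$r, p = ev$p)
      }
      fit <- fit_hyperparameters(m, dataset, fit_window = config$fit_window)
      hps[[m]] <- fit
      ev <- evaluate_forward(m, fit$hp, dataset, config$fit_window)
      fwd_rows[[m]] <- data.frame(
        model = m, n = n, source = "refit",
        nrmse_mean = ev$nrmse_mean, nrmse_sd = ev$nrmse_sd,
        r = ev$r, p = ev$p)
      rep <- tissue_inversion_report(dataset, m, fit$hp,
                                     fit_window = config$fit_window,
                                     seed = config$seed + 1000L * k,
                                     hb_tables = hb, constants = consts)
      inv_rows[[m]] <- cbind(model = m, n = n, rep$summary)
    }
    per_index[[sprintf("%.2f", n)]] <- list(
      n = n, dataset = dataset, hyperparameters = hps,
      forward = do.call(rbind, c(fwd_rows, list(make.row.names = FALSE))),
      inversion = do.call(rbind, c(inv_rows, list(make.row.names = FALSE))))
  }
  out <- structure(list(
    per_index = per_index,
    forward = do.call(rbind, c(lapply(per_index, `[[`, "forward"),
                               list(make.row.names = FALSE))),
    inversion = do.call(rbind, c(lapply(per_index, `[[`, "inversion"),
                                 list(make.row.names = FALSE))),
    config = config), class = "mc_study")
  if (!is.null(config$out_dir)) .persist_mc_study(out, config$out_dir)
  out
}

.persist_mc_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$forward, file.path(out_dir, "forward_nrmse.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(study$inversion, file.path(out_dir, "inversion_ape.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (key in names(study$per_index)) {
    el <- study$per_index[[key]]
    write_reference_dataset(el$dataset,
                            file.path(out_dir, sprintf("mc_dataset_n%s", key)))
    write_hyperparameters(lapply(el$hyperparameters, `[[`, "hp"),
                          file.path(out_dir, sprintf("hyperparameters_n%s.tsv", key)))
  }
  cfg <- study$config
  writeLines(c(sprintf("seed: %d", cfg$seed),
               sprintf("n_spectra: %d", cfg$n_spectra),
               sprintf("n_photons: %g", cfg$n_photons),
               sprintf("thickness_cm: %g", cfg$thickness),
               sprintf("indices: %s", paste(cfg$refractive_indices, collapse = " ")),
               sprintf("fit_window_nm: %s", paste(cfg$fit_window, collapse = "-"))),
             file.path(out_dir, "run_config.txt"))
  invisible(out_dir)
}

#' Configuration for the synthetic phantom study
#'
#' @param models Analytical models to evaluate.
#' @param engine Reference engine for the pseudo-measured spectra
#'   (`"yudovsky"` or `"mc"`).
#' @param noise A [measurement_noise_model()].
#' @param grid Wavelength grid.
#' @param fit_window Fit/evaluation window, nm (phantom convention
#'   450--575).
#' @param n_photons MC engine photon count (when `engine = "mc"`).
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return A `phantom_study_config` list.
#' @export
phantom_study_config <- function(models = c("yudovsky", "jacques", "mbl"),
                                 engine = "yudovsky",
                                 noise = measurement_noise_model(),
                                 grid = wavelength_grid(),
                                 fit_window = c(450, 575),
                                 n_photons = 1e4,
                                 seed = 1L, out_dir = NULL) {
  structure(list(models = models, engine = engine, noise = noise,
                 grid = grid, fit_window = fit_window,
                 n_photons = n_photons, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "phantom_study_config")
}

#' Run the synthetic phantom study
#'
#' Builds the 70-phantom design (14 dye configurations x 5 intralipid
#' levels), synthesizes pseudo-measured spectra at refractive index 1.35
#' with the configured noise model, then evaluates each analytical model's
#' forward NRMSE (quantitative and relative, over the phantom window) and
#' solves the bounded inverse problem in both modes, summarising recovery
#' of the dye fractions, `c_tot` and the intralipid concentration.
#'
#' Entries whose ground-truth value of a parameter is zero are excluded
#' from that parameter's APE summary (the APE is undefined there); they
#' still enter the recovered-vs-truth correlation.
#'
#' @param config A [phantom_study_config()].
#' @return A `phantom_study` list: `designs`, `measured` (spectra),
#'   `forward` and `inversion` data.frames.
#' @export
run_phantom_study <- function(config = phantom_study_config()) {
  grid <- config$grid
  designs <- phantom_design_matrix()
  fixtures <- default_dye_fixtures()
  tables <- synth_dye_extinctions(fixtures, grid)   # unshifted analysis tables
  background <- synth_gelatin_background(grid)
  il <- intralipid_model()
  hp135 <- lapply(c(yudovsky = "yudovsky", jacques = "jacques", mbl = "mbl"),
                  function(m) reference_hyperparameters(m, 1.35, "refit"))
  noise <- config$noise
  noise$seed <- noise$seed + config$seed

  measured <- lapply(seq_along(designs), function(i) {
    synth_phantom_measurement(designs[[i]], fixtures, il, noise,
                              engine = config$engine, grid = grid,
                              background = background, hp = hp135$yudovsky,
                              mc_cfg = mc_config(n_photons = config$n_photons,
                                                 n_inside = 1.35,
                                                 seed = config$seed),
                              entry_seed = i)
  })
  props_true <- lapply(designs, function(p) {
    phantom_optical_properties(p, tables, background, grid, il)
  })

  fwd_rows <- list(); inv_rows <- list()
  par_names <- c("frac_ar1", "frac_ar14", "frac_cv", "c_tot", "intralipid_pct")
  for (m in config$models) {
    for (mode in c("quantitative", "relative")) {
      pred <- lapply(props_true, function(pp) forward_model(m, pp, hp135[[m]]))
      idx <- window_indices(grid, config$fit_window)
      pair <- lapply(seq_along(designs), function(i) {
        s <- pred[[i]]$values; r <- measured[[i]]$values
        if (mode == "relative") {
          s <- s / mean(s[window_indices(grid, config$fit_window)])
          r <- r / mean(r[window_indices(grid, config$fit_window)])
        }
        list(s = s[idx], r = r[idx])
      })
      per <- vapply(pair, function(x) nrmse(x$s, x$r), numeric(1))
      reg <- regression_summary(unlist(lapply(pair, `[[`, "r")),
                                unlist(lapply(pair, `[[`, "s")))
      fwd_rows[[paste(m, mode)]] <- data.frame(
        model = m, mode = mode, nrmse_mean = mean(per),
        nrmse_sd = stats::sd(per), r = reg$r, p = reg$p)

      fits <- lapply(seq_along(designs), function(i) {
        nd <- if (designs[[i]]$frac_cv > 0) 3 else 2
        invert_phantom(measured[[i]], m, hp135[[m]], tables, background, il,
                       n_dyes = nd, mode = mode,
                       fit_window = config$fit_window,
                       seed = config$seed + i)
      })
      res <- do.call(rbind, lapply(seq_along(designs), function(i) {
        d <- designs[[i]]; rec <- fits[[i]]$recovered
        data.frame(entry = i, n_dyes = if (d$frac_cv > 0) 3L else 2L,
                   parameter = par_names,
                   truth = unlist(d[par_names]),
                   recovered = unlist(rec[par_names]), row.names = NULL)
      }))
      for (pn in par_names) {
        sub <- res[res$parameter == pn, ]
        ok <- sub$truth != 0
        if (sum(ok) < 3) next
        s <- ape_summary(ape(sub$recovered[ok], sub$truth[ok]))
        reg <- regression_summary(sub$truth, sub$recovered)
        inv_rows[[paste(m, mode, pn)]] <- data.frame(
          model = m, mode = mode, parameter = pn,
          median_ape = s[["median"]], iqr_ape = s[["iqr"]],
          r = reg$r, p = reg$p, n_used = sum(ok))
      }
    }
  }
  out <- structure(list(designs = designs, measured = measured,
                        forward = do.call(rbind, c(fwd_rows, list(make.row.names = FALSE))),
                        inversion = do.call(rbind, c(inv_rows, list(make.row.names = FALSE))),
                        config = config), class = "phantom_study")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out$forward, file.path(config$out_dir, "phantom_forward.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(out$inversion, file.path(config$out_dir, "phantom_inversion.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
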