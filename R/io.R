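#' Write a spectrum to tabular text
#'
#' Plain-text format: `# key: value` header lines carrying the mode, the
#' normalization window (when relative) and units, followed by a
#' tab-separated table with columns `wavelength_nm` and `reflectance`.
#' Values round-trip at full double precision.
#'
#' @param sp A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode: %s", sp$mode), con)
  if (!is.null(sp$normalization_window)) {
    writeLines(sprintf("# normalization_window: %.17g %.17g",
                       sp$normalization_window[1], sp$normalization_window[2]), con)
  }
  writeLines("# units: wavelength_nm reflectance_fraction", con)
  writeLines("wavelength_nm\treflectance", con)
  writeLines(sprintf("%.17g\t%.17g", sp$grid, sp$values), con)
  invisible(path)
}

#' Read a spectrum from tabular text
#'
#' Inverse of [write_spectrum()]. Malformed files raise a `parse_error`
#' carrying the offending line number; a relative-mode header without a
#' normalization window raises a validation error.
#'
#' @param path File path.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines)
  meta <- list()
  for (i in header) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), header)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) {
    drs_stop(sprintf("%s: no data rows", path), "parse_error")
  }
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("wavelength_nm", "reflectance") %in% cols)) {
    drs_stop(sprintf("%s line %d: expected columns wavelength_nm, reflectance",
                     path, length(header) + 1L), "parse_error")
  }
  wl <- numeric(0); vals <- numeric(0)
  iw <- match("wavelength_nm", cols); iv <- match("reflectance", cols)
  for (k in seq_along(body[-1])) {
    fields <- strsplit(body[k + 1L], "\t", fixed = TRUE)[[1]]
    x <- suppressWarnings(as.numeric(fields))
    if (length(fields) < length(cols) || anyNA(x[c(iw, iv)])) {
      drs_stop(sprintf("%s line %d: malformed data row", path,
                       length(header) + 1L + k), "parse_error")
    }
    wl <- c(wl, x[iw]); vals <- c(vals, x[iv])
  }
  mode <- meta$mode %||% "quantitative"
  win <- NULL
  if (!is.null(meta$normalization_window)) {
    win <- as.numeric(strsplit(meta$normalization_window, "\\s+")[[1]])
  }
  if (mode == "relative" && is.null(win)) {
    drs_stop(sprintf("%s: relative spectrum without normalization window", path),
             "invalid_spectrum")
  }
  spectrum(wl, vals, mode = mode, normalization_window = win)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write hyperparameters to structured text
#'
#' One row per coefficient set: `model_id`, `n`, `source`, `m1..m6`
#' (unused coefficients empty).
#'
#' @param hps A [model_hyperparameters()] or list of them.
#' @param path Output path.
#' @param source Character tag(s) recorded per row (e.g. `"refit"`).
#' @return `path`, invisibly.
#' @export
write_hyperparameters <- function(hps, path, source = "refit") {
  if (inherits(hps, "model_hyperparameters")) hps <- list(hps)
  source <- rep_len(source, length(hps))
  rows <- lapply(seq_along(hps), function(i) {
    hp <- hps[[i]]
    m <- c(hp$m, rep(NA_real_, 6 - length(hp$m)))
    data.frame(model_id = hp$model_id, n = hp$n, source = source[i],
               t(stats::setNames(m, paste0("m", 1:6))))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read hyperparameters written by [write_hyperparameters()]
#'
#' @param path File path.
#' @return List of [model_hyperparameters()] (named `model_id@n`).
#' @export
read_hyperparameters <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    k <- model_coef_count(tab$model_id[i])
    model_hyperparameters(tab$model_id[i], tab$n[i],
                          as.numeric(tab[i, paste0("m", seq_len(k))]))
  })
  names(out) <- sprintf("%s@%s", tab$model_id, format(tab$n))
  out
}

#' Persist a reference dataset as a directory of spectra plus a manifest
#'
#' The manifest (`manifest.tsv`) stores one row of generative parameters
#' per entry plus the dataset index and provenance in `#` header lines;
#' each entry's spectrum goes to `spectrum_<i>.tsv`. Optical properties
#' are recomputed from the parameters on read, so a persisted dataset plus
#' the package fully determines every report computed from it.
#'
#' @param dataset A [reference_dataset()] of tissue entries.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "reference_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$entries), function(i) {
    p <- dataset$entries[[i]]$params
    write_spectrum(dataset$entries[[i]]$spectrum,
                   file.path(dir, sprintf("spectrum_%03d.tsv", i)))
    data.frame(entry = i, sto2 = p$sto2, f_blood = p$f_blood,
               a = p$a, b = p$b, g = p$g)
  })
  con <- file(file.path(dir, "manifest.tsv"), "w")
  on.exit(close(con))
  writeLines(sprintf("# n: %.17g", dataset$n), con)
  writeLines(sprintf("# provenance: %s", dataset$provenance), con)
  tab <- do.call(rbind, rows)
  writeLines(paste(names(tab), collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a reference dataset persisted by [write_reference_dataset()]
#'
#' @param dir Dataset directory.
#' @param hb_tables,constants Chromophore model used to recompute each
#'   entry's optical properties from its manifest parameters.
#' @return A [reference_dataset()].
#' @export
read_reference_dataset <- function(dir, hb_tables = load_hemoglobin_extinction(),
                                   constants = blood_constants()) {
  man_path <- file.path(dir, "manifest.tsv")
  lines <- readLines(man_path)
  meta <- list()
  for (l in grep("^#", lines, value = TRUE)) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  tab <- utils::read.table(man_path, header = TRUE, sep = "\t", comment.char = "#")
  n <- as.numeric(meta$n)
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    sp <- read_spectrum(file.path(dir, sprintf("spectrum_%03d.tsv", tab$entry[i])))
    p <- tissue_params(sto2 = tab$sto2[i], f_blood = tab$f_blood[i],
                       a = tab$a[i], b = tab$b[i], g = tab$g[i], n = n)
    props <- tissue_optical_properties(p, wavelength_grid(wavelengths = sp$grid),
                                       hb_tables, constants)
    list(params = p, props = props, spectrum = sp)
  })
  reference_dataset(n, entries, provenance = meta$provenance %||% "mc")
}
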