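# Shared fixtures. MC-backed reference datasets are expensive, so they are
# built lazily once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

# Desk-scale reference dataset used by the acceptance-level checks:
# 20 spectra, 1e4 photon packets per wavelength, full 450-650 nm grid.
acceptance_dataset <- function(n) {
  key <- sprintf("mc_%0.2f", n)
  if (is.null(.fixture_cache[[key]])) {
    seed <- if (n == 1.44) 101L else 102L
    params <- sample_tissue_dataset(20, n = n, seed = seed)
    .fixture_cache[[key]] <- mc_reference_dataset(
      params, wavelength_grid(), n_photons = 1e4, seed = seed)
  }
  .fixture_cache[[key]]
}

# A tiny synthetic (model-generated) dataset: fast, noiseless, useful for
# calibration self-consistency checks.
model_generated_dataset <- function(model_id, hp, params_list,
                                    grid = wavelength_grid()) {
  entries <- lapply(params_list, function(p) {
    props <- tissue_optical_properties(p, grid)
    list(params = p, props = props,
         spectrum = forward_model(model_id, props, hp))
  })
  reference_dataset(hp$n, entries, provenance = "mc")
}

# In-bounds tissue parameter sets away from the bound edges
interior_tissue_params <- function(n = 1.44) {
  list(
    tissue_params(0.65, 0.03, 30, 1.2, g = 0.8, n = n),
    tissue_params(0.30, 0.01, 50, 2.0, g = 0.8, n = n),
    tissue_params(0.85, 0.05, 15, 0.8, g = 0.8, n = n)
  )
}

phantom_test_tables <- function(grid = wavelength_grid()) {
  synth_dye_extinctions(default_dye_fixtures(), grid)
}
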