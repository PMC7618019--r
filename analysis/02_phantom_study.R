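#!/usr/bin/env Rscript
# Synthetic gelatin-phantom study.
#
# Builds the 70-phantom design (14 dye configurations x 5 intralipid
# levels), synthesizes pseudo-measured spectra at n = 1.35 with
# spectrophotometer-like artefacts (1% multiplicative noise, 0.02 baseline
# offset, 3 nm crystal-violet peak jitter), and evaluates each analytical
# model's forward fit and composition recovery in quantitative and relative
# (mean-normalized, 450-575 nm) modes. Tables land in results/phantom_study/.

library(drspectra)

cfg <- phantom_study_config(
  engine = "yudovsky",
  noise = measurement_noise_model(relative_noise_sd = 0.01,
                                  baseline_offset = 0.02,
                                  peak_shift_sd = 3),
  seed = 20240902, out_dir = "results/phantom_study")

study <- run_phantom_study(cfg)

cat("\nForward fidelity against pseudo-measured phantom spectra (450-575 nm):\n")
print(study$forward, digits = 3, row.names = FALSE)
cat("\nComposition recovery (median APE, %; zero-truth entries excluded):\n")
print(study$inversion, digits = 3, row.names = FALSE)
cat("\nNote the concentration/scattering degeneracy: c_tot and intralipid\n")
cat("recover far worse than the dye fractions under measurement artefacts.\n")
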