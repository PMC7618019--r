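test_that("noiseless tissue self-inversion recovers all parameters", {
  grid <- wavelength_grid()
  hb <- load_hemoglobin_extinction()
  truth <- tissue_params(0.62, 0.025, 28, 1.4, g = 0.8, n = 1.44)
  props <- tissue_optical_properties(truth, grid, hb)
  for (m in c("yudovsky", "jacques", "mbl")) {
    hp <- reference_hyperparameters(m, 1.44, "refit")
    sp <- forward_model(m, props, hp)
    fit <- invert_tissue(sp, m, hp, hb)
    rec <- fit$recovered
    for (pn in c("sto2", "f_blood", "a", "b")) {
      expect_lt(ape(rec[[pn]], truth[[pn]]), 0.1)
    }
    expect_true(fit$converged)
  }
})

test_that("recovered tissue parameters respect their bounds exactly", {
  grid <- wavelength_grid()
  hb <- load_hemoglobin_extinction()
  bounds <- tissue_bounds()
  # a spectrum whose generating parameters sit at/beyond bound edges forces
  # the optimizer against the box
  truth <- tissue_params(0.99, 0.068, 9, 3.2, g = 0.8, n = 1.44)
  props <- tissue_optical_properties(truth, grid, hb)
  hp <- reference_hyperparameters("yudovsky", 1.44, "refit")
  sp0 <- forward_model("yudovsky", props, hp)
  # corrupt towards the boundary to provoke clamping
  sp <- spectrum(grid, pmax(sp0$values * 0.97 - 0.01, 0))
  fit <- invert_tissue(sp, "yudovsky", hp, hb)
  rec <- fit$recovered
  expect_gte(rec$sto2, bounds$sto2[1]);    expect_lte(rec$sto2, bounds$sto2[2])
  expect_gte(rec$f_blood, bounds$f_blood[1]); expect_lte(rec$f_blood, bounds$f_blood[2])
  expect_gte(rec$a, bounds$a[1]);          expect_lte(rec$a, bounds$a[2])
  expect_gte(rec$b, bounds$b[1]);          expect_lte(rec$b, bounds$b[2])
})

test_that("noiseless phantom self-inversion is exact for 2- and 3-dye media", {
  grid <- wavelength_grid()
  tabs <- phantom_test_tables(grid)
  back <- synth_gelatin_background(grid)
  il <- intralipid_model()
  hp <- reference_hyperparameters("yudovsky", 1.35, "refit")

  for (truth in list(phantom_params(10, 0.75, 0.25, 0, intralipid_pct = 3.5),
                     phantom_params(10, 0.5, 0.25, 0.25, intralipid_pct = 2))) {
    props <- phantom_optical_properties(truth, tabs, back, grid, il)
    sp <- yudovsky_forward(props, hp)
    nd <- if (truth$frac_cv > 0) 3 else 2
    fit <- invert_phantom(sp, "yudovsky", hp, tabs, back, il, n_dyes = nd,
                          fit_window = c(450, 575))
    rec <- fit$recovered
    expect_lt(ape(rec$frac_ar1, truth$frac_ar1), 0.1)
    expect_lt(ape(rec$frac_ar14, truth$frac_ar14), 0.1)
    expect_lt(ape(rec$c_tot, truth$c_tot), 0.5)
    expect_lt(ape(rec$intralipid_pct, truth$intralipid_pct), 0.5)
    expect_equal(rec$frac_ar1 + rec$frac_ar14 + rec$frac_cv, 1, tolerance = 1e-12)
  }
})

test_that("relative mode resists baseline offsets better than quantitative mode", {
  grid <- wavelength_grid()
  tabs <- phantom_test_tables(grid)
  back <- synth_gelatin_background(grid)
  il <- intralipid_model()
  hp <- reference_hyperparameters("yudovsky", 1.35, "refit")
  truth <- phantom_params(10, 0.65, 0.35, 0, intralipid_pct = 3.5)
  props <- phantom_optical_properties(truth, tabs, back, grid, il)
  clean <- yudovsky_forward(props, hp)
  offset <- spectrum(grid, clean$values + 0.05)

  fq <- invert_phantom(offset, "yudovsky", hp, tabs, back, il, n_dyes = 2,
                       mode = "quantitative")
  fr <- invert_phantom(offset, "yudovsky", hp, tabs, back, il, n_dyes = 2,
                       mode = "relative")
  err_q <- ape(fq$recovered$frac_ar1, truth$frac_ar1)
  err_r <- ape(fr$recovered$frac_ar1, truth$frac_ar1)
  expect_lt(err_r, err_q)
  expect_lt(err_r, 5)
})

test_that("total dye concentration and intralipid trade off against each other", {
  # near-identical spectra arise from different (c_tot, I) pairs: pinning
  # c_tot 50% high still fits the spectrum closely with good fractions
  grid <- wavelength_grid()
  tabs <- phantom_test_tables(grid)
  back <- synth_gelatin_background(grid)
  il <- intralipid_model()
  hp <- reference_hyperparameters("yudovsky", 1.35, "refit")
  truth <- phantom_params(10, 0.5, 0.5, 0, intralipid_pct = 3.5)
  props <- phantom_optical_properties(truth, tabs, back, grid, il)
  sp <- yudovsky_forward(props, hp)

  pinned <- invert_phantom(sp, "yudovsky", hp, tabs, back, il, n_dyes = 2,
                           bounds = list(c_tot = c(15, 15.0001),
                                         intralipid = c(0.5, 8)))
  idx <- window_indices(grid, c(450, 575))
  resid_nrmse <- pinned$residual_norm / sqrt(sum(sp$values[idx]^2))
  expect_lt(resid_nrmse, 0.05)          # spectrum nearly reproduced...
  expect_gt(ape(pinned$recovered$c_tot, truth$c_tot), 40)  # ...at wrong c_tot
  expect_lt(ape(pinned$recovered$frac_ar1, truth$frac_ar1), 10)
})

test_that("multi-start inversion matches or beats the midpoint start", {
  grid <- wavelength_grid()
  hb <- load_hemoglobin_extinction()
  truth <- tissue_params(0.15, 0.06, 60, 0.4, g = 0.8, n = 1.44)
  props <- tissue_optical_properties(truth, grid, hb)
  hp <- reference_hyperparameters("jacques", 1.44, "refit")
  sp <- jacques_forward(props, hp)
  f1 <- invert_tissue(sp, "jacques", hp, hb, n_starts = 1L)
  f4 <- invert_tissue(sp, "jacques", hp, hb, n_starts = 4L, seed = 3)
  expect_lte(f4$residual_norm, f1$residual_norm + 1e-12)
  expect_length(f4$residual_norms, 4L)
})
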