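test_that("tissue sampling stays in bounds and is seed-deterministic", {
  ps <- sample_tissue_dataset(100, n = 1.44, seed = 5)
  expect_length(ps, 100L)
  b <- tissue_bounds()
  for (p in ps) {
    expect_true(p$a >= b$a[1] && p$a <= b$a[2])
    expect_true(p$b >= b$b[1] && p$b <= b$b[2])
    expect_true(p$sto2 >= 0 && p$sto2 <= 1)
    expect_true(p$f_blood >= b$f_blood[1] && p$f_blood <= b$f_blood[2])
    expect_true(p$g >= 0.7 && p$g <= 0.9)
    expect_equal(p$n, 1.44)
  }
  ps2 <- sample_tissue_dataset(100, n = 1.44, seed = 5)
  expect_identical(ps, ps2)
  expect_false(identical(ps, sample_tissue_dataset(100, n = 1.44, seed = 6)))
})

test_that("sampled StO2 marginal is uniform", {
  ps <- sample_tissue_dataset(1e4, n = 1.44, seed = 11)
  sto2 <- vapply(ps, `[[`, numeric(1), "sto2")
  ks <- suppressWarnings(stats::ks.test(sto2, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the phantom design matrix reproduces the study design", {
  d <- phantom_design_matrix()
  expect_length(d, 70L)                       # 14 dye configs x 5 intralipid
  ctots <- sort(unique(vapply(d, `[[`, numeric(1), "c_tot")))
  expect_equal(ctots, c(1, 10, 20))
  ils <- sort(unique(vapply(d, `[[`, numeric(1), "intralipid_pct")))
  expect_length(ils, 5L)
  expect_true(all(ils >= 1 & ils <= 6))
  for (p in d) {
    expect_equal(p$frac_ar1 + p$frac_ar14 + p$frac_cv, 1, tolerance = 1e-12)
  }
  n3 <- sum(vapply(d, function(p) p$frac_cv > 0, logical(1)))
  expect_equal(n3, 7L * 5L)                   # seven 3-dye configurations
})

test_that("synthetic dye curves respect their fixture geometry", {
  grid <- wavelength_grid()
  fx <- default_dye_fixtures()
  tabs <- synth_dye_extinctions(fx, grid)
  fine <- wavelength_grid(450, 650, 1)
  argmax <- function(tb) fine[which.max(extinction_at(tb, fine))]
  # distinct red-dye peaks (identifiability precondition), CV in the red
  expect_false(argmax(tabs$ar1) == argmax(tabs$ar14))
  expect_equal(argmax(tabs$ar1), 505, tolerance = 3)
  expect_equal(argmax(tabs$ar14), 515, tolerance = 3)
  expect_equal(argmax(tabs$cv), 590, tolerance = 3)

  # zero gelatin shift puts the argmax at the configured center
  fx0 <- fx
  fx0$ar1$gelatin_shift <- 0
  t0 <- synth_dye_extinctions(fx0, grid)
  expect_equal(argmax(t0$ar1), fx0$ar1$centers[1], tolerance = 2)

  # effective curves scale linearly with amplitude and scale factor
  fx2 <- fx
  fx2$cv$amplitudes <- fx$cv$amplitudes * 2
  t2 <- synth_dye_extinctions(fx2, grid)
  expect_equal(extinction_at(t2$cv, grid), 2 * extinction_at(tabs$cv, grid),
               tolerance = 1e-12)
})

test_that("noiseless synthesis is an exact forward-model passthrough", {
  grid <- wavelength_grid()
  p <- phantom_params(10, 0.5, 0.5, 0, intralipid_pct = 3.5)
  quiet <- measurement_noise_model(0, 0, 0, seed = 1)
  meas <- synth_phantom_measurement(p, noise = quiet, engine = "yudovsky",
                                    grid = grid)
  tabs <- phantom_test_tables(grid)
  props <- phantom_optical_properties(p, tabs, synth_gelatin_background(grid),
                                      grid)
  direct <- yudovsky_forward(props,
                             reference_hyperparameters("yudovsky", 1.35, "refit"))
  expect_identical(meas$values, direct$values)
})

test_that("baseline offsets hurt quantitative but not relative agreement", {
  grid <- wavelength_grid()
  p <- phantom_params(10, 0.5, 0.5, 0, intralipid_pct = 3.5)
  clean <- synth_phantom_measurement(p, noise = measurement_noise_model(0, 0, 0),
                                     engine = "yudovsky", grid = grid)
  shifted <- synth_phantom_measurement(p,
                                       noise = measurement_noise_model(0, 0.05, 0),
                                       engine = "yudovsky", grid = grid)
  idx <- window_indices(grid, c(450, 575))
  q <- nrmse(shifted$values[idx], clean$values[idx])
  r <- nrmse(mean_normalize(shifted, c(450, 575))$values[idx],
             mean_normalize(clean, c(450, 575))$values[idx])
  expect_gt(q, 0.05)
  expect_lt(r, q / 2)
})

test_that("a shifted CV peak markedly degrades dye-fraction recovery", {
  grid <- wavelength_grid()
  back <- synth_gelatin_background(grid)
  il <- intralipid_model()
  hp <- reference_hyperparameters("yudovsky", 1.35, "refit")
  truth <- phantom_params(10, 0.5, 0.25, 0.25, intralipid_pct = 3.5)

  # "measured" spectrum built with a CV curve displaced by 8 nm; analysis
  # then proceeds with the nominal (unshifted) tables
  shifted_tabs <- synth_dye_extinctions(default_dye_fixtures(), grid,
                                        extra_shift = c(CV = 8))
  meas <- yudovsky_forward(
    phantom_optical_properties(truth, shifted_tabs, back, grid, il), hp)
  nominal_tabs <- phantom_test_tables(grid)
  fit <- invert_phantom(meas, "yudovsky", hp, nominal_tabs, back, il,
                        n_dyes = 3, fit_window = c(450, 575))
  rec <- fit$recovered
  # noiseless self-inversion recovers fractions to < 0.1%; the modelling
  # mismatch in one chromophore degrades the others by orders of magnitude
  # while all stay bounded
  expect_gt(ape(rec$frac_ar1, truth$frac_ar1), 5)
  expect_lt(ape(rec$frac_cv, truth$frac_cv), 50)
})

test_that("generators are pure functions of their configuration and seed", {
  p <- phantom_params(10, 0.5, 0.25, 0.25, intralipid_pct = 2)
  nm <- measurement_noise_model(0.01, 0.02, 3, seed = 9)
  m1 <- synth_phantom_measurement(p, noise = nm, entry_seed = 4L)
  m2 <- synth_phantom_measurement(p, noise = nm, entry_seed = 4L)
  expect_identical(m1$values, m2$values)
  m3 <- synth_phantom_measurement(p, noise = nm, entry_seed = 5L)
  expect_false(identical(m1$values, m3$values))
  expect_true(all(m1$values >= 0 & m1$values <= 1))
})
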