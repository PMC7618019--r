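test_that("wavelength grid validation catches malformed grids", {
  expect_error(wavelength_grid(wavelengths = c(500)), class = "invalid_grid")
  expect_error(wavelength_grid(wavelengths = c(500, 480)), class = "invalid_grid")
  expect_error(wavelength_grid(wavelengths = c(390, 500)), class = "invalid_grid")
  expect_length(wavelength_grid(), 41L)
})

test_that("Mie power-law reduced scattering matches direct evaluation", {
  g500 <- wavelength_grid(wavelengths = c(450, 500, 650))
  # amplitude is the value at the 500 nm reference for any exponent
  for (b in c(0.1, 1, 3.3)) {
    expect_equal(reduced_scattering_mie(10, b, g500)[2], 10)
  }
  expect_equal(reduced_scattering_mie(40, 3.3, g500)[3], 40 * 1.3^(-3.3),
               tolerance = 1e-12)
  expect_equal(reduced_scattering_mie(40, 3.3, g500)[3], 16.83, tolerance = 1e-3)
  expect_error(reduced_scattering_mie(-1, 1, g500), class = "invalid_parameter")
})

test_that("reduced-to-full scattering conversion handles the anisotropy range", {
  expect_equal(full_scattering_from_reduced(10, 0), 10)
  expect_equal(full_scattering_from_reduced(10, 0.8), 50)
  expect_equal(full_scattering_from_reduced(16.83, 0.9), 168.3)
  expect_error(full_scattering_from_reduced(10, 1), class = "invalid_parameter")
})

test_that("background absorption follows the calibrated power law", {
  g <- wavelength_grid(wavelengths = c(450, 500, 650))
  mu <- background_absorption(g)
  expect_equal(mu[2], 7.84e8 / 500^3.255, tolerance = 1e-12)
  expect_equal(mu[2], 1.286, tolerance = 1e-3)
  expect_equal(mu[3], 0.547, tolerance = 1e-3)
  expect_lt(mu[3], mu[1])   # decreasing with wavelength
})

test_that("blood absorption applies the hemoglobin mixing rule", {
  g <- wavelength_grid(450, 650, 50)
  scale <- 150 * log(10) / 64500
  expect_equal(scale, 5.355e-3, tolerance = 1e-4)

  # flat synthetic tables isolate the scale factor
  flat <- extinction_table("flat", c(440, 660), c(1e4, 1e4))
  tabs <- list(hbo2 = flat, hb = flat)
  for (sto2 in c(0, 0.37, 1)) {
    expect_equal(blood_absorption(sto2, g, tabs), rep(scale * 1e4, length(g)),
                 tolerance = 1e-12)
  }
  expect_equal(blood_absorption(0.37, g, tabs)[1], 53.55, tolerance = 1e-3)

  # pure oxygenation: deoxy term vanishes
  hb <- load_hemoglobin_extinction()
  expect_equal(blood_absorption(1, g, hb),
               scale * extinction_at(hb$hbo2, g), tolerance = 1e-12)
  expect_error(blood_absorption(1.2, g, hb), class = "invalid_parameter")
})

test_that("hemoglobin lookups interpolate but never extrapolate", {
  hb <- load_hemoglobin_extinction()
  tab <- hb$hbo2
  # midpoint of two tabulated nodes is their average under linear interpolation
  w_mid <- (tab$wavelengths[5] + tab$wavelengths[6]) / 2
  got <- extinction_at(tab, wavelength_grid(wavelengths = c(w_mid, 600)))[1]
  expect_equal(got, (tab$epsilon[5] + tab$epsilon[6]) / 2)
  expect_error(
    extinction_at(extinction_table("x", c(500, 520), c(1, 2)),
                  wavelength_grid(450, 650, 5)),
    class = "extinction_out_of_range")
})

test_that("tissue absorption is an affine blend of blood and background", {
  g <- wavelength_grid()
  hb <- load_hemoglobin_extinction()
  mk <- function(f) tissue_optical_properties(
    tissue_params(0.6, f, 20, 1), g, hb)$mu_a
  lo <- mk(0); mid <- mk(0.5); hi <- mk(1)
  expect_equal(lo, background_absorption(g), tolerance = 1e-12)
  expect_equal(hi, blood_absorption(0.6, g, hb), tolerance = 1e-12)
  expect_equal(mid, (lo + hi) / 2, tolerance = 1e-12)

  # and affine in sto2 at fixed f_blood
  mk2 <- function(s) tissue_optical_properties(
    tissue_params(s, 0.03, 20, 1), g, hb)$mu_a
  expect_equal(mk2(0.5), (mk2(0) + mk2(1)) / 2, tolerance = 1e-12)
})

test_that("phantom absorption: three-dye formula degenerates to two-dye at CV = 0", {
  g <- wavelength_grid()
  tabs <- phantom_test_tables(g)
  back <- synth_gelatin_background(g)
  p3 <- phantom_params(10, 0.3, 0.7, 0, intralipid_pct = 2)
  mu3 <- phantom_absorption(p3, tabs, back, g)
  # direct two-dye evaluation
  mu2 <- 8e-6 * 10 * log(10) *
    (0.3 * extinction_at(tabs$ar1, g) + 0.7 * extinction_at(tabs$ar14, g)) + back
  expect_identical(mu3, mu2)

  # single-dye limit and the no-dye limit
  p1 <- phantom_params(10, 1, 0, 0, intralipid_pct = 2)
  expect_equal(phantom_absorption(p1, tabs, back, g),
               8e-6 * 10 * log(10) * extinction_at(tabs$ar1, g) + back)
  p0 <- phantom_params(1e-12, 0.5, 0.5, 0, intralipid_pct = 2)
  expect_equal(phantom_absorption(p0, tabs, back, g), back, tolerance = 1e-9)

  expect_error(phantom_params(10, 0.5, 0.6, 0.1), class = "invalid_parameter")
})

test_that("intralipid scattering follows the affine amplitude calibration", {
  g500 <- wavelength_grid(wavelengths = c(450, 500, 650))
  im <- intralipid_model()
  expect_equal(intralipid_scattering(1, im, g500)[2], 9.21, tolerance = 1e-12)
  expect_equal(intralipid_scattering(3.5, im, g500)[2], 25.86, tolerance = 1e-12)
  # affine-increasing in concentration
  a_at <- vapply(c(1, 2, 4, 6), function(i) intralipid_scattering(i, im, g500)[2],
                 numeric(1))
  expect_true(all(diff(a_at) > 0))
  expect_equal(diff(a_at, lag = 1)[1] / 1, 6.66, tolerance = 1e-12)
})

test_that("optical property containers reject nonconforming input", {
  g <- wavelength_grid(450, 650, 50)
  expect_error(optical_properties(g, c(1, 2), rep(1, length(g))),
               class = "invalid_parameter")
  expect_error(optical_properties(g, rep(-1, length(g)), rep(1, length(g))),
               class = "invalid_parameter")
})
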