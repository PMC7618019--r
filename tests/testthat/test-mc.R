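test_that("weight bookkeeping is exact for every tally", {
  cases <- list(c(1, 100, 0.8), c(10, 20, 0.7), c(0.5, 300, 0.9),
                c(30, 5, 0.75))
  for (cs in cases) {
    r <- simulate_single(cs[1], cs[2], cs[3],
                         mc_config(n_photons = 2000, n_inside = 1.44, seed = 11))
    total <- r$r_diffuse + r$r_specular + r$transmitted + r$absorbed
    expect_lt(abs(total - 1), 1e-9)
    expect_true(r$r_diffuse >= 0 && r$r_diffuse <= 1)
  }
})

test_that("specular deduction matches normal-incidence Fresnel", {
  r <- simulate_single(10, 1, 0.8, mc_config(n_photons = 10, n_inside = 1.44,
                                             n_outside = 1.0))
  expect_equal(r$r_specular, (0.44 / 2.44)^2, tolerance = 1e-12)
  expect_equal(r$r_specular, 0.0325, tolerance = 1e-3)
})

test_that("a pure absorber with matched indices returns nothing", {
  r <- simulate_single(50, 0, 0.8, mc_config(n_photons = 500, n_inside = 1.0,
                                             n_outside = 1.0, seed = 3))
  expect_equal(r$r_diffuse, 0)
  expect_equal(r$r_specular, 0)
  expect_equal(r$absorbed, 1, tolerance = 1e-12)
  expect_error(simulate_single(0, 0, 0.8), class = "degenerate_medium")
})

test_that("a non-absorbing scatterer in matched media returns nearly everything", {
  # mu_s' = 10 via g = 0.8, 3 cm slab: diffuse + transmitted account for all
  # weight (absorbed holds only the roulette balance) and reflectance dominates
  r <- simulate_single(0, 50, 0.8, mc_config(n_photons = 5000, n_inside = 1.0,
                                             n_outside = 1.0, seed = 5))
  expect_lt(abs(r$r_diffuse + r$transmitted - 1), 1e-3)
  expect_gt(r$r_diffuse, 0.9)
})

test_that("identical inputs and seed give bit-identical tallies", {
  a <- simulate_single(2, 80, 0.85, mc_config(n_photons = 3000, n_inside = 1.44,
                                              seed = 99), wl_index = 7L)
  b <- simulate_single(2, 80, 0.85, mc_config(n_photons = 3000, n_inside = 1.44,
                                              seed = 99), wl_index = 7L)
  expect_identical(a, b)
  # a different wavelength substream decorrelates the tallies
  c <- simulate_single(2, 80, 0.85, mc_config(n_photons = 3000, n_inside = 1.44,
                                              seed = 99), wl_index = 8L)
  expect_false(identical(a$r_diffuse, c$r_diffuse))
})

test_that("diffuse reflectance is monotone in absorption and scattering", {
  cfg <- function(s) mc_config(n_photons = 2e4, n_inside = 1.44, seed = s)
  # decreasing in mu_a at fixed mu_s
  rs <- lapply(seq_along(c(1, 5, 20)), function(i) {
    simulate_single(c(1, 5, 20)[i], 100, 0.8, cfg(21), wl_index = i)
  })
  for (i in 1:2) {
    gap <- rs[[i]]$r_diffuse - rs[[i + 1]]$r_diffuse
    se <- sqrt(rs[[i]]$se_r_diffuse^2 + rs[[i + 1]]$se_r_diffuse^2)
    expect_gt(gap, 3 * se)
  }
  # increasing in mu_s at fixed mu_a
  rs <- lapply(seq_along(c(25, 100, 400)), function(i) {
    simulate_single(5, c(25, 100, 400)[i], 0.8, cfg(22), wl_index = i)
  })
  for (i in 1:2) {
    gap <- rs[[i + 1]]$r_diffuse - rs[[i]]$r_diffuse
    se <- sqrt(rs[[i]]$se_r_diffuse^2 + rs[[i + 1]]$se_r_diffuse^2)
    expect_gt(gap, 3 * se)
  }
})

test_that("1 cm and 3 cm slabs agree at study-range optical properties", {
  # semi-infinite approximation: thickness-independent above 1 cm
  r1 <- simulate_single(1, 150, 0.8, mc_config(n_photons = 2e4, thickness = 1,
                                               n_inside = 1.44, seed = 31))
  r3 <- simulate_single(1, 150, 0.8, mc_config(n_photons = 2e4, thickness = 3,
                                               n_inside = 1.44, seed = 32))
  se <- sqrt(r1$se_r_diffuse^2 + r3$se_r_diffuse^2)
  expect_lt(abs(r1$r_diffuse - r3$r_diffuse), 3 * se)
})

test_that("kernel agrees with the independent naive oracle", {
  cases <- list(c(5, 50, 0.8), c(10, 100, 0.9), c(2, 30, 0.7),
                c(20, 20, 0.8), c(1, 60, 0.85))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    fast <- simulate_single(cs[1], cs[2], cs[3],
                            mc_config(n_photons = 2e4, n_inside = 1.44,
                                      seed = 40 + i))
    slow <- naive_mc_slab(cs[1], cs[2], cs[3], n_photons = 1500,
                          n_in = 1.44, seed = 50 + i)
    se <- sqrt(fast$se_r_diffuse^2 + slow$se^2)
    expect_lt(abs(fast$r_diffuse - slow$r_diffuse), 3 * se)
  }
})

test_that("spectrum simulation is deterministic and tracks absorption features", {
  grid <- wavelength_grid(450, 650, 25)
  p <- tissue_params(0.7, 0.03, 30, 1.2, g = 0.8, n = 1.44)
  props <- tissue_optical_properties(p, grid)
  cfg <- mc_config(n_photons = 3000, n_inside = 1.44, seed = 60)
  s1 <- simulate_spectrum(props, p$g, cfg)
  s2 <- simulate_spectrum(props, p$g, cfg)
  expect_identical(s1$values, s2$values)
  expect_s3_class(s1, "spectrum")
  # reflectance is highest where absorption is lowest (red end)
  expect_gt(s1$values[length(grid)], s1$values[1])
})
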