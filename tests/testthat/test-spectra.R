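test_that("resampling is exact on the identity and linear between samples", {
  sp <- hb_spectrum(c(400, 450, 500), c(0.2, 0.5, 0.3))
  expect_equal(resample_to_grid(sp, c(400, 450, 500))$absorbances,
               c(0.2, 0.5, 0.3))
  two <- hb_spectrum(c(400, 500), c(0.0, 1.0))
  expect_equal(resample_to_grid(two, c(400, 450, 500))$absorbances[2L], 0.5)
  expect_error(resample_to_grid(two, c(390, 450)),
               class = "hemolig_error_out_of_range")
})

test_that("resampling a dense Gaussian band to half density tracks the analytic curve", {
  dense <- seq(380, 500, by = 0.5)
  gauss <- function(x) 0.8 * exp(-((x - 420) / 10)^2 / 2)
  sp <- hb_spectrum(dense, gauss(dense))
  coarse <- seq(380, 500, by = 1)
  rs <- resample_to_grid(sp, coarse)
  expect_lt(max(abs(rs$absorbances - gauss(coarse))), 1e-3)
})

test_that("unmixing recovers pure species and exact mixtures", {
  basis <- make_reference_basis()
  pure <- hb_spectrum(basis$grid, basis$references$oxy$absorbances)
  comp <- unmix(pure, basis)
  expect_equal(unname(comp$coefficients),
               c(1, 0, 0), tolerance = 1e-8)
  expect_equal(comp$offset, 0, tolerance = 1e-8)
  expect_lt(comp$residual_rms, 1e-10)

  mix <- simulate_spectrum(basis, c(oxy = 0.6, deoxy = 0.3, met = 0.1),
                           offset = 0.02)
  comp <- unmix(mix, basis)
  expect_equal(unname(comp$coefficients), c(0.6, 0.3, 0.1), tolerance = 1e-8)
  expect_equal(comp$offset, 0.02, tolerance = 1e-8)
})

test_that("unmixing any exact linear combination returns the generating coefficients", {
  basis <- make_reference_basis()
  set.seed(11)
  for (i in 1:20) {
    co <- runif(3, 0, 1.2)
    off <- runif(1, -0.05, 0.05)
    mix <- simulate_spectrum(basis, setNames(co, c("oxy", "deoxy", "met")),
                             offset = off)
    comp <- unmix(mix, basis)
    expect_equal(unname(comp$coefficients), co, tolerance = 1e-8)
    expect_equal(comp$offset, off, tolerance = 1e-8)
  }
})

test_that("noisy unmixing agrees with the brute-force grid-search oracle", {
  # small instance: 3 references on a 30-wavelength grid
  grid <- seq(380, 496, by = 4)
  basis <- make_reference_basis(grid = grid)
  mix <- simulate_spectrum(basis, c(oxy = 0.6, deoxy = 0.3, met = 0.1),
                           offset = 0.02, noise_sd = 0.002, seed = 21)
  comp <- unmix(mix, basis)
  expect_lt(max(abs(comp$coefficients - c(0.6, 0.3, 0.1))), 0.011)
  oracle <- grid_search_unmix(mix, basis)
  # agreement to the resolution of the oracle's fine grid
  expect_lt(max(abs(comp$coefficients - oracle$coefficients)), 3e-3)
  expect_lt(abs(comp$offset - oracle$offset), 5e-3)
})

test_that("residual does not increase when a reference present in the signal is added", {
  basis3 <- make_reference_basis()
  refs2 <- basis3$references[c("oxy", "deoxy")]
  basis2 <- hb_reference_basis(refs2)
  mix <- simulate_spectrum(basis3, c(oxy = 0.5, deoxy = 0.3, met = 0.2),
                           noise_sd = 0.002, seed = 3)
  r2 <- unmix(mix, basis2)$residual_rms
  r3 <- unmix(mix, basis3)$residual_rms
  expect_lte(r3, r2 + 1e-12)
})

test_that("a rank-deficient basis is rejected", {
  grid <- seq(380, 500, by = 1)
  a <- exp(-((grid - 420) / 10)^2 / 2)
  basis <- hb_reference_basis(oxy = hb_spectrum(grid, a),
                              deoxy = hb_spectrum(grid, 2 * a),
                              met = hb_spectrum(grid, exp(-((grid - 405) / 12)^2 / 2)))
  mix <- hb_spectrum(grid, a + 0.01)
  expect_error(unmix(mix, basis), class = "hemolig_error_degenerate_basis")
})

test_that("saturation excludes met, is scale-invariant, and guards the zero case", {
  expect_equal(saturation(c(oxy = 1, deoxy = 0)), 1.0)
  expect_equal(saturation(c(oxy = 0.25, deoxy = 0.25)), 0.5)
  expect_equal(saturation(c(oxy = 0.6, deoxy = 0.3, met = 0.1)), 2 / 3,
               tolerance = 1e-12)
  for (s in c(0.1, 1, 7.3))
    expect_equal(saturation(c(oxy = 0.6 * s, deoxy = 0.3 * s, met = 0.1 * s)),
                 2 / 3, tolerance = 1e-12)
  expect_error(saturation(c(oxy = 0, deoxy = 0, met = 1)),
               class = "hemolig_error_undefined_saturation")
})
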