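test_that("the default reference basis is well conditioned and distinguishable", {
  basis <- make_reference_basis()
  expect_setequal(names(basis$references), c("oxy", "deoxy", "met"))
  expect_equal(range(basis$grid), c(380, 500))
  B <- vapply(basis$references, function(s) s$absorbances,
              numeric(length(basis$grid)))
  expect_lt(kappa(B, exact = TRUE), 100)
  expect_error(make_reference_basis(list(
    oxy = data.frame(center_nm = 415, width_nm = 11, height_AU = 1))),
    class = "hemolig_error_input")
  expect_error(make_reference_basis(list(
    oxy = data.frame(center_nm = 415, width_nm = 11, height_AU = 1),
    deoxy = data.frame(center_nm = 415, width_nm = 11, height_AU = 1))),
    class = "hemolig_error_degenerate_basis")
})

test_that("all generators are bit-reproducible under a fixed seed", {
  expect_identical(make_reference_basis(), make_reference_basis())
  a <- simulate_equilibrium_curve(14.4, 1.8, noise_sd = 0.01, seed = 5)
  b <- simulate_equilibrium_curve(14.4, 1.8, noise_sd = 0.01, seed = 5)
  expect_identical(a, b)
  c_ <- simulate_equilibrium_curve(14.4, 1.8, noise_sd = 0.01, seed = 6)
  expect_false(identical(a$saturation, c_$saturation))
  expect_identical(a$pO2_torr, c_$pO2_torr)  # noise is on Y only
  m <- hb1_model()
  t1 <- simulate_photolysis_trace(m, 1, noise_sd = 0.01, seed = 5)
  t2 <- simulate_photolysis_trace(m, 1, noise_sd = 0.01, seed = 5)
  expect_identical(t1, t2)
  d1 <- simulate_displacement(13.1, 1, noise_sd = 1e-3, seed = 5)
  d2 <- simulate_displacement(13.1, 1, noise_sd = 1e-3, seed = 5)
  expect_identical(d1, d2)
  x1 <- simulate_autoxidation(2.2e-4, noise_sd = 0.01, seed = 5)
  x2 <- simulate_autoxidation(2.2e-4, noise_sd = 0.01, seed = 5)
  expect_identical(x1, x2)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_equilibrium_curve(5.5, 1.2, noise_sd = 0.01, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("noiseless equilibrium points lie exactly on the generating Hill curve", {
  cur <- simulate_equilibrium_curve(14.4, 1.8, steps = 5, noise_sd = 0)
  expect_equal(cur$saturation, hill_model(cur$pO2_torr, 14.4, 1.8),
               tolerance = 1e-12)
  expect_equal(range(cur$saturation), c(0.2, 0.8), tolerance = 1e-12)
  expect_error(simulate_equilibrium_curve(14.4, 1.8, noise_sd = 0.3),
               class = "hemolig_error_input")
})

test_that("CO pressure shifts the bimolecular phase tenfold in time", {
  sc <- hb_scenario("Hb1", 25, 7.4)
  m1 <- sc$rebinding
  co01 <- co_concentration(0.1, 298.15)
  m01 <- m1; m01$k_R <- sc$kon_R * co01; m01$k_T <- sc$kon_T * co01
  tr1 <- simulate_photolysis_trace(m1, 1, noise_sd = 0)
  tr01 <- simulate_photolysis_trace(m01, 0.1, noise_sd = 0)
  # time for the bimolecular phase to reach half of its amplitude
  half_time <- function(tr) {
    bim <- tr$N[which.min(abs(tr$times_s - 1e-5))]
    t <- tr$times_s[tr$times_s > 1e-5]
    t[which.min(abs(tr$N[tr$times_s > 1e-5] - bim / 2))]
  }
  expect_equal(half_time(tr01) / half_time(tr1), 10, tolerance = 0.2)
})

test_that("displacement and autoxidation generators have the stated closed forms", {
  tr <- simulate_displacement(13.1, duration_s = 1, noise_sd = 0)
  expect_equal(tr$A420, 0.45 + 0.10 * exp(-13.1 * tr$times_s),
               tolerance = 1e-15)
  ser <- simulate_autoxidation(1.3e-4, duration_min = 1200, noise_sd = 0)
  expect_equal(ser$met_fraction[length(ser$met_fraction)],
               1 - exp(-1.3e-4 * 1200), tolerance = 1e-12)
  expect_equal(1 - exp(-1.3e-4 * 1200), 0.144, tolerance = 5e-3)
  expect_error(simulate_displacement(13.1, duration_s = -1),
               class = "hemolig_error_input")
  expect_error(simulate_autoxidation(-1), class = "hemolig_error_domain")
})

test_that("autoxidation can be rendered as raw spectra and re-analysed", {
  out <- simulate_autoxidation(3.9e-4, duration_min = 600, step_min = 60,
                               as_spectra = TRUE, spectra_noise_sd = 0.002,
                               seed = 8)
  basis <- make_reference_basis()
  ser <- met_fraction_timecourse(out$spectra, out$time_min,
                                 basis$references$oxy, basis$references$met)
  expect_lt(max(abs(ser$met_fraction - out$series$met_fraction)), 0.02)
})

test_that("scenario presets reproduce the published parameter sets verbatim", {
  pre <- hb_presets()
  expect_equal(nrow(pre$equilibrium), 24L)
  expect_equal(nrow(pre$kinetics), 24L)
  sc <- hb_scenario("Hb1", 25, 7.4, atp = FALSE)
  expect_equal(sc$P50, 5.5); expect_equal(sc$nH, 1.2)
  expect_equal(sc$kon_R, 9.4e5); expect_equal(sc$kon_T, 2.4e5)
  expect_equal(unname(rt_fractions(sc$rebinding)), c(84, 16))
  expect_equal(sc$koff_s, 13.1); expect_equal(sc$kox_per_min, 2.2e-4)
  sc2 <- hb_scenario("Hb3", 25, 7.4, atp = TRUE)
  expect_equal(sc2$P50, 13.3); expect_equal(sc2$kon_R / sc2$kon_T, 7.3 / 2.8)
  expect_error(hb_scenario("Hb1", 25, 9.9), class = "hemolig_error_input")
})

test_that("generator-fitter round trips at zero noise recover every preset", {
  pre <- hb_presets()
  sub <- pre$equilibrium[pre$equilibrium$temperature_C == 25 &
                           pre$equilibrium$pH == 7.4, ]
  for (i in seq_len(nrow(sub))) {
    cur <- simulate_equilibrium_curve(sub$P50_torr[i], sub$nH[i],
                                      noise_sd = 0)
    f <- fit_hill(cur)
    expect_equal(f$P50, sub$P50_torr[i], tolerance = 1e-6)
    expect_equal(f$nH, sub$nH[i], tolerance = 1e-6)
  }
})
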