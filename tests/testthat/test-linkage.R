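test_that("the Bohr coefficient is the slope of log P50 against pH", {
  expect_equal(bohr_coefficient(10, 7.4, 10, 6.7), 0)
  expect_equal(bohr_coefficient(10, 7.4, 20, 6.7), -0.430, tolerance = 5e-4)
  # two-point value from the published 25 C stripped P50 pair; the printed
  # coefficient (-0.2) differs, presumably computed from unrounded P50s
  expect_equal(round(bohr_coefficient(5.5, 7.4, 8.9, 6.7), 3), -0.299)
  expect_error(bohr_coefficient(10, 7.4, 20, 7.4),
               class = "hemolig_error_division")
})

test_that("least-squares Bohr slope matches the two-point value and extends to more points", {
  g <- hb_p50_grid(temperature_C = c(25, 25), pH = c(7.4, 6.7),
                   atp = FALSE, P50_torr = c(5.5, 8.9))
  expect_equal(bohr_coefficient_fit(g, 298.15, FALSE),
               bohr_coefficient(5.5, 7.4, 8.9, 6.7))
  # three points on an exact Bohr line with slope -0.45
  pH <- c(6.6, 7.0, 7.6)
  g3 <- hb_p50_grid(temperature_C = 25, pH = pH, atp = TRUE,
                    P50_torr = 10^(1.2 - 0.45 * (pH - 7)))
  expect_equal(bohr_coefficient_fit(g3, 298.15, TRUE), -0.45,
               tolerance = 1e-10)
})

test_that("proton release per tetramer is four times the Bohr magnitude", {
  expect_equal(protons_per_tetramer(-0.2), 0.8)
  expect_equal(protons_per_tetramer(-0.5), 2.0)
  expect_equal(protons_per_tetramer(0), 0)
})

test_that("van't Hoff enthalpy reproduces hand-computed values and the trivial limit", {
  dh <- vant_hoff_dH(5.5, 298.15, 2.9, 288.15)
  expect_equal(dh$dH_corrected, -7.9, tolerance = 0.05)
  flat <- vant_hoff_dH(10, 298.15, 10, 288.15)
  expect_equal(flat$dH_raw, 0)
  expect_equal(flat$dH_corrected, 3.0)
  expect_equal(vant_hoff_dH(13.3, 298.15, 10.6, 288.15)$dH_corrected,
               -0.9, tolerance = 0.05)
  expect_error(vant_hoff_dH(5, 298.15, 3, 298.15),
               class = "hemolig_error_division")
})

test_that("the van't Hoff expression is symmetric under exchanging the two state points", {
  a <- vant_hoff_dH(5.5, 298.15, 2.9, 288.15)
  b <- vant_hoff_dH(2.9, 288.15, 5.5, 298.15)
  expect_equal(a$dH_raw, b$dH_raw, tolerance = 1e-12)
  expect_equal(a$dH_corrected - a$dH_raw, 3, tolerance = 1e-12)
})

test_that("an exact van't Hoff line round-trips its enthalpy to machine precision", {
  # log10 P50 = a + b / T implies dH_raw = 4.574 * b / 1000 exactly
  b <- -2388.7; a <- 8.75
  T1 <- 298.15; T2 <- 288.15
  P1 <- 10^(a + b / T1); P2 <- 10^(a + b / T2)
  dh <- vant_hoff_dH(P1, T1, P2, T2)
  expect_equal(dh$dH_raw, 4.574 * b / 1000, tolerance = 1e-9)
})

test_that("0 C extrapolation through the two measured temperatures matches the published entries", {
  # stripped isoforms, pH 7.4: published 0 C values 1.0, 0.9, 1.3 Torr
  pairs <- list(Hb1 = c(5.5, 2.9), Hb2 = c(5.7, 2.8), Hb3 = c(7.7, 3.9))
  expected <- c(Hb1 = 1.0, Hb2 = 0.9, Hb3 = 1.3)
  for (iso in names(pairs)) {
    g <- hb_p50_grid(temperature_C = c(25, 15), pH = 7.4, atp = FALSE,
                     P50_torr = pairs[[iso]], isoform = iso)
    expect_equal(round(extrapolate_p50(g, 273.15), 1), unname(expected[iso]))
  }
})

test_that("extrapolation to an anchor temperature returns the anchor P50", {
  g <- hb_p50_grid(temperature_C = c(25, 15), pH = 7.4, atp = FALSE,
                   P50_torr = c(5.5, 2.9))
  expect_equal(extrapolate_p50(g, 298.15), 5.5, tolerance = 1e-10)
  expect_equal(extrapolate_p50(g, 288.15), 2.9, tolerance = 1e-10)
})

test_that("extrapolation shifts along the Bohr slope when the target pH differs", {
  g <- hb_p50_grid(temperature_C = c(25, 15), pH = 7.4, atp = FALSE,
                   P50_torr = c(5.5, 2.9))
  p74 <- extrapolate_p50(g, 273.15)
  p78 <- extrapolate_p50(g, 273.15, target_pH = 7.8, phi = -0.2)
  expect_equal(log10(p78) - log10(p74), -0.2 * 0.4, tolerance = 1e-12)
  expect_error(extrapolate_p50(g, 273.15, target_pH = 7.8),
               class = "hemolig_error_input")
})

test_that("grids with insufficient temperatures are rejected", {
  g <- hb_p50_grid(temperature_C = 25, pH = 7.4, atp = FALSE, P50_torr = 5.5)
  expect_error(extrapolate_p50(g, 273.15),
               class = "hemolig_error_insufficient_data")
  expect_error(hb_p50_grid(temperature_C = c(25, 25), pH = c(7.4, 7.4),
                           atp = FALSE, P50_torr = c(5, 6)),
               class = "hemolig_error_input")
})

test_that("linkage_summary assembles phi, protons, enthalpy and extrapolation per ATP state", {
  pre <- hb_presets()
  eq <- pre$equilibrium[pre$equilibrium$isoform == "Hb1", ]
  g <- hb_p50_grid(temperature_C = eq$temperature_C, pH = eq$pH,
                   atp = eq$atp, P50_torr = eq$P50_torr, isoform = "Hb1")
  link <- linkage_summary(g)
  expect_equal(round(link$stripped$dH_corrected, 1), -7.9)
  expect_equal(round(link$atp$dH_corrected, 1), -0.7)
  expect_equal(round(link$stripped$P50_extrapolated, 1), 1.0)
  expect_equal(link$stripped$protons, 4 * abs(link$stripped$phi))
})
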