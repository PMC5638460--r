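# Published equilibrium and kinetic parameter sets for the three Greenland
# shark (Somniosus microcephalus) Hb isoforms, used as generator inputs by
# the synthetic-data module and as the anchor values of the linkage layer.

#' Published parameter presets for shark Hb isoforms
#'
#' Equilibrium (P50/nH by temperature, pH and ATP state, with the reported
#' Bohr coefficients, R-state O2 dissociation rates and autoxidation rates)
#' and CO-rebinding kinetic parameters (R/T percentages of the bimolecular
#' phase and bimolecular rate constants) for the three hemoglobin isoforms of
#' the Greenland shark, as measured at 15 and 25 C. These are the parameter
#' sets the synthetic-data generators reproduce verbatim as inputs, so that a
#' synthetic analogue of each results table can be regenerated and compared.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{equilibrium}{data frame: isoform, temperature_C, pH, atp,
#'       P50_torr, nH.}
#'     \item{phi}{data frame: isoform, atp, phi (reported Bohr coefficients).}
#'     \item{koff}{data frame: isoform, atp, koff_s (R-state O2 dissociation,
#'       pH 6.5, 25 C).}
#'     \item{kox}{data frame: isoform, kox_per_min (autoxidation, pH 7.45,
#'       25 C; `HbA` is the human reference value).}
#'     \item{kinetics}{data frame: isoform, temperature_C, pH, atp, R_pct,
#'       T_pct, kon_R, kon_T (M^-1 s^-1).}
#'   }
#' @export
hb_presets <- function() {
  eq <- rbind(
    data.frame(isoform = "Hb1", temperature_C = 25,
               pH = c(7.4, 6.7, 7.4, 6.7), atp = c(FALSE, FALSE, TRUE, TRUE),
               P50_torr = c(5.5, 8.9, 14.4, 46.1), nH = c(1.2, 1.4, 1.8, 1.6)),
    data.frame(isoform = "Hb2", temperature_C = 25,
               pH = c(7.4, 6.7, 7.4, 6.7), atp = c(FALSE, FALSE, TRUE, TRUE),
               P50_torr = c(5.7, 8.7, 12.5, 40.8), nH = c(1.6, 1.9, 1.8, 1.6)),
    data.frame(isoform = "Hb3", temperature_C = 25,
               pH = c(7.4, 6.7, 7.4, 6.7), atp = c(FALSE, FALSE, TRUE, TRUE),
               P50_torr = c(7.7, 11.6, 13.3, 36.2), nH = c(1.4, 1.7, 1.9, 1.7)),
    data.frame(isoform = "Hb1", temperature_C = 15,
               pH = c(7.4, 6.8, 7.4, 6.8), atp = c(FALSE, FALSE, TRUE, TRUE),
               P50_torr = c(2.9, 4.1, 11.6, 28.2), nH = c(1.5, 1.7, 2.1, 1.3)),
    data.frame(isoform = "Hb2", temperature_C = 15,
               pH = c(7.4, 6.8, 7.4, 6.8), atp = c(FALSE, FALSE, TRUE, TRUE),
               P50_torr = c(2.8, 4.4, 9.2, 23.2), nH = c(1.6, 2.0, 1.9, 1.3)),
    data.frame(isoform = "Hb3", temperature_C = 15,
               pH = c(7.4, 6.8, 7.4, 6.8), atp = c(FALSE, FALSE, TRUE, TRUE),
               P50_torr = c(3.9, 6.0, 10.6, 22.9), nH = c(1.8, 1.7, 2.0, 1.7)))
  phi <- data.frame(
    isoform = rep(c("Hb1", "Hb2", "Hb3"), each = 2L),
    atp = rep(c(FALSE, TRUE), 3L),
    phi = c(-0.2, -0.6, -0.2, -0.6, -0.2, -0.5))
  koff <- data.frame(
    isoform = rep(c("Hb1", "Hb2", "Hb3"), each = 2L),
    atp = rep(c(FALSE, TRUE), 3L),
    koff_s = c(13.1, 10.5, 7.1, 6.6, 35.1, 33.3))
  kox <- data.frame(
    isoform = c("Hb1", "Hb2", "Hb3", "HbA"),
    kox_per_min = c(2.2e-4, 3.1e-4, 3.9e-4, 1.3e-4))
  kin <- rbind(
    data.frame(isoform = "Hb1", temperature_C = 25,
               pH = c(7.4, 7.4, 6.4, 6.4), atp = c(FALSE, TRUE, FALSE, TRUE),
               R_pct = c(84, 22, 10, 27), T_pct = c(16, 78, 0, 73),
               kon_R = c(9.4e5, 9.4e5, 4.2e5, 4.2e5),
               kon_T = c(2.4e5, 2.4e5, 2.0e5, 2.0e5)),
    data.frame(isoform = "Hb2", temperature_C = 25,
               pH = c(7.4, 7.4, 6.4, 6.4), atp = c(FALSE, TRUE, FALSE, TRUE),
               R_pct = c(100, 12, 80, 26), T_pct = c(0, 88, 20, 74),
               kon_R = c(7.0e5, 7.0e5, 4.9e5, 4.9e5),
               kon_T = c(1.8e5, 1.8e5, 1.7e5, 1.7e5)),
    data.frame(isoform = "Hb3", temperature_C = 25,
               pH = c(7.4, 7.4, 6.4, 6.4), atp = c(FALSE, TRUE, FALSE, TRUE),
               R_pct = c(92, 13, 68, 5), T_pct = c(8, 87, 32, 95),
               kon_R = c(7.3e5, 7.3e5, 6.5e5, 6.5e5),
               kon_T = c(2.8e5, 2.8e5, 1.0e5, 1.0e5)),
    data.frame(isoform = "Hb1", temperature_C = 15,
               pH = c(7.4, 7.4, 6.4, 6.4), atp = c(FALSE, TRUE, FALSE, TRUE),
               R_pct = c(90, 21, 90, 20), T_pct = c(10, 79, 10, 80),
               kon_R = c(5.9e5, 5.9e5, 2.3e5, 2.3e5),
               kon_T = c(1.3e5, 1.3e5, 1.3e5, 1.3e5)),
    data.frame(isoform = "Hb2", temperature_C = 15,
               pH = c(7.4, 7.4, 6.4, 6.4), atp = c(FALSE, TRUE, FALSE, TRUE),
               R_pct = c(97, 13, 83, 25), T_pct = c(3, 87, 17, 75),
               kon_R = c(4.7e5, 4.7e5, 2.8e5, 2.8e5),
               kon_T = c(1.0e5, 1.0e5, 1.0e5, 1.0e5)),
    data.frame(isoform = "Hb3", temperature_C = 15,
               pH = c(7.4, 7.4, 6.4, 6.4), atp = c(FALSE, TRUE, FALSE, TRUE),
               R_pct = c(85, 17, 96, 74), T_pct = c(15, 82, 4, 26),
               kon_R = c(5.5e5, 5.5e5, 4.2e5, 4.2e5),
               kon_T = c(1.5e5, 1.5e5, 0.5e5, 0.5e5)))
  list(equilibrium = eq, phi = phi, koff = koff, kox = kox, kinetics = kin)
}

#' Assemble a full synthetic scenario for one condition
#'
#' Bundles every generator parameter for one isoform/temperature/pH/ATP
#' combination: Hill parameters, the rebinding model (the published R/T
#' partitioning and bimolecular rate constants, with the documented geminate
#' assumptions: total geminate amplitude 8% of the signal split over two
#' stretched components with lifetimes 100 ns and 1 us and beta 0.8, since no
#' geminate parameters are published), koff,R, kox, the noise model and the
#' seed. Amplitudes sum to 1 so N(0) = 1.
#'
#' @param isoform `"Hb1"`, `"Hb2"` or `"Hb3"`.
#' @param temperature_C 15 or 25.
#' @param pH one of the preset pH values (7.4/6.7/6.8 equilibrium; 7.4/6.4
#'   kinetics — the nearest kinetic pH is used for the rebinding block).
#' @param atp logical: 2 mM ATP present.
#' @param CO_atm CO partial pressure for the rebinding block (default 1 atm).
#' @param seed integer seed recorded in the scenario.
#' @param noise list of Gaussian noise sd per signal type; defaults
#'   `Y_sd = 0.01`, `N_sd = 0.01`, `A_sd = 0.002` AU.
#' @return An object of class `"hb_scenario"` (a named list).
#' @export
hb_scenario <- function(isoform = "Hb1", temperature_C = 25, pH = 7.4,
                        atp = FALSE, CO_atm = 1, seed = 1L,
                        noise = list(Y_sd = 0.01, N_sd = 0.01, A_sd = 0.002)) {
  pre <- hb_presets()
  eq <- pre$equilibrium
  row <- eq[eq$isoform == isoform & eq$temperature_C == temperature_C &
              eq$pH == pH & eq$atp == atp, ]
  if (nrow(row) != 1L)
    hl_stop("no equilibrium preset for this condition", "hemolig_error_input")
  kin <- pre$kinetics
  ksub <- kin[kin$isoform == isoform & kin$temperature_C == temperature_C &
                kin$atp == atp, ]
  krow <- ksub[which.min(abs(ksub$pH - pH)), ]
  CO_M <- co_concentration(CO_atm, temperature_C + 273.15)
  bim_total <- 0.92  # geminate assumed 8% of total amplitude
  model <- hb_rebinding_model(
    geminate = data.frame(amplitude = c(0.04, 0.04),
                          tau_s = c(1e-7, 1e-6), beta = c(0.8, 0.8)),
    A_R = bim_total * krow$R_pct / 100,
    k_R = krow$kon_R * CO_M,
    A_T = bim_total * krow$T_pct / 100,
    k_T = krow$kon_T * CO_M,
    relabel = TRUE)
  koff <- pre$koff
  koff_s <- koff$koff_s[koff$isoform == isoform & koff$atp == atp]
  kox <- pre$kox$kox_per_min[pre$kox$isoform == isoform]
  structure(list(
    isoform = isoform,
    condition = hb_condition(temperature_C = temperature_C, pH = pH,
                             ATP_mM = if (atp) 2 else 0, label = isoform),
    P50 = row$P50_torr, nH = row$nH,
    rebinding = model, CO_atm = CO_atm, CO_M = CO_M,
    kon_R = krow$kon_R, kon_T = krow$kon_T,
    R_pct = krow$R_pct, T_pct = krow$T_pct,
    koff_s = if (length(koff_s)) koff_s else NA_real_,
    kox_per_min = if (length(kox)) kox else NA_real_,
    noise = noise, seed = as.integer(seed)),
    class = "hb_scenario")
}

#' @export
print.hb_scenario <- function(x, ...) {
  cat(sprintf("<hb_scenario> %s, %.0f C, pH %.1f, %s ATP (seed %d)\n",
              x$isoform, x$condition$temperature_K - 273.15, x$condition$pH,
              if (x$condition$ATP_mM > 0) "+" else "-", x$seed))
  cat(sprintf("  P50 %.1f Torr, nH %.1f | R/T %.0f/%.0f%%, kon_R %.2g, kon_T %.2g | koff %.3g s^-1, kox %.2g min^-1\n",
              x$P50, x$nH, x$R_pct, x$T_pct, x$kon_R, x$kon_T,
              x$koff_s, x$kox_per_min))
  invisible(x)
}
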