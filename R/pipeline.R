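#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param isoforms isoform labels to analyse.
#' @param equilibrium,kinetics,displacement,autoxidation logical switches for
#'   the pipeline branches.
#' @param noise noise model (sd per signal type) passed to the generators.
#' @param hill_steps saturation steps per simulated equilibrium curve.
#' @param mc_replicates unused by the pipeline itself; recorded for
#'   provenance when configs are logged.
#' @return A named list of class `"hb_config"`.
#' @export
hb_config <- function(seed = 1L, isoforms = "Hb1",
                      equilibrium = TRUE, kinetics = TRUE,
                      displacement = TRUE, autoxidation = TRUE,
                      noise = list(Y_sd = 0.01, N_sd = 0.01, A_sd = 0.002),
                      hill_steps = 5L, mc_replicates = 0L) {
  structure(list(seed = as.integer(seed), isoforms = isoforms,
                 equilibrium = equilibrium, kinetics = kinetics,
                 displacement = displacement, autoxidation = autoxidation,
                 noise = noise, hill_steps = hill_steps,
                 mc_replicates = mc_replicates),
            class = "hb_config")
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "hb_config")) return(config)
  if (!is.list(config))
    hl_stop("config must be an hb_config, a list or a YAML path",
            "hemolig_error_input")
  needed <- c("seed", "isoforms")
  missing <- setdiff(needed, names(config))
  if (length(missing))
    hl_stop(sprintf("config is missing required keys: %s",
                    paste(missing, collapse = ", ")),
            "hemolig_error_input")
  do.call(hb_config, config[intersect(names(config),
                                      names(formals(hb_config)))])
}

# deterministic per-stage sub-seeds, kept well below 2^31
stage_seed <- function(seed, stage, i = 0L)
  (as.integer(seed) * 97L + stage * 1009L + i * 13L) %% 2000000000L

#' Run the full synthetic analysis pipeline
#'
#' Generates synthetic data from the bundled isoform presets and pushes each
#' signal through its analysis stage: equilibrium curves through the Hill
#' fit and the P50 grid through the Bohr / van't Hoff linkage layer;
#' photolysis trace pairs (1 and 0.1 atm CO, with and without ATP) through
#' the global R/T kinetic fit; displacement traces through the
#' mono-exponential koff fit; and autoxidation series through the
#' initial-rate estimator. Deterministic given the config (every stage seed
#' derives from the master seed).
#'
#' @param config an [hb_config()], a plain list with at least `seed` and
#'   `isoforms`, or the path to a YAML file of the same shape.
#' @return An object of class `"hb_report"`: list with data frames
#'   `equilibrium` (isoform, temperature_C, pH, atp, P50_torr, nH,
#'   dH_corrected, phi, protons, P50_0C_torr, koff_s, kox_per_min) and
#'   `kinetics` (isoform, temperature_C, pH, atp, R_pct, T_pct, kon_R,
#'   kon_T), plus the evaluated `config` and a `log` of stage records.
#' @examples
#' \donttest{
#' rep <- run_pipeline(hb_config(seed = 7, isoforms = "Hb1",
#'                               kinetics = FALSE, displacement = FALSE,
#'                               autoxidation = FALSE))
#' rep$equilibrium
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  pre <- hb_presets()
  log <- list(seed = cfg$seed, noise = cfg$noise,
              package_version = as.character(utils::packageVersion("hemolig")))
  eq_rows <- list(); kin_rows <- list()
  for (iso in cfg$isoforms) {
    if (cfg$equilibrium) {
      sub <- pre$equilibrium[pre$equilibrium$isoform == iso, ]
      fits <- lapply(seq_len(nrow(sub)), function(i) {
        r <- sub[i, ]
        cur <- simulate_equilibrium_curve(
          r$P50_torr, r$nH, steps = cfg$hill_steps,
          noise_sd = cfg$noise$Y_sd,
          seed = stage_seed(cfg$seed, 1L, i + 100L * match(iso, cfg$isoforms)),
          condition = hb_condition(temperature_C = r$temperature_C, pH = r$pH,
                                   ATP_mM = if (r$atp) 2 else 0, label = iso))
        fit_hill(cur)
      })
      sub$P50_fit <- vapply(fits, function(f) f$P50, numeric(1))
      sub$nH_fit <- vapply(fits, function(f) f$nH, numeric(1))
      grid <- hb_p50_grid(temperature_C = sub$temperature_C, pH = sub$pH,
                          atp = sub$atp, P50_torr = sub$P50_fit,
                          isoform = iso)
      link <- linkage_summary(grid)
      koff <- pre$koff[pre$koff$isoform == iso, ]
      kox <- pre$kox$kox_per_min[pre$kox$isoform == iso]
      for (i in seq_len(nrow(sub))) {
        r <- sub[i, ]
        st <- if (r$atp) "atp" else "stripped"
        eq_rows[[length(eq_rows) + 1L]] <- data.frame(
          isoform = iso, temperature_C = r$temperature_C, pH = r$pH,
          atp = r$atp, P50_torr = r$P50_fit, nH = r$nH_fit,
          dH_corrected = if (!is.null(link[[st]]$dH_corrected))
            link[[st]]$dH_corrected else NA_real_,
          phi = if (!is.null(link[[st]]$phi)) link[[st]]$phi else NA_real_,
          protons = if (!is.null(link[[st]]$protons))
            link[[st]]$protons else NA_real_,
          P50_0C_torr = if (!is.null(link[[st]]$P50_extrapolated))
            link[[st]]$P50_extrapolated else NA_real_,
          koff_s = { k <- koff$koff_s[koff$atp == r$atp]
                     if (length(k)) k else NA_real_ },
          kox_per_min = if (length(kox)) kox else NA_real_)
      }
      log[[paste0("equilibrium_", iso)]] <- sprintf(
        "%d curves fitted, %d-step, Y sd %.3g", nrow(sub), cfg$hill_steps,
        cfg$noise$Y_sd)
    }
    if (cfg$kinetics) {
      for (atp in c(FALSE, TRUE)) {
        sc <- hb_scenario(iso, 25, 7.4, atp = atp,
                          seed = stage_seed(cfg$seed, 2L, atp))
        traces <- lapply(c(1, 0.1), function(p) {
          m <- sc$rebinding
          # apparent rates scale with [CO]; geminate phase does not
          m$k_R <- sc$kon_R * co_concentration(p, sc$condition$temperature_K)
          m$k_T <- sc$kon_T * co_concentration(p, sc$condition$temperature_K)
          simulate_photolysis_trace(
            m, CO_atm = p, noise_sd = cfg$noise$N_sd,
            seed = stage_seed(cfg$seed, 3L, round(100 * p) + atp),
            condition = sc$condition)
        })
        gf <- global_fit(traces)
        summ <- kinetic_summary(gf[[1L]], attr(gf, "CO_M")[1L],
                                condition = sc$condition)
        kin_rows[[length(kin_rows) + 1L]] <- data.frame(
          isoform = iso, temperature_C = 25, pH = 7.4, atp = atp,
          R_pct = summ$fR, T_pct = summ$fT,
          kon_R = attr(gf, "kon_R"), kon_T = attr(gf, "kon_T"))
      }
      log[[paste0("kinetics_", iso)]] <-
        "global fit of 1/0.1 atm CO trace pairs, +/- ATP, 25 C pH 7.4"
    }
  }
  eq <- if (length(eq_rows)) do.call(rbind, eq_rows) else NULL
  kin <- if (length(kin_rows)) do.call(rbind, kin_rows) else NULL
  disp <- NULL; autox <- NULL
  if (cfg$displacement) {
    koff <- pre$koff
    disp <- do.call(rbind, lapply(cfg$isoforms, function(iso) {
      k <- koff$koff_s[koff$isoform == iso & !koff$atp]
      tr <- simulate_displacement(
        k, duration_s = 6 / k, noise_sd = 0.0005,
        seed = stage_seed(cfg$seed, 4L, match(iso, cfg$isoforms)))
      fit <- fit_monoexp(tr)
      data.frame(isoform = iso, koff_true_s = k, koff_s = fit$koff,
                 se_koff = fit$se_koff)
    }))
  }
  if (cfg$autoxidation) {
    autox <- do.call(rbind, lapply(cfg$isoforms, function(iso) {
      k <- pre$kox$kox_per_min[pre$kox$isoform == iso]
      ser <- simulate_autoxidation(
        k, noise_sd = 0.005,
        seed = stage_seed(cfg$seed, 5L, match(iso, cfg$isoforms)))
      fit <- initial_rate(ser)
      data.frame(isoform = iso, kox_true_per_min = k,
                 kox_per_min = fit$kox, se_kox = fit$se_kox)
    }))
  }
  structure(list(equilibrium = eq, kinetics = kin, displacement = disp,
                 autoxidation = autox, config = cfg, log = log),
            class = "hb_report")
}

#' @export
print.hb_report <- function(x, ...) {
  cat("<hb_report>\n")
  for (nm in c("equilibrium", "kinetics", "displacement", "autoxidation"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
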