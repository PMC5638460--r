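# Readers and writers. CSV with unit-bearing headers is the canonical
# exchange format for traces and spectra; JSON for fitted results. Headers
# are validated on read so unit mistakes fail loudly instead of silently.

check_header <- function(df, expected, path) {
  if (!all(expected %in% names(df)))
    hl_stop(sprintf("%s: expected columns %s, found %s", path,
                    paste(expected, collapse = ","),
                    paste(names(df), collapse = ",")),
            "hemolig_error_input")
}

#' Read / write spectra as CSV
#'
#' Two-column CSV with header `wavelength_nm,absorbance`.
#'
#' @param path file path.
#' @param label label attached to the spectrum on read.
#' @return `read_spectrum_csv` returns an [hb_spectrum()].
#' @export
read_spectrum_csv <- function(path, label = basename(path)) {
  df <- read.csv(path)
  check_header(df, c("wavelength_nm", "absorbance"), path)
  hb_spectrum(df$wavelength_nm, df$absorbance, label = label)
}

#' @rdname read_spectrum_csv
#' @param spectrum an [hb_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "hb_spectrum"))
  write.csv(data.frame(wavelength_nm = spectrum$wavelengths,
                       absorbance = spectrum$absorbances),
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write equilibrium curves as CSV
#'
#' Two-column CSV with header `pO2_torr,saturation`; condition metadata
#' travels in a sidecar YAML file (see [read_condition_yaml()]).
#'
#' @param path file path.
#' @param condition an [hb_condition()] to attach.
#' @return `read_equilibrium_csv` returns an [hb_equilibrium_curve()].
#' @export
read_equilibrium_csv <- function(path, condition = hb_condition()) {
  df <- read.csv(path)
  check_header(df, c("pO2_torr", "saturation"), path)
  hb_equilibrium_curve(df$pO2_torr, df$saturation, condition)
}

#' @rdname read_equilibrium_csv
#' @param curve an [hb_equilibrium_curve()].
#' @export
write_equilibrium_csv <- function(curve, path) {
  stopifnot(inherits(curve, "hb_equilibrium_curve"))
  write.csv(data.frame(pO2_torr = curve$pO2_torr,
                       saturation = curve$saturation),
            path, row.names = FALSE)
  invisible(path)
}

#' Read / write photolysis traces as CSV
#'
#' Two-column CSV with header `time_s,N`.
#'
#' @param path file path.
#' @param CO_atm CO partial pressure of the trace.
#' @param condition an [hb_condition()].
#' @return `read_trace_csv` returns an [hb_photolysis_trace()].
#' @export
read_trace_csv <- function(path, CO_atm, condition = hb_condition()) {
  df <- read.csv(path)
  check_header(df, c("time_s", "N"), path)
  hb_photolysis_trace(df$time_s, df$N, CO_atm, condition)
}

#' @rdname read_trace_csv
#' @param trace an [hb_photolysis_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "hb_photolysis_trace"))
  write.csv(data.frame(time_s = trace$times_s, N = trace$N),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a displacement trace as CSV
#'
#' Two-column CSV with header `time_s,A420`.
#'
#' @param path file path.
#' @param condition an [hb_condition()].
#' @return An [hb_displacement_trace()].
#' @export
read_displacement_csv <- function(path, condition = hb_condition()) {
  df <- read.csv(path)
  check_header(df, c("time_s", "A420"), path)
  hb_displacement_trace(df$time_s, df$A420, condition)
}

#' Read / write a P50 grid as CSV
#'
#' CSV with header `temperature_C,pH,atp_mM,P50_torr`.
#'
#' @param path file path.
#' @param isoform isoform label to attach.
#' @return `read_p50_grid_csv` returns an [hb_p50_grid()].
#' @export
read_p50_grid_csv <- function(path, isoform = "") {
  df <- read.csv(path)
  check_header(df, c("temperature_C", "pH", "atp_mM", "P50_torr"), path)
  hb_p50_grid(temperature_C = df$temperature_C, pH = df$pH,
              atp = df$atp_mM > 0, P50_torr = df$P50_torr, isoform = isoform)
}

#' @rdname read_p50_grid_csv
#' @param grid an [hb_p50_grid()].
#' @export
write_p50_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "hb_p50_grid"))
  write.csv(data.frame(temperature_C = grid$temperature_K - 273.15,
                       pH = grid$pH, atp_mM = ifelse(grid$atp, 2, 0),
                       P50_torr = grid$P50_torr),
            path, row.names = FALSE)
  invisible(path)
}

#' Read an experimental condition from a YAML sidecar
#'
#' Key-value file with any of `temperature_C`, `temperature_K`, `pH`,
#' `KCl_mM`, `ATP_mM`, `urea_mM`, `heme_mM`, `label`.
#'
#' @param path YAML file path.
#' @return An [hb_condition()].
#' @export
read_condition_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- c("temperature_C", "temperature_K", "pH", "KCl_mM", "ATP_mM",
             "urea_mM", "heme_mM", "label")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    hl_stop(sprintf("unknown condition keys: %s",
                    paste(unknown, collapse = ", ")),
            "hemolig_error_input")
  do.call(hb_condition, vals)
}

#' Write a species composition as JSON
#'
#' Records `{references: {name: coeff}, offset, residual_rms}`.
#'
#' @param composition an `"hb_composition"` from [unmix()].
#' @param path output path.
#' @export
write_composition_json <- function(composition, path) {
  stopifnot(inherits(composition, "hb_composition"))
  jsonlite::write_json(
    list(references = as.list(composition$coefficients),
         offset = composition$offset,
         residual_rms = composition$residual_rms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a Hill fit as JSON
#'
#' Records `{P50_torr, nH, se_P50, se_nH}` (plus RSS and flags).
#'
#' @param fit an `"hb_hill_fit"`.
#' @param path output path.
#' @export
write_hill_json <- function(fit, path) {
  stopifnot(inherits(fit, "hb_hill_fit"))
  jsonlite::write_json(
    list(P50_torr = fit$P50, nH = fit$nH, se_P50 = fit$se_P50,
         se_nH = fit$se_nH, rss = fit$rss, converged = fit$converged,
         extrapolated = fit$extrapolated),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# report-layer rounding: one decimal for P50/dH/phi columns, two significant
# figures for rate constants; applied only at serialisation
round_report <- function(df) {
  one_dec <- intersect(names(df), c("P50_torr", "P50_0C_torr", "dH_raw",
                                    "dH_corrected", "phi", "nH", "fR", "fT",
                                    "R_pct", "T_pct", "protons"))
  two_sig <- intersect(names(df), c("koff_s", "kox_per_min", "kon_R", "kon_T"))
  for (cn in one_dec) df[[cn]] <- round(df[[cn]], 1L)
  for (cn in two_sig) df[[cn]] <- signif(df[[cn]], 2L)
  df
}

#' Write a report table
#'
#' Serialises a pipeline report table (see [run_pipeline()]) with stable
#' column order and the reporting rounding rules: one decimal for P50, nH,
#' enthalpies, Bohr coefficients and percentages; two significant figures
#' for rate constants. Rounding happens only here; the in-memory tables stay
#' at full precision.
#'
#' @param table a data frame (equilibrium- or kinetics-layout report table).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_report <- function(table, path, format = c("csv", "json")) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    hl_stop("report table must be a non-empty data frame",
            "hemolig_error_input")
  format <- match.arg(format)
  out <- round_report(table)
  if (format == "csv") write.csv(out, path, row.names = FALSE)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                            dataframe = "rows")
  invisible(path)
}
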