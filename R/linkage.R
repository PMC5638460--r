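#' P50 grid across temperature, pH and ATP
#'
#' The substrate of all thermodynamic-linkage calculations: P50 values indexed
#' by (temperature, pH, ATP state) for one hemoglobin isoform.
#'
#' @param temperature_K temperatures in kelvin (use `temperature_C` for
#'   Celsius input).
#' @param temperature_C temperatures in Celsius; converted with 273.15.
#' @param pH solution pH per entry.
#' @param atp logical (or 0/1): ATP present.
#' @param P50_torr P50 values in Torr, > 0.
#' @param isoform isoform label.
#' @return An object of class `"hb_p50_grid"` (a data frame).
#' @export
hb_p50_grid <- function(temperature_K = NULL, temperature_C = NULL,
                        pH, atp, P50_torr, isoform = "") {
  if (is.null(temperature_K)) {
    if (is.null(temperature_C))
      hl_stop("supply temperature_K or temperature_C", "hemolig_error_input")
    temperature_K <- temperature_C + 273.15
  }
  atp <- as.logical(atp)
  df <- data.frame(temperature_K = temperature_K, pH = pH, atp = atp,
                   P50_torr = P50_torr)
  if (any(df$P50_torr <= 0) || any(!is.finite(df$P50_torr)))
    hl_stop("P50 must be strictly positive", "hemolig_error_input")
  key <- paste(df$temperature_K, df$pH, df$atp)
  if (anyDuplicated(key))
    hl_stop("duplicate (temperature, pH, ATP) entries", "hemolig_error_input")
  attr(df, "isoform") <- isoform
  class(df) <- c("hb_p50_grid", "data.frame")
  df
}

#' Bohr coefficient from two P50/pH points
#'
#' phi = (log10 P50_a - log10 P50_b) / (pH_a - pH_b); negative for a normal
#' (alkaline) Bohr effect. With more than two points supply a grid to
#' [bohr_coefficient_fit()].
#'
#' @param P50_a,P50_b P50 values in Torr, > 0.
#' @param pH_a,pH_b the corresponding pH values (must differ).
#' @return The Bohr coefficient (unitless).
#' @examples
#' bohr_coefficient(10, 7.4, 20, 6.7)   # -0.430
#' @export
bohr_coefficient <- function(P50_a, pH_a, P50_b, pH_b) {
  if (P50_a <= 0 || P50_b <= 0)
    hl_stop("P50 must be positive", "hemolig_error_domain")
  if (pH_a == pH_b)
    hl_stop("Bohr coefficient undefined at equal pH", "hemolig_error_division")
  (log10(P50_a) - log10(P50_b)) / (pH_a - pH_b)
}

#' Bohr coefficient by least squares over a grid
#'
#' Ordinary least-squares slope of log10 P50 against pH across all entries of
#' a [hb_p50_grid()] at one temperature and ATP state (the Bohr plot is
#' treated as linear over the pH range examined).
#'
#' @param grid an [hb_p50_grid()].
#' @param temperature_K restrict to this temperature.
#' @param atp restrict to this ATP state.
#' @return The fitted slope (Bohr coefficient).
#' @export
bohr_coefficient_fit <- function(grid, temperature_K, atp) {
  stopifnot(inherits(grid, "hb_p50_grid"))
  sub <- grid[grid$temperature_K == temperature_K & grid$atp == atp, ]
  if (nrow(sub) < 2L)
    hl_stop("need at least 2 pH points at the requested condition",
            "hemolig_error_insufficient_data")
  if (nrow(sub) == 2L)
    return(bohr_coefficient(sub$P50_torr[1L], sub$pH[1L],
                            sub$P50_torr[2L], sub$pH[2L]))
  unname(coef(lm(log10(P50_torr) ~ pH, data = sub))[2L])
}

#' Oxygen-linked proton release per tetramer
#'
#' Number of protons released on oxygenation per Hb tetramer, 4 * |phi|
#' (one Bohr proton per heme at the limit).
#'
#' @param phi Bohr coefficient.
#' @return Protons per tetramer (unitless, >= 0).
#' @examples
#' protons_per_tetramer(-0.2)  # 0.8
#' protons_per_tetramer(-0.5)  # 2.0
#' @export
protons_per_tetramer <- function(phi) 4 * abs(phi)

#' Van't Hoff oxygenation enthalpy from two temperatures
#'
#' Overall oxygenation enthalpy from the temperature dependence of P50,
#'
#'   dH_raw = -4.574 * (T1 * T2 / (T1 - T2)) * (log10 P50_T1 - log10 P50_T2) / 1000
#'
#' in kcal/mol (4.574 = R ln 10 in cal mol^-1 K^-1, used exactly as the
#' conventional constant). The corrected value removes the heat of O2
#' solubilisation: dH_corrected = dH_raw - correction, with the default
#' correction of -3 kcal/mol, so corrected = raw + 3. The expression is
#' symmetric under exchange of the two (P50, T) pairs.
#'
#' @param P50_T1,T1 P50 (Torr) and absolute temperature (K) at one condition.
#' @param P50_T2,T2 the same at the second temperature (T2 != T1).
#' @param solubilisation_correction heat of O2 solubilisation in kcal/mol
#'   (default -3).
#' @return List with `dH_raw` and `dH_corrected`, both kcal/mol.
#' @examples
#' vant_hoff_dH(5.5, 298.15, 2.9, 288.15)  # corrected ~ -7.9 kcal/mol
#' @export
vant_hoff_dH <- function(P50_T1, T1, P50_T2, T2,
                         solubilisation_correction = -3) {
  if (P50_T1 <= 0 || P50_T2 <= 0)
    hl_stop("P50 must be positive", "hemolig_error_domain")
  if (T1 == T2)
    hl_stop("van't Hoff enthalpy undefined at equal temperatures",
            "hemolig_error_division")
  dlog <- log10(P50_T1) - log10(P50_T2)
  dH_raw <- -4.574 * (T1 * T2 / (T1 - T2)) * dlog / 1000
  list(dH_raw = dH_raw,
       dH_corrected = dH_raw - solubilisation_correction)
}

#' Extrapolate P50 across temperature and pH
#'
#' Fits log10 P50 linearly against 1/T through the grid entries at the anchor
#' pH and ATP state (a linear van't Hoff plot), evaluates at `target_T`, then
#' shifts along a linear Bohr plot by `phi * (target_pH - anchor_pH)`. This is
#' how sub-zero operating points are obtained when direct measurement below
#' the instrument's working range is impossible.
#'
#' @param grid an [hb_p50_grid()] with >= 2 temperatures at `anchor_pH`.
#' @param target_T target absolute temperature (K).
#' @param target_pH target pH (defaults to the anchor pH: no Bohr shift).
#' @param phi Bohr coefficient used for the pH shift (required when
#'   `target_pH` differs from the anchor).
#' @param anchor_pH pH at which the van't Hoff line is fitted; default the
#'   most common pH in the grid.
#' @param atp ATP state to use (default FALSE, i.e. stripped).
#' @return Extrapolated P50 in Torr.
#' @examples
#' g <- hb_p50_grid(temperature_C = c(25, 15), pH = 7.4, atp = FALSE,
#'                  P50_torr = c(5.5, 2.9))
#' extrapolate_p50(g, target_T = 273.15)  # ~1.0 Torr at 0 C
#' @export
extrapolate_p50 <- function(grid, target_T, target_pH = NULL, phi = NULL,
                            anchor_pH = NULL, atp = FALSE) {
  stopifnot(inherits(grid, "hb_p50_grid"))
  if (is.null(anchor_pH)) {
    tab <- table(grid$pH[grid$atp == atp])
    if (length(tab) == 0L)
      hl_stop("no grid entries at the requested ATP state",
              "hemolig_error_insufficient_data")
    anchor_pH <- as.numeric(names(tab)[which.max(tab)])
  }
  sub <- grid[grid$pH == anchor_pH & grid$atp == atp, ]
  if (nrow(sub) < 2L)
    hl_stop("need at least 2 temperatures at the anchor pH",
            "hemolig_error_insufficient_data")
  # linear van't Hoff plot: log10 P50 vs 1/T (2 points -> exact line)
  fit <- lm(log10(P50_torr) ~ I(1 / temperature_K), data = sub)
  logP <- unname(predict(fit, data.frame(temperature_K = target_T)))
  if (!is.null(target_pH) && target_pH != anchor_pH) {
    if (is.null(phi))
      hl_stop("phi required to shift to a different pH", "hemolig_error_input")
    logP <- logP + phi * (target_pH - anchor_pH)
  }
  10^logP
}

#' Full linkage summary for one isoform
#'
#' Convenience wrapper computing the Bohr coefficient (per ATP state), proton
#' release, van't Hoff enthalpies between the two grid temperatures, and 0 C
#' extrapolations, from a two-temperature/two-pH [hb_p50_grid()].
#'
#' @param grid an [hb_p50_grid()].
#' @param anchor_pH pH used for the van't Hoff pairs and extrapolation
#'   (default 7.4).
#' @param target_T_C temperature (Celsius) to extrapolate to (default 0).
#' @return An object of class `"hb_linkage_result"`: per-ATP-state list of
#'   `phi`, `protons`, `dH_raw`, `dH_corrected`, `P50_extrapolated`.
#' @export
linkage_summary <- function(grid, anchor_pH = 7.4, target_T_C = 0) {
  stopifnot(inherits(grid, "hb_p50_grid"))
  target_T <- target_T_C + 273.15
  out <- lapply(c(stripped = FALSE, atp = TRUE), function(a) {
    sub <- grid[grid$atp == a, ]
    if (nrow(sub) == 0L) return(NULL)
    temps <- sort(unique(sub$temperature_K), decreasing = TRUE)
    anchor <- sub[sub$pH == anchor_pH, ]
    res <- list()
    # Bohr coefficient at the warmer temperature where both pH columns exist
    for (Tk in temps) {
      at_T <- sub[sub$temperature_K == Tk, ]
      if (nrow(at_T) >= 2L) {
        res$phi <- bohr_coefficient_fit(grid, Tk, a)
        res$protons <- protons_per_tetramer(res$phi)
        break
      }
    }
    if (length(temps) >= 2L && nrow(anchor) >= 2L) {
      two <- anchor[order(-anchor$temperature_K), ][1:2, ]
      dh <- vant_hoff_dH(two$P50_torr[1L], two$temperature_K[1L],
                         two$P50_torr[2L], two$temperature_K[2L])
      res$dH_raw <- dh$dH_raw
      res$dH_corrected <- dh$dH_corrected
      res$P50_extrapolated <- extrapolate_p50(grid, target_T,
                                              anchor_pH = anchor_pH, atp = a)
    }
    res
  })
  structure(c(out, list(isoform = attr(grid, "isoform"),
                        anchor_pH = anchor_pH, target_T_C = target_T_C)),
            class = "hb_linkage_result")
}

#' @export
print.hb_linkage_result <- function(x, ...) {
  cat(sprintf("<hb_linkage_result> %s (anchor pH %.1f)\n",
              if (nzchar(x$isoform)) x$isoform else "(unlabelled)",
              x$anchor_pH))
  for (state in c("stripped", "atp")) {
    r <- x[[state]]
    if (is.null(r)) next
    cat(sprintf("  %-8s phi=%s protons=%s dH_corr=%s kcal/mol P50(%g C)=%s Torr\n",
                state,
                if (is.null(r$phi)) "NA" else sprintf("%.3f", r$phi),
                if (is.null(r$protons)) "NA" else sprintf("%.2f", r$protons),
                if (is.null(r$dH_corrected)) "NA" else sprintf("%.2f", r$dH_corrected),
                x$target_T_C,
                if (is.null(r$P50_extrapolated)) "NA" else sprintf("%.2f", r$P50_extrapolated)))
  }
  invisible(x)
}
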