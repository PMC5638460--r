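#' Oxygen-equilibrium curve
#'
#' pO2 / fractional-saturation points plus condition metadata, as produced by
#' thin-layer or tonometric oxygenation experiments (typically 4-6 saturation
#' steps in the ~20-80% range).
#'
#' @param pO2_torr O2 partial pressures in Torr, strictly positive.
#' @param saturation fractional saturations in [0, 1], same length.
#' @param condition an [hb_condition()].
#' @return An object of class `"hb_equilibrium_curve"`.
#' @export
hb_equilibrium_curve <- function(pO2_torr, saturation,
                                 condition = hb_condition()) {
  pO2_torr <- as.numeric(pO2_torr); saturation <- as.numeric(saturation)
  if (length(pO2_torr) != length(saturation))
    hl_stop("pO2 and saturation must have equal length", "hemolig_error_input")
  if (length(pO2_torr) < 3L)
    hl_stop("an equilibrium curve needs at least 3 points",
            "hemolig_error_input")
  if (any(pO2_torr <= 0) || any(!is.finite(pO2_torr)))
    hl_stop("pO2 must be strictly positive", "hemolig_error_input")
  if (any(saturation < 0 | saturation > 1) || any(!is.finite(saturation)))
    hl_stop("saturation must lie in [0, 1]", "hemolig_error_input")
  stopifnot(inherits(condition, "hb_condition"))
  structure(list(pO2_torr = pO2_torr, saturation = saturation,
                 condition = condition),
            class = "hb_equilibrium_curve")
}

#' @export
print.hb_equilibrium_curve <- function(x, ...) {
  cat(sprintf("<hb_equilibrium_curve> %d points, pO2 %.3g-%.3g Torr, Y %.2f-%.2f\n",
              length(x$pO2_torr), min(x$pO2_torr), max(x$pO2_torr),
              min(x$saturation), max(x$saturation)))
  print(x$condition)
  invisible(x)
}

#' Hill equation
#'
#' Fractional saturation Y = pO2^n / (P50^n + pO2^n). At pO2 = P50 the value
#' is exactly 0.5 for any n > 0.
#'
#' @param pO2 O2 partial pressure (Torr), > 0; vectorised.
#' @param P50 half-saturation pressure (Torr), > 0.
#' @param n Hill coefficient, > 0 (1 = non-cooperative).
#' @return Saturation in (0, 1), strictly increasing in `pO2`.
#' @examples
#' hill_model(10, P50 = 10, n = 2.3)  # 0.5
#' hill_model(30, P50 = 10, n = 1)    # 0.75
#' @export
hill_model <- function(pO2, P50, n) {
  if (any(pO2 <= 0) || P50 <= 0 || n <= 0)
    hl_stop("hill_model arguments must be strictly positive",
            "hemolig_error_domain")
  # computed on the log scale for numerical stability at extreme pO2/P50
  r <- n * (log(pO2) - log(P50))
  stats::plogis(r)
}

#' Inverse Hill equation
#'
#' pO2 at which the Hill curve reaches saturation `Y`.
#'
#' @param Y target saturation strictly inside (0, 1).
#' @param P50,n Hill parameters, > 0.
#' @return pO2 in Torr.
#' @export
hill_inverse <- function(Y, P50, n) {
  if (any(Y <= 0 | Y >= 1) || P50 <= 0 || n <= 0)
    hl_stop("hill_inverse needs Y in (0,1) and positive parameters",
            "hemolig_error_domain")
  P50 * (Y / (1 - Y))^(1 / n)
}

# Hill-plot (log[Y/(1-Y)] vs log pO2) regression; used only to initialise the
# nonlinear fit, never as the estimator (linearisation distorts the error
# structure of Y)
hill_plot_init <- function(pO2, Y) {
  eps <- 1e-6
  Yc <- pmin(pmax(Y, eps), 1 - eps)
  lg <- log10(Yc / (1 - Yc))
  lp <- log10(pO2)
  fit <- lm(lg ~ lp)
  n0 <- unname(coef(fit)[2L])
  # P50: where the Hill plot crosses 0
  P50_0 <- 10^(-unname(coef(fit)[1L]) / n0)
  if (!is.finite(n0) || n0 <= 0) n0 <- 1
  if (!is.finite(P50_0) || P50_0 <= 0) P50_0 <- exp(mean(log(pO2)))
  list(P50 = min(max(P50_0, 1e-3), 1000), n = min(max(n0, 0.3), 6))
}

#' Fit the Hill equation to an equilibrium curve
#'
#' Nonlinear least squares on the untransformed saturation scale
#' (Levenberg-Marquardt), initialised from the Hill-plot regression, with
#' bounds P50 in (0, 1000] Torr and n in [0.3, 6]. Standard errors come from
#' the local curvature (the estimated covariance of the fit).
#'
#' @param curve an [hb_equilibrium_curve()], with at least 3 points strictly
#'   inside (0, 1).
#' @return An object of class `"hb_hill_fit"`: list with `P50`, `nH`, `se_P50`,
#'   `se_nH`, `rss`, `converged`, `extrapolated` (TRUE when all points lie on
#'   one side of Y = 0.5, with a warning), and the input `curve`.
#' @examples
#' cur <- simulate_equilibrium_curve(P50 = 14.4, n = 1.8, steps = 5,
#'                                   noise_sd = 0, seed = 1)
#' fit_hill(cur)
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "hb_equilibrium_curve"))
  p <- curve$pO2_torr; Y <- curve$saturation
  inside <- Y > 0 & Y < 1
  if (sum(inside) < 3L)
    hl_stop("need at least 3 points with saturation strictly inside (0, 1)",
            "hemolig_error_input")
  p <- p[inside]; Y <- Y[inside]
  init <- hill_plot_init(p, Y)
  df <- data.frame(p = p, Y = Y)
  fit <- tryCatch(
    minpack.lm::nlsLM(Y ~ p^n / (P50^n + p^n), data = df,
                      start = list(P50 = init$P50, n = init$n),
                      lower = c(P50 = 1e-6, n = 0.3),
                      upper = c(P50 = 1000, n = 6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      hl_stop(paste0("Hill fit failed to converge: ", conditionMessage(e),
                     sprintf(" (init P50=%.3g, n=%.3g)", init$P50, init$n)),
              "hemolig_error_fit_failure"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  extrap <- all(Y < 0.5) || all(Y > 0.5)
  if (extrap)
    hl_warn("all saturation points on one side of 0.5; P50 is extrapolated",
            "hemolig_warning_extrapolated_p50")
  structure(list(P50 = unname(est["P50"]), nH = unname(est["n"]),
                 se_P50 = unname(se[1L]), se_nH = unname(se[2L]),
                 rss = sum(residuals(fit)^2),
                 converged = fit$convInfo$isConv,
                 extrapolated = extrap,
                 curve = curve),
            class = "hb_hill_fit")
}

#' @export
print.hb_hill_fit <- function(x, ...) {
  cat(sprintf("<hb_hill_fit> P50 = %.3f +/- %.3f Torr, nH = %.3f +/- %.3f (RSS %.3g)%s\n",
              x$P50, x$se_P50, x$nH, x$se_nH, x$rss,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

# millimolar extinction coefficients used for heme quantification
.heme_extinction <- list(
  `CO-ferrous` = list(wavelengths = c(540, 569), eps_mM = 13.4),
  generic      = list(wavelengths = 405,         eps_mM = 150)
)

#' Heme concentration from absorbance
#'
#' Beer-Lambert estimate on a heme basis. For `species = "CO-ferrous"` the
#' absorbances at 540 and 569 nm are averaged and divided by the millimolar
#' extinction coefficient 13.4 mM^-1 cm^-1; for `species = "generic"` the
#' Soret absorbance at 405 nm is divided by 150 mM^-1 cm^-1.
#'
#' @param absorbances named numeric: absorbance (AU) keyed by wavelength (nm),
#'   e.g. `c("540" = 0.134, "569" = 0.134)`.
#' @param species `"CO-ferrous"` or `"generic"`.
#' @param pathlength_cm optical pathlength in cm (default 1).
#' @return Heme concentration in mM.
#' @examples
#' heme_concentration(c("540" = 0.134, "569" = 0.134), "CO-ferrous")  # 0.01 mM
#' @export
heme_concentration <- function(absorbances,
                               species = c("CO-ferrous", "generic"),
                               pathlength_cm = 1) {
  species <- match.arg(species)
  spec <- .heme_extinction[[species]]
  need <- as.character(spec$wavelengths)
  if (is.null(names(absorbances)) || !all(need %in% names(absorbances)))
    hl_stop(sprintf("absorbances must include wavelength(s) %s nm",
                    paste(need, collapse = ", ")),
            "hemolig_error_input")
  if (pathlength_cm <= 0)
    hl_stop("pathlength must be positive", "hemolig_error_domain")
  A <- mean(as.numeric(absorbances[need]))
  A / (spec$eps_mM * pathlength_cm)
}

#' Convert absorbance steps at 436 nm to fractional saturation
#'
#' Deoxygenation is monitored at 436 nm (a deoxy-sensitive wavelength); with
#' endpoint absorbances for the fully deoxygenated and fully oxygenated
#' states supplied, each step absorbance maps linearly onto saturation.
#'
#' @param A436 absorbances at 436 nm at each pO2 step.
#' @param A_deoxy absorbance of the fully deoxygenated endpoint.
#' @param A_oxy absorbance of the fully oxygenated endpoint.
#' @return Fractional saturations in [0, 1] (values clipped to the endpoints
#'   raise an error if outside by more than 5% of the span).
#' @export
saturation_from_A436 <- function(A436, A_deoxy, A_oxy) {
  span <- A_deoxy - A_oxy
  if (abs(span) < .Machine$double.eps)
    hl_stop("endpoint absorbances must differ", "hemolig_error_input")
  Y <- (A_deoxy - A436) / span
  if (any(Y < -0.05) || any(Y > 1.05))
    hl_stop("absorbance outside the endpoint span; check endpoints",
            "hemolig_error_out_of_range")
  pmin(pmax(Y, 0), 1)
}
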