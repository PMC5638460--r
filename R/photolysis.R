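#' CO-rebinding model: two stretched exponentials plus two exponentials
#'
#' Parameterisation of a nanosecond flash-photolysis rebinding decay:
#' two stretched-exponential geminate components (rebinding from inside the
#' protein matrix, CO-concentration independent) and two exponential
#' bimolecular components ascribed to the fast-rebinding R and slow-rebinding
#' T quaternary states,
#'
#'   N(t) = sum_i A_i exp(-(t/tau_i)^beta_i) + A_R exp(-k_R t) + A_T exp(-k_T t)
#'
#' @param geminate data frame with columns `amplitude` (>= 0), `tau_s` (> 0)
#'   and `beta` (in (0, 1]); one or two rows.
#' @param A_R,A_T bimolecular amplitudes, >= 0.
#' @param k_R,k_T apparent bimolecular rates in s^-1, > 0; the R state must
#'   rebind faster (`k_R > k_T`); pass `relabel = TRUE` to swap automatically.
#' @param relabel swap R/T labels if `k_R < k_T` (default FALSE: error).
#' @return An object of class `"hb_rebinding_model"`.
#' @export
hb_rebinding_model <- function(geminate, A_R, k_R, A_T, k_T,
                               relabel = FALSE) {
  geminate <- as.data.frame(geminate)
  need <- c("amplitude", "tau_s", "beta")
  if (!all(need %in% names(geminate)))
    hl_stop("geminate needs columns amplitude, tau_s, beta",
            "hemolig_error_input")
  if (nrow(geminate) < 1L || nrow(geminate) > 2L)
    hl_stop("one or two geminate components expected", "hemolig_error_input")
  if (any(geminate$amplitude < 0) || any(geminate$tau_s <= 0) ||
      any(geminate$beta <= 0) || any(geminate$beta > 1))
    hl_stop("geminate parameters out of range (A >= 0, tau > 0, beta in (0,1])",
            "hemolig_error_domain")
  if (A_R < 0 || A_T < 0 || k_R <= 0 || k_T <= 0)
    hl_stop("bimolecular parameters out of range", "hemolig_error_domain")
  if (k_R < k_T) {
    if (!relabel)
      hl_stop("R state must rebind faster than T (k_R > k_T); set relabel = TRUE to swap",
              "hemolig_error_input")
    tmp <- A_R; A_R <- A_T; A_T <- tmp
    tmp <- k_R; k_R <- k_T; k_T <- tmp
  }
  structure(list(geminate = geminate[need], A_R = A_R, k_R = k_R,
                 A_T = A_T, k_T = k_T),
            class = "hb_rebinding_model")
}

#' @export
print.hb_rebinding_model <- function(x, ...) {
  cat("<hb_rebinding_model>\n  geminate:\n")
  for (i in seq_len(nrow(x$geminate)))
    cat(sprintf("    A=%.4f tau=%.3g s beta=%.3f\n",
                x$geminate$amplitude[i], x$geminate$tau_s[i], x$geminate$beta[i]))
  cat(sprintf("  R: A=%.4f k=%.4g s^-1 | T: A=%.4f k=%.4g s^-1\n",
              x$A_R, x$k_R, x$A_T, x$k_T))
  invisible(x)
}

total_amplitude <- function(model)
  sum(model$geminate$amplitude) + model$A_R + model$A_T

#' Evaluate a rebinding model
#'
#' @param t times in seconds, >= 0; vectorised.
#' @param model an [hb_rebinding_model()].
#' @return N(t), the fraction of deoxy (unliganded) molecules; equals the sum
#'   of all amplitudes at t = 0 and is non-increasing in t.
#' @export
model_eval <- function(t, model) {
  stopifnot(inherits(model, "hb_rebinding_model"))
  if (any(t < 0)) hl_stop("negative time", "hemolig_error_domain")
  out <- model$A_R * exp(-model$k_R * t) + model$A_T * exp(-model$k_T * t)
  for (i in seq_len(nrow(model$geminate))) {
    g <- model$geminate[i, ]
    out <- out + g$amplitude * exp(-(t / g$tau_s)^g$beta)
  }
  out
}

#' Photolysis trace
#'
#' A normalised CO-rebinding decay: N(t), the deoxy fraction after the laser
#' pulse, on a (typically log-spaced) time grid spanning nanoseconds to
#' seconds, with the CO partial pressure the sample was equilibrated with.
#'
#' @param times_s times in seconds, strictly increasing.
#' @param N deoxy fraction, finite, in [0, 1.05] (small noise overshoots above
#'   1 are tolerated).
#' @param CO_atm CO partial pressure in atm, > 0.
#' @param condition an [hb_condition()].
#' @return An object of class `"hb_photolysis_trace"`.
#' @export
hb_photolysis_trace <- function(times_s, N, CO_atm,
                                condition = hb_condition()) {
  times_s <- as.numeric(times_s); N <- as.numeric(N)
  if (length(times_s) != length(N))
    hl_stop("times and N must have equal length", "hemolig_error_input")
  if (any(diff(times_s) <= 0))
    hl_stop("times must be strictly increasing", "hemolig_error_input")
  if (any(!is.finite(N)))
    hl_stop("N must be finite", "hemolig_error_input")
  if (any(N < -0.05) || any(N > 1.05))
    hl_stop("N outside [0, 1.05]", "hemolig_error_input")
  if (!is.finite(CO_atm) || CO_atm <= 0)
    hl_stop("CO pressure must be positive", "hemolig_error_input")
  stopifnot(inherits(condition, "hb_condition"))
  structure(list(times_s = times_s, N = N, CO_atm = CO_atm,
                 condition = condition),
            class = "hb_photolysis_trace")
}

#' @export
print.hb_photolysis_trace <- function(x, ...) {
  cat(sprintf("<hb_photolysis_trace> %d points, %.3g-%.3g s, %.2g atm CO\n",
              length(x$times_s), min(x$times_s), max(x$times_s), x$CO_atm))
  invisible(x)
}

# default aqueous CO solubility (Henry) table, M per atm
.co_solubility_default <- data.frame(
  temperature_C = c(15, 20, 25),
  solubility_M_per_atm = c(1.13e-3, 1.04e-3, 9.8e-4)
)

#' Dissolved CO concentration from partial pressure
#'
#' Henry's-law conversion using an aqueous CO solubility table (default
#' entries at 15, 20 and 25 C; the 25 C solubility is 9.8e-4 M/atm), linearly
#' interpolated in temperature within the table range.
#'
#' @param pressure_atm CO partial pressure in atm, in (0, 1.2].
#' @param temperature_K absolute temperature in K; must fall inside the
#'   table's temperature range.
#' @param table override solubility table: data frame with columns
#'   `temperature_C` and `solubility_M_per_atm`.
#' @return CO concentration in mol/L.
#' @examples
#' co_concentration(1, 298.15)    # ~9.8e-4 M
#' co_concentration(0.1, 298.15)  # one tenth of that
#' @export
co_concentration <- function(pressure_atm, temperature_K = 298.15,
                             table = NULL) {
  if (is.null(table)) table <- .co_solubility_default
  if (any(pressure_atm <= 0) || any(pressure_atm > 1.2))
    hl_stop("CO pressure must lie in (0, 1.2] atm", "hemolig_error_domain")
  tC <- temperature_K - 273.15
  if (tC < min(table$temperature_C) || tC > max(table$temperature_C))
    hl_stop(sprintf("temperature %.1f C outside solubility table range [%g, %g] C",
                    tC, min(table$temperature_C), max(table$temperature_C)),
            "hemolig_error_out_of_range")
  s <- approx(table$temperature_C, table$solubility_M_per_atm, xout = tC)$y
  pressure_atm * s
}

# ---- fitting machinery -----------------------------------------------------

# parameter packing for nls.lm: rates/lifetimes in log10, amplitudes and beta
# raw, with box bounds that separate the geminate and bimolecular phases and
# prevent label swapping
.pack_model <- function(model) {
  g <- model$geminate
  p <- c()
  for (i in seq_len(nrow(g)))
    p <- c(p, setNames(c(g$amplitude[i], log10(g$tau_s[i]), g$beta[i]),
                       paste0(c("A_g", "ltau_g", "beta_g"), i)))
  c(p, A_R = model$A_R, lk_R = log10(model$k_R),
    A_T = model$A_T, lk_T = log10(model$k_T))
}

.unpack_model <- function(p, n_gem) {
  g <- data.frame(amplitude = numeric(n_gem), tau_s = numeric(n_gem),
                  beta = numeric(n_gem))
  for (i in seq_len(n_gem)) {
    g$amplitude[i] <- p[[paste0("A_g", i)]]
    g$tau_s[i] <- 10^p[[paste0("ltau_g", i)]]
    g$beta[i] <- p[[paste0("beta_g", i)]]
  }
  hb_rebinding_model(g, A_R = p[["A_R"]], k_R = 10^p[["lk_R"]],
                     A_T = p[["A_T"]], k_T = 10^p[["lk_T"]],
                     relabel = TRUE)
}

.model_bounds <- function(n_gem) {
  lo <- c(); hi <- c()
  for (i in seq_len(n_gem)) {
    lo <- c(lo, setNames(c(0, log10(1e-9), 0.3),
                         paste0(c("A_g", "ltau_g", "beta_g"), i)))
    hi <- c(hi, setNames(c(1.5, log10(1e-4), 1.0),
                         paste0(c("A_g", "ltau_g", "beta_g"), i)))
  }
  list(lower = c(lo, A_R = 0, lk_R = 0, A_T = 0, lk_T = 0),
       upper = c(hi, A_R = 1.5, lk_R = 6, A_T = 1.5, lk_T = 6))
}

# two-exponential least squares on the bimolecular tail, started from a
# deterministic grid of rate pairs; returns the best (A_R, k_R, A_T, k_T)
init_bimolecular_tail <- function(t, N, bim_total) {
  k_mid <- {
    t_half <- t[which.min(abs(N - bim_total / 2))]
    min(max(log(2) / max(t_half, 1e-6), 2), 5e5)
  }
  starts <- list(c(2, 0.5), c(4, 0.25), c(8, 1), c(1, 1 / 8), c(16, 4))
  best <- NULL
  for (s in starts) {
    p0 <- c(A_R = 0.5 * bim_total, lk_R = log10(min(k_mid * s[1L], 9e5)),
            A_T = 0.5 * bim_total, lk_T = log10(max(k_mid * s[2L], 1.5)))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = c(0, 0, 0, 0), upper = c(1.5, 6, 1.5, 6),
        fn = function(p) N - (p[["A_R"]] * exp(-10^p[["lk_R"]] * t) +
                                p[["A_T"]] * exp(-10^p[["lk_T"]] * t)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  p <- best$par
  list(A_R = p[["A_R"]], k_R = 10^p[["lk_R"]],
       A_T = p[["A_T"]], k_T = 10^p[["lk_T"]])
}

# deterministic heuristic initialiser: geminate from the early decades, the
# bimolecular pair from a two-exponential fit of the tail
auto_init_rebinding <- function(trace, n_stretched = 2L) {
  t <- trace$times_s; N <- trace$N
  N0 <- N[1L]
  # plateau between geminate (< ~1 us) and bimolecular (> ~100 us) phases
  i_plat <- which.min(abs(t - 1e-5))
  N_plat <- N[i_plat]
  gem_total <- max(N0 - N_plat, 0.01)
  bim_total <- max(N_plat, 0.05)
  tail <- t >= 2e-5
  bim <- init_bimolecular_tail(t[tail], N[tail], bim_total)
  gem <- data.frame(
    amplitude = rep(gem_total / n_stretched, n_stretched),
    tau_s = if (n_stretched == 2L) c(1e-7, 1e-6) else 3e-7,
    beta = rep(0.8, n_stretched))
  hb_rebinding_model(gem,
                     A_R = max(bim$A_R, 1e-3), k_R = min(max(bim$k_R, 2), 9e5),
                     A_T = max(bim$A_T, 1e-3), k_T = min(max(bim$k_T, 1.5), 9e5),
                     relabel = TRUE)
}

#' Fit a rebinding model to one photolysis trace
#'
#' Levenberg-Marquardt least squares on the supplied samples (uniform weights;
#' traces should be log-spaced in time so all nine decades carry comparable
#' leverage). Lifetimes and rates are fitted on a log10 scale within bounds
#' that keep the geminate (tau in [1e-9, 1e-4] s) and bimolecular (apparent
#' rate in [1, 1e6] s^-1) phases separated; beta is bounded to [0.3, 1].
#' R/T identification is enforced by relabelling so that k_R > k_T.
#'
#' @param trace an [hb_photolysis_trace()] with >= 50 samples spanning at
#'   least 5 time decades.
#' @param init an [hb_rebinding_model()] starting point; when NULL a
#'   deterministic heuristic initialiser is used.
#' @param n_stretched number of stretched geminate components (2, or 1 for
#'   low-SNR traces).
#' @return The fitted `hb_rebinding_model`, with attributes `converged`,
#'   `rss`, `se` (per-parameter standard errors on the packed scale) and
#'   `boundary_warning`.
#' @export
fit_trace <- function(trace, init = NULL, n_stretched = 2L) {
  stopifnot(inherits(trace, "hb_photolysis_trace"))
  t <- trace$times_s; N <- trace$N
  if (length(t) < 50L)
    hl_stop("need at least 50 samples", "hemolig_error_input")
  if (log10(max(t) / min(t)) < 5)
    hl_stop("trace must span at least 5 time decades", "hemolig_error_input")
  if (is.null(init)) init <- auto_init_rebinding(trace, n_stretched)
  n_gem <- nrow(init$geminate)
  p0 <- .pack_model(init)
  b <- .model_bounds(n_gem)
  p0 <- pmin(pmax(p0, b$lower), b$upper)
  resid_fn <- function(p) {
    m <- .unpack_model(as.list(p), n_gem)
    N - model_eval(t, m)
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = b$lower, upper = b$upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 100000,
                              ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 0L || fit$info == 5L)
    hl_stop(sprintf("rebinding fit did not converge (info %d): %s",
                    fit$info, fit$message),
            "hemolig_error_fit_failure")
  p <- fit$par
  at_bound <- any(abs(p[grep("^beta_g", names(p))] - 0.3) < 1e-6) ||
    any(abs(p[grep("^beta_g", names(p))] - 1.0) < 1e-9 &
        abs(p0[grep("^beta_g", names(p0))] - 1.0) > 1e-9)
  if (at_bound)
    hl_warn("a stretching exponent is pinned at its bound",
            "hemolig_warning_beta_boundary")
  model <- .unpack_model(as.list(p), n_gem)
  # single-phase traces: when one bimolecular amplitude is negligible its
  # fitted rate is meaningless, so the dominant component is reported as R
  # (the stray keeps its amplitude in the T slot at a nominal slower rate)
  bim <- model$A_R + model$A_T
  if (bim > 0 && model$A_R < 0.01 * bim) {
    model <- hb_rebinding_model(model$geminate,
                                A_R = model$A_T, k_R = model$k_T,
                                A_T = model$A_R, k_T = model$k_T / 4)
  }
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) *
                        fit$deviance / max(length(t) - length(p), 1L)),
                 error = function(e) rep(NA_real_, length(p)))
  attr(model, "converged") <- TRUE
  attr(model, "rss") <- fit$deviance
  attr(model, "se") <- se
  attr(model, "boundary_warning") <- at_bound
  model
}

#' Global fit of photolysis traces across CO concentrations and effectors
#'
#' Fits all traces simultaneously with the rate parameters shared: geminate
#' lifetimes/stretches and the bimolecular rate constants kon_R and kon_T are
#' common to every trace, while the apparent bimolecular rates of each trace
#' are constrained to kon * [CO] for that trace's CO concentration, and all
#' amplitudes are free per trace (allosteric effectors such as ATP change the
#' R/T partitioning, not the rate constants).
#'
#' @param traces list of [hb_photolysis_trace()] sharing temperature and pH.
#' @param init an [hb_rebinding_model()] used to start the shared parameters
#'   (apparent rates interpreted at the first trace's [CO]); default: the
#'   heuristic initialiser on the first trace.
#' @param n_stretched number of geminate components.
#' @param share_geminate share the geminate lifetimes and stretches across
#'   traces (default TRUE); with FALSE only the bimolecular rate constants
#'   are shared and each trace keeps its own geminate shape.
#' @param solubility_table optional CO solubility override for
#'   [co_concentration()].
#' @return A list of fitted `hb_rebinding_model` (one per trace, same order),
#'   with attributes `kon_R`, `kon_T` (M^-1 s^-1), `CO_M` (per-trace
#'   concentrations), `rss` and `converged`.
#' @export
global_fit <- function(traces, init = NULL, n_stretched = 2L,
                       share_geminate = TRUE, solubility_table = NULL) {
  if (inherits(traces, "hb_photolysis_trace")) traces <- list(traces)
  if (!length(traces) ||
      !all(vapply(traces, inherits, logical(1), "hb_photolysis_trace")))
    hl_stop("traces must be hb_photolysis_trace objects", "hemolig_error_input")
  temps <- vapply(traces, function(x) x$condition$temperature_K, numeric(1))
  pHs <- vapply(traces, function(x) x$condition$pH, numeric(1))
  if (diff(range(temps)) > 1e-9 || diff(range(pHs)) > 1e-9)
    hl_stop("traces must share temperature and pH", "hemolig_error_input")
  if (length(traces) == 1L) {
    m <- fit_trace(traces[[1L]], init = init, n_stretched = n_stretched)
    CO <- co_concentration(traces[[1L]]$CO_atm, temps[1L], solubility_table)
    kon <- bimolecular_constants(m, CO)
    return(structure(list(m), kon_R = kon[["kon_R"]], kon_T = kon[["kon_T"]],
                     CO_M = CO, rss = attr(m, "rss"), converged = TRUE))
  }
  CO <- vapply(traces, function(x)
    co_concentration(x$CO_atm, x$condition$temperature_K, solubility_table),
    numeric(1))
  # initialise from independent per-trace fits (deterministic); shared
  # blocks start from the first trace, kon from the geometric mean across
  # traces of the per-trace apparent rates over [CO]
  nt <- length(traces)
  if (is.null(init)) {
    mlist <- lapply(seq_len(nt), function(j)
      suppressWarnings(fit_trace(traces[[j]], n_stretched = n_stretched)))
    init <- mlist[[1L]]
    kon_R0 <- exp(mean(log(vapply(seq_len(nt), function(j)
      mlist[[j]]$k_R / CO[j], numeric(1)))))
    kon_T0 <- exp(mean(log(vapply(seq_len(nt), function(j)
      mlist[[j]]$k_T / CO[j], numeric(1)))))
  } else {
    mlist <- rep(list(init), nt)
    kon_R0 <- init$k_R / CO[1L]
    kon_T0 <- init$k_T / CO[1L]
  }
  n_gem <- nrow(init$geminate)
  # shared block: log10 kon pair, plus the geminate shapes when shared;
  # per-trace block: amplitudes (and geminate shapes when not shared)
  gem_suffix <- function(j) if (share_geminate) "" else paste0("_t", j)
  gem0 <- function(m, suffix) unlist(lapply(seq_len(n_gem), function(i)
    setNames(c(log10(m$geminate$tau_s[i]), m$geminate$beta[i]),
             paste0(c("ltau_g", "beta_g"), i, suffix))))
  shared0 <- c(lkon_R = log10(kon_R0), lkon_T = log10(kon_T0))
  if (share_geminate) shared0 <- c(gem0(init, ""), shared0)
  amp0 <- unlist(lapply(seq_len(nt), function(j) {
    m <- mlist[[j]]
    p <- setNames(c(m$geminate$amplitude, m$A_R, m$A_T),
                  paste0(c(paste0("A_g", seq_len(n_gem)), "A_R", "A_T"),
                         "_t", j))
    if (!share_geminate) p <- c(p, gem0(m, paste0("_t", j)))
    p
  }))
  p0 <- c(shared0, amp0)
  gem_lo <- rep(c(log10(1e-9), 0.3), n_gem)
  gem_hi <- rep(c(log10(1e-4), 1.0), n_gem)
  lo <- c(lkon_R = 2, lkon_T = 2)
  hi <- c(lkon_R = 10, lkon_T = 10)
  lo <- c(lo, setNames(rep(0, nt * (n_gem + 2L)),
                       grep("^A_", names(amp0), value = TRUE)))
  hi <- c(hi, setNames(rep(1.5, nt * (n_gem + 2L)),
                       grep("^A_", names(amp0), value = TRUE)))
  gem_names <- grep("^(ltau|beta)_g", names(p0), value = TRUE)
  n_gem_blocks <- length(gem_names) / (2L * n_gem)
  lo <- c(lo, setNames(rep(gem_lo, n_gem_blocks), gem_names))
  hi <- c(hi, setNames(rep(gem_hi, n_gem_blocks), gem_names))
  lo <- lo[names(p0)]; hi <- hi[names(p0)]
  p0 <- pmin(pmax(p0, lo), hi)
  build_models <- function(p) {
    p <- as.list(p)
    lapply(seq_len(nt), function(j) {
      sfx <- gem_suffix(j)
      g <- data.frame(
        amplitude = vapply(seq_len(n_gem), function(i)
          p[[paste0("A_g", i, "_t", j)]], numeric(1)),
        tau_s = vapply(seq_len(n_gem), function(i)
          10^p[[paste0("ltau_g", i, sfx)]], numeric(1)),
        beta = vapply(seq_len(n_gem), function(i)
          p[[paste0("beta_g", i, sfx)]], numeric(1)))
      hb_rebinding_model(g,
                         A_R = p[[paste0("A_R_t", j)]],
                         k_R = 10^p[["lkon_R"]] * CO[j],
                         A_T = p[[paste0("A_T_t", j)]],
                         k_T = 10^p[["lkon_T"]] * CO[j],
                         relabel = TRUE)
    })
  }
  resid_fn <- function(p) {
    ms <- build_models(p)
    unlist(lapply(seq_len(nt), function(j)
      traces[[j]]$N - model_eval(traces[[j]]$times_s, ms[[j]])))
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lo, upper = hi, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, maxfev = 200000,
                              ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 0L || fit$info == 5L)
    hl_stop(sprintf("global fit did not converge (info %d): %s",
                    fit$info, fit$message),
            "hemolig_error_fit_failure")
  p <- as.list(fit$par)
  models <- build_models(fit$par)
  kon_R <- 10^p[["lkon_R"]]; kon_T <- 10^p[["lkon_T"]]
  if (kon_R < kon_T) { tmp <- kon_R; kon_R <- kon_T; kon_T <- tmp }
  structure(models, kon_R = kon_R, kon_T = kon_T, CO_M = CO,
            rss = fit$deviance, converged = TRUE)
}

#' R/T fractions of the bimolecular phase
#'
#' Percentage of fast (R) and slow (T) rebinding, from the exponential
#' amplitudes normalised by the overall bimolecular amplitude.
#'
#' @param model an [hb_rebinding_model()].
#' @return Named numeric `c(fR, fT)` in percent, summing to 100.
#' @examples
#' m <- hb_rebinding_model(data.frame(amplitude = 0.08, tau_s = 1e-7,
#'                                    beta = 0.8),
#'                         A_R = 0.84, k_R = 900, A_T = 0.16, k_T = 230)
#' rt_fractions(m)  # 84 / 16
#' @export
rt_fractions <- function(model) {
  stopifnot(inherits(model, "hb_rebinding_model"))
  tot <- model$A_R + model$A_T
  if (tot <= 0)
    hl_stop("bimolecular amplitude is zero; R/T fractions undefined",
            "hemolig_error_undefined_fraction")
  fR <- 100 * model$A_R / tot
  c(fR = fR, fT = 100 - fR)
}

#' Bimolecular rate constants from apparent rates
#'
#' kon = apparent rate / [CO] for each quaternary state. The ratio
#' kon_R / kon_T equals k_R / k_T and is independent of the CO concentration.
#'
#' @param model an [hb_rebinding_model()].
#' @param CO_M free CO concentration in mol/L, > 0.
#' @return Named numeric `c(kon_R, kon_T)` in M^-1 s^-1.
#' @export
bimolecular_constants <- function(model, CO_M) {
  stopifnot(inherits(model, "hb_rebinding_model"))
  if (CO_M <= 0) hl_stop("CO concentration must be positive",
                         "hemolig_error_domain")
  c(kon_R = model$k_R / CO_M, kon_T = model$k_T / CO_M)
}

#' Kinetic summary of a fitted rebinding model
#'
#' Table-row analogue per condition: R/T percentages of the bimolecular
#' phase, bimolecular rate constants, and the geminate share of the total
#' amplitude.
#'
#' @param model an [hb_rebinding_model()].
#' @param CO_M CO concentration in mol/L used to convert apparent rates.
#' @param condition an [hb_condition()] attached as metadata.
#' @return An object of class `"hb_kinetic_summary"`.
#' @export
kinetic_summary <- function(model, CO_M, condition = hb_condition()) {
  f <- rt_fractions(model)
  kon <- bimolecular_constants(model, CO_M)
  gem_pct <- 100 * sum(model$geminate$amplitude) / total_amplitude(model)
  structure(list(fR = unname(f["fR"]), fT = unname(f["fT"]),
                 kon_R = unname(kon["kon_R"]), kon_T = unname(kon["kon_T"]),
                 geminate_pct = gem_pct, CO_M = CO_M, condition = condition),
            class = "hb_kinetic_summary")
}

#' @export
print.hb_kinetic_summary <- function(x, ...) {
  cat(sprintf("<hb_kinetic_summary> R %.1f%% / T %.1f%%, kon_R %.3g, kon_T %.3g M^-1 s^-1 (geminate %.1f%%, [CO] %.3g M)\n",
              x$fR, x$fT, x$kon_R, x$kon_T, x$geminate_pct, x$CO_M))
  invisible(x)
}

#' Compare kinetic summaries across two conditions
#'
#' Reports the change in R-state population (percentage points and relative
#' percent) and the kon ratios between two conditions of the same isoform at
#' the same temperature (e.g. with and without ATP or urea).
#'
#' @param summary_a,summary_b two [kinetic_summary()] objects; `b` is treated
#'   as the perturbed condition, changes reported as b relative to a.
#' @return List with `dfR_points`, `dfR_relative_pct`, `kon_R_ratio`,
#'   `kon_T_ratio`.
#' @examples
#' # an R-state population going from 60% to 81% is a 35% relative increase
#' @export
compare_conditions <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "hb_kinetic_summary"),
            inherits(summary_b, "hb_kinetic_summary"))
  ca <- summary_a$condition; cb <- summary_b$condition
  if (abs(ca$temperature_K - cb$temperature_K) > 1e-9 ||
      (nzchar(ca$label) && nzchar(cb$label) && ca$label != cb$label))
    hl_stop("summaries must share isoform and temperature",
            "hemolig_error_input")
  dfR <- summary_b$fR - summary_a$fR
  list(dfR_points = dfR,
       dfR_relative_pct = 100 * dfR / summary_a$fR,
       kon_R_ratio = summary_b$kon_R / summary_a$kon_R,
       kon_T_ratio = summary_b$kon_T / summary_a$kon_T)
}
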