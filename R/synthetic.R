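# Synthetic-data generators. Each one is a pure function of its arguments
# including the seed (the caller's RNG stream is restored on exit), so
# regeneration is bit-reproducible.

#' Generate a Gaussian-band reference basis
#'
#' Builds smooth synthetic reference spectra as sums of Gaussian bands on a
#' 1-nm grid. The default band positions follow the wavelengths that matter
#' for heme spectroscopy in the Soret region: the met Soret near 405 nm, the
#' oxy Soret near 415 nm and a deoxy band near 430 nm (so that 436 nm is
#' deoxy-sensitive). These are synthetic stand-ins for measured reference
#' spectra, adequate for exercising the unmixing machinery, not a model of
#' real heme band shapes.
#'
#' @param peaks named list (one entry per species) of data frames with
#'   columns `center_nm`, `width_nm`, `height_AU`; all centers must lie in
#'   [350, 700] nm. Default: oxy/deoxy/met as described.
#' @param grid wavelength grid in nm (default 380-500 nm at 1 nm).
#' @return An [hb_reference_basis()].
#' @export
make_reference_basis <- function(peaks = NULL, grid = seq(380, 500, by = 1)) {
  if (is.null(peaks)) {
    peaks <- list(
      oxy   = data.frame(center_nm = c(415, 490), width_nm = c(11, 30),
                         height_AU = c(1.00, 0.06)),
      deoxy = data.frame(center_nm = c(430, 480), width_nm = c(14, 35),
                         height_AU = c(0.90, 0.08)),
      met   = data.frame(center_nm = c(405, 470), width_nm = c(13, 40),
                         height_AU = c(1.10, 0.05)))
  }
  if (length(peaks) < 2L)
    hl_stop("need at least two species", "hemolig_error_input")
  centers <- lapply(peaks, function(p) p$center_nm)
  if (any(unlist(centers) < 350) || any(unlist(centers) > 700))
    hl_stop("band centers must lie inside 350-700 nm", "hemolig_error_input")
  key <- vapply(peaks, function(p)
    paste(p$center_nm, p$width_nm, p$height_AU, collapse = ";"), character(1))
  if (anyDuplicated(key))
    hl_stop("identical band specifications across species",
            "hemolig_error_degenerate_basis")
  refs <- lapply(names(peaks), function(nm) {
    p <- peaks[[nm]]
    a <- rowSums(vapply(seq_len(nrow(p)), function(i)
      p$height_AU[i] * exp(-((grid - p$center_nm[i]) / p$width_nm[i])^2 / 2),
      numeric(length(grid))))
    hb_spectrum(grid, a, label = nm)
  })
  names(refs) <- names(peaks)
  basis <- hb_reference_basis(refs)
  B <- basis_matrix(basis)
  nb <- sqrt(colSums(B^2))
  cosim <- crossprod(B) / tcrossprod(nb)
  diag(cosim) <- 0
  if (any(cosim >= 0.999))
    hl_stop("species spectra are indistinguishable (cosine similarity >= 0.999)",
            "hemolig_error_degenerate_basis")
  basis
}

#' Simulate a spectrum as a mixture of basis species
#'
#' Linear mixture of the reference spectra plus a constant offset and
#' additive Gaussian noise; the generating counterpart of [unmix()].
#'
#' @param basis an [hb_reference_basis()].
#' @param coefficients named numeric, one coefficient per reference (missing
#'   names default to 0), >= 0.
#' @param offset constant baseline offset in AU.
#' @param noise_sd Gaussian noise sd in AU (default 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return An [hb_spectrum()] on the basis grid.
#' @export
simulate_spectrum <- function(basis, coefficients, offset = 0, noise_sd = 0,
                              seed = 1L) {
  stopifnot(inherits(basis, "hb_reference_basis"))
  co <- setNames(numeric(length(basis$references)), names(basis$references))
  if (is.null(names(coefficients)) ||
      !all(names(coefficients) %in% names(co)))
    hl_stop("coefficients must be named after basis references",
            "hemolig_error_input")
  if (any(coefficients < 0))
    hl_stop("coefficients must be >= 0", "hemolig_error_input")
  co[names(coefficients)] <- coefficients
  a <- drop(basis_matrix(basis) %*% co) + offset
  if (noise_sd > 0)
    a <- a + with_seed(seed, rnorm(length(a), 0, noise_sd))
  hb_spectrum(basis$grid, a, label = "synthetic mixture")
}

#' Simulate an oxygen-equilibrium curve
#'
#' Saturation steps are placed at evenly spaced target saturations inside
#' `Y_range` (mirroring the 4-6 steps in the ~20-80% range of a thin-layer
#' experiment); pO2 values are solved from the inverse Hill equation so the
#' noiseless points lie exactly on the generating curve, then Gaussian noise
#' is added to Y only.
#'
#' @param P50,n generating Hill parameters, > 0.
#' @param steps number of saturation steps, 4-6 typical (>= 3 accepted).
#' @param Y_range length-2 target saturation range (default c(0.2, 0.8)).
#' @param noise_sd Gaussian sd on Y; must be < 0.25 (larger is non-physical).
#' @param seed RNG seed.
#' @param condition an [hb_condition()].
#' @return An [hb_equilibrium_curve()].
#' @export
simulate_equilibrium_curve <- function(P50, n, steps = 5L,
                                       Y_range = c(0.2, 0.8),
                                       noise_sd = 0.01, seed = 1L,
                                       condition = hb_condition()) {
  if (P50 <= 0 || n <= 0)
    hl_stop("Hill parameters must be positive", "hemolig_error_domain")
  if (steps < 3L)
    hl_stop("need at least 3 steps", "hemolig_error_input")
  if (noise_sd >= 0.25)
    hl_stop("noise sd >= 0.25 is non-physical for a fraction",
            "hemolig_error_input")
  Yt <- seq(min(Y_range), max(Y_range), length.out = steps)
  pO2 <- hill_inverse(Yt, P50, n)
  Y <- Yt
  if (noise_sd > 0) {
    Y <- Y + with_seed(seed, rnorm(steps, 0, noise_sd))
    Y <- pmin(pmax(Y, 1e-4), 1 - 1e-4)
  }
  hb_equilibrium_curve(pO2, Y, condition)
}

#' Simulate a flash-photolysis rebinding trace
#'
#' Evaluates the rebinding model on a log-spaced time grid and adds Gaussian
#' noise. With the bundled scenario presets the model amplitudes sum to 1, so
#' N equals 1 at time zero; the noiseless trace reproduces [model_eval()]
#' exactly at the sampled times.
#'
#' @param model an [hb_rebinding_model()].
#' @param CO_atm CO partial pressure recorded on the trace (the model's
#'   apparent rates are taken as given; use [hb_scenario()] to derive them
#'   from kon and pressure).
#' @param t_range length-2 time span in seconds (default c(1e-8, 1)).
#' @param points_per_decade samples per time decade (default 25, the density
#'   of a typical log-averaged flash-photolysis trace).
#' @param noise_sd Gaussian sd on N (default 0).
#' @param seed RNG seed.
#' @param condition an [hb_condition()].
#' @return An [hb_photolysis_trace()].
#' @export
simulate_photolysis_trace <- function(model, CO_atm = 1,
                                      t_range = c(1e-8, 1),
                                      points_per_decade = 25L,
                                      noise_sd = 0, seed = 1L,
                                      condition = hb_condition()) {
  stopifnot(inherits(model, "hb_rebinding_model"))
  if (length(t_range) != 2L || any(t_range <= 0) || t_range[1L] >= t_range[2L])
    hl_stop("t_range must be an increasing positive pair", "hemolig_error_input")
  ndec <- log10(t_range[2L] / t_range[1L])
  npts <- max(2L, ceiling(ndec * points_per_decade) + 1L)
  t <- 10^seq(log10(t_range[1L]), log10(t_range[2L]), length.out = npts)
  N <- model_eval(t, model)
  if (noise_sd > 0) {
    N <- N + with_seed(seed, rnorm(npts, 0, noise_sd))
    N <- pmin(pmax(N, 0), 1.05)
  }
  hb_photolysis_trace(t, N, CO_atm, condition)
}

#' Simulate a stopped-flow displacement trace
#'
#' Mono-exponential absorbance decay A(t) = A_inf + dA exp(-koff t) with
#' additive Gaussian noise, on a uniform time grid.
#'
#' @param koff decay rate in s^-1, > 0.
#' @param duration_s trace length in seconds, > 0.
#' @param n_samples number of samples (default 200).
#' @param A_inf,dA endpoint absorbance and decay amplitude in AU.
#' @param noise_sd Gaussian sd in AU (default 0).
#' @param seed RNG seed.
#' @param condition an [hb_condition()].
#' @return An [hb_displacement_trace()].
#' @export
simulate_displacement <- function(koff, duration_s, n_samples = 200L,
                                  A_inf = 0.45, dA = 0.10, noise_sd = 0,
                                  seed = 1L, condition = hb_condition()) {
  if (koff <= 0) hl_stop("koff must be positive", "hemolig_error_domain")
  if (duration_s <= 0) hl_stop("duration must be positive",
                               "hemolig_error_input")
  t <- seq(0, duration_s, length.out = n_samples)
  A <- A_inf + dA * exp(-koff * t)
  if (noise_sd > 0) A <- A + with_seed(seed, rnorm(n_samples, 0, noise_sd))
  hb_displacement_trace(t, A, condition)
}

#' Simulate an autoxidation time course
#'
#' Saturating-exponential met-fraction time course
#' f(t) = 1 - exp(-kox t), sampled every `step_min` minutes (default 30, as
#' in a 20-hour spectral series), with optional Gaussian noise. When
#' `as_spectra = TRUE` each timepoint is also rendered as a raw spectrum
#' (1 - f) oxy + f met on the supplied basis, for exercising
#' [met_fraction_timecourse()].
#'
#' @param kox autoxidation rate in min^-1, > 0.
#' @param duration_min total duration in minutes, > 0 (default 1200 = 20 h).
#' @param step_min sampling interval in minutes (default 30).
#' @param noise_sd Gaussian sd on the met fraction (default 0).
#' @param seed RNG seed.
#' @param as_spectra return raw spectra instead of fractions.
#' @param basis reference basis used when `as_spectra = TRUE` (needs `oxy`
#'   and `met` references); default [make_reference_basis()].
#' @param spectra_noise_sd Gaussian sd in AU added to raw spectra.
#' @param condition an [hb_condition()].
#' @return An [hb_autox_series()], or when `as_spectra = TRUE` a list with
#'   `spectra` (list of [hb_spectrum()]), `time_min` and `series` (the
#'   noiseless fraction series).
#' @export
simulate_autoxidation <- function(kox, duration_min = 1200, step_min = 30,
                                  noise_sd = 0, seed = 1L,
                                  as_spectra = FALSE, basis = NULL,
                                  spectra_noise_sd = 0,
                                  condition = hb_condition()) {
  if (kox <= 0) hl_stop("kox must be positive", "hemolig_error_domain")
  if (duration_min <= 0) hl_stop("duration must be positive",
                                 "hemolig_error_input")
  t <- seq(0, duration_min, by = step_min)
  f <- 1 - exp(-kox * t)
  if (!as_spectra) {
    if (noise_sd > 0) {
      f <- f + with_seed(seed, rnorm(length(t), 0, noise_sd))
      f <- pmin(pmax(f, 0), 1)
    }
    return(hb_autox_series(t, f, condition))
  }
  if (is.null(basis)) basis <- make_reference_basis()
  if (!all(c("oxy", "met") %in% names(basis$references)))
    hl_stop("basis must contain 'oxy' and 'met' references",
            "hemolig_error_input")
  spectra <- lapply(seq_along(t), function(i)
    simulate_spectrum(basis,
                      c(oxy = 1 - f[i], met = f[i]),
                      noise_sd = spectra_noise_sd,
                      seed = seed + i))
  list(spectra = spectra, time_min = t,
       series = hb_autox_series(t, f, condition))
}
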