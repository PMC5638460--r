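#' Absorbance spectrum
#'
#' A sampled absorbance spectrum on a strictly increasing wavelength grid.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing.
#' @param absorbances numeric vector of absorbances in AU, same length, finite.
#' @param label free-text label.
#' @return An object of class `"hb_spectrum"`.
#' @examples
#' sp <- hb_spectrum(380:500, exp(-((380:500 - 415) / 15)^2))
#' @export
hb_spectrum <- function(wavelengths, absorbances, label = "") {
  wavelengths <- as.numeric(wavelengths)
  absorbances <- as.numeric(absorbances)
  if (length(wavelengths) != length(absorbances))
    hl_stop("wavelengths and absorbances must have equal length",
            "hemolig_error_input")
  if (length(wavelengths) < 2L)
    hl_stop("a spectrum needs at least two samples", "hemolig_error_input")
  if (any(diff(wavelengths) <= 0))
    hl_stop("wavelengths must be strictly increasing", "hemolig_error_input")
  if (any(!is.finite(absorbances)) || any(!is.finite(wavelengths)))
    hl_stop("spectrum values must be finite", "hemolig_error_input")
  structure(list(wavelengths = wavelengths, absorbances = absorbances,
                 label = as.character(label)),
            class = "hb_spectrum")
}

#' @export
print.hb_spectrum <- function(x, ...) {
  cat(sprintf("<hb_spectrum> %s: %d points, %.1f-%.1f nm, A in [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$absorbances), max(x$absorbances)))
  invisible(x)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto `grid`, which must lie within the wavelength
#' span of the spectrum (no extrapolation).
#'
#' @param spectrum an [hb_spectrum()].
#' @param grid numeric vector of target wavelengths (nm), strictly increasing.
#' @return An `hb_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "hb_spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0))
    hl_stop("grid must be strictly increasing", "hemolig_error_input")
  if (min(grid) < min(spectrum$wavelengths) ||
      max(grid) > max(spectrum$wavelengths))
    hl_stop("grid extends outside the spectrum's wavelength span",
            "hemolig_error_out_of_range")
  a <- approx(spectrum$wavelengths, spectrum$absorbances, xout = grid,
              method = "linear")$y
  hb_spectrum(grid, a, label = spectrum$label)
}

#' Reference basis of heme-species spectra
#'
#' Named reference spectra (at minimum `oxy`, `deoxy`, `met`) sharing one
#' wavelength grid, used by [unmix()].
#'
#' @param ... named `hb_spectrum` objects, or a single named list of them.
#' @return An object of class `"hb_reference_basis"`.
#' @export
hb_reference_basis <- function(...) {
  refs <- list(...)
  if (length(refs) == 1L && is.list(refs[[1L]]) &&
      !inherits(refs[[1L]], "hb_spectrum")) refs <- refs[[1L]]
  if (length(refs) < 2L)
    hl_stop("a reference basis needs at least two species",
            "hemolig_error_input")
  nms <- names(refs)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    hl_stop("references must carry unique non-empty names",
            "hemolig_error_input")
  if (!all(vapply(refs, inherits, logical(1), "hb_spectrum")))
    hl_stop("all references must be hb_spectrum objects", "hemolig_error_input")
  grid <- refs[[1L]]$wavelengths
  same <- vapply(refs, function(s) length(s$wavelengths) == length(grid) &&
                   all(s$wavelengths == grid), logical(1))
  if (!all(same))
    hl_stop("all references must share one wavelength grid",
            "hemolig_error_input")
  structure(list(grid = grid, references = refs),
            class = "hb_reference_basis")
}

#' @export
print.hb_reference_basis <- function(x, ...) {
  cat(sprintf("<hb_reference_basis> %s on %d wavelengths (%.1f-%.1f nm)\n",
              paste(names(x$references), collapse = ", "),
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

basis_matrix <- function(basis) {
  vapply(basis$references, function(s) s$absorbances,
         numeric(length(basis$grid)))
}

#' Decompose a spectrum into reference species
#'
#' Fits the measured spectrum as a nonnegative linear combination of the
#' reference spectra plus a single wavelength-independent baseline offset,
#' minimising the squared residual. The offset is unconstrained and profiled
#' out by mean-centring, after which the species coefficients are the
#' nonnegative least-squares solution of the centred problem. Nonnegativity
#' is imposed as a constraint during the fit (species fractions cannot be
#' negative), not by clipping an unconstrained solution.
#'
#' @param spectrum an [hb_spectrum()] already on the basis grid (use
#'   [resample_to_grid()] first if needed); a fitting window may be applied
#'   with `window`.
#' @param basis an [hb_reference_basis()].
#' @param window optional length-2 numeric, wavelength window (nm) over which
#'   to fit; default the full common grid (the Soret region 380-500 nm when
#'   using [make_reference_basis()] defaults).
#' @return An object of class `"hb_composition"`: list with `coefficients`
#'   (named, >= 0), `offset` (AU), `residual_rms` (AU), `fitted` (numeric).
#' @seealso [saturation()]
#' @export
unmix <- function(spectrum, basis, window = NULL) {
  stopifnot(inherits(spectrum, "hb_spectrum"),
            inherits(basis, "hb_reference_basis"))
  if (length(spectrum$wavelengths) != length(basis$grid) ||
      !all(spectrum$wavelengths == basis$grid))
    hl_stop("spectrum must be resampled to the basis grid before unmixing",
            "hemolig_error_input")
  keep <- rep(TRUE, length(basis$grid))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- basis$grid >= min(window) & basis$grid <= max(window)
  }
  B <- basis_matrix(basis)[keep, , drop = FALSE]
  y <- spectrum$absorbances[keep]
  if (nrow(B) <= ncol(B) + 1L)
    hl_stop("grid must be longer than number of references + 1",
            "hemolig_error_input")
  if (qr(B)$rank < ncol(B))
    hl_stop("degenerate basis: references are linearly dependent",
            "hemolig_error_degenerate_basis")
  Bc <- sweep(B, 2L, colMeans(B))
  if (qr(Bc)$rank < ncol(Bc))
    hl_stop("degenerate basis: references identical up to a constant offset",
            "hemolig_error_degenerate_basis")
  yc <- y - mean(y)
  fit <- pracma::lsqnonneg(Bc, yc)
  coefs <- setNames(fit$x, names(basis$references))
  offset <- mean(y) - sum(colMeans(B) * coefs)
  fitted <- drop(B %*% coefs) + offset
  res <- y - fitted
  structure(list(coefficients = coefs, offset = offset,
                 residual_rms = sqrt(mean(res^2)),
                 fitted = fitted, wavelengths = basis$grid[keep]),
            class = "hb_composition")
}

#' @export
print.hb_composition <- function(x, ...) {
  cat("<hb_composition>\n  coefficients:",
      paste(sprintf("%s=%.4f", names(x$coefficients), x$coefficients),
            collapse = ", "),
      sprintf("\n  offset: %.5f AU, residual RMS: %.3g AU\n",
              x$offset, x$residual_rms))
  invisible(x)
}

#' Fractional oxygen saturation from a species composition
#'
#' Returns oxy / (oxy + deoxy). The met coefficient is deliberately excluded
#' from the denominator: oxidised heme does not bind O2, and oxidation is
#' handled as a separate correction, so saturation refers to the ferrous pool
#' only. The result is invariant under uniform scaling of all coefficients.
#'
#' @param composition an `"hb_composition"` from [unmix()], or a named numeric
#'   vector with elements `oxy` and `deoxy`.
#' @return Fraction in [0, 1].
#' @export
saturation <- function(composition) {
  co <- if (inherits(composition, "hb_composition"))
    composition$coefficients else composition
  if (!all(c("oxy", "deoxy") %in% names(co)))
    hl_stop("composition must contain 'oxy' and 'deoxy' coefficients",
            "hemolig_error_input")
  oxy <- co[["oxy"]]; deoxy <- co[["deoxy"]]
  if (oxy + deoxy <= 0)
    hl_stop("saturation undefined: oxy + deoxy coefficients are zero",
            "hemolig_error_undefined_saturation")
  oxy / (oxy + deoxy)
}
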