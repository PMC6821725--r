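#' Spectral state of a retinal protein
#'
#' A photocycle intermediate (or the ground state) is represented by a
#' Gaussian absorption band in wavelength: its name, absorption maximum,
#' full width at half maximum and peak amplitude.
#'
#' @param name State label, e.g. `"K540"`.
#' @param lambda_max Absorption maximum in nm; must lie in \[330, 730\].
#' @param fwhm Full width at half maximum in nm (> 0). Retinal bands are
#'   broad; 90 nm is a typical value.
#' @param peak_amplitude Peak absorbance (>= 0, dimensionless).
#' @return An object of class `spectral_state`.
#' @seealso [state_spectrum()], [retinal_states()]
#' @export
spectral_state <- function(name, lambda_max, fwhm = 90, peak_amplitude = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lambda_max) || lambda_max < 330 || lambda_max > 730)
    stop("lambda_max must lie within [330, 730] nm")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  if (!is.finite(peak_amplitude) || peak_amplitude < 0)
    stop("peak_amplitude must be non-negative")
  structure(list(name = name, lambda_max = lambda_max, fwhm = fwhm,
                 peak_amplitude = peak_amplitude),
            class = "spectral_state")
}

#' Evaluate a spectral state's Gaussian band on a wavelength grid
#'
#' @param state A [spectral_state()].
#' @param wavelengths Wavelength grid in nm.
#' @return Numeric vector of absorbances.
#' @export
state_spectrum <- function(state, wavelengths) {
  stopifnot(inherits(state, "spectral_state"))
  state$peak_amplitude *
    exp(-4 * log(2) * ((wavelengths - state$lambda_max) / state$fwhm)^2)
}

#' Canonical spectral states of the OLPVRII photocycle
#'
#' Ground state (514 nm) and the K (540 nm), M (410 nm), N (525 nm) and
#' O (550 nm) intermediates. Only the absorption maxima are measured
#' quantities; bandwidths and relative amplitudes are plausible defaults
#' (the M band of microbial rhodopsins is narrower and weaker than the
#' visible bands).
#'
#' @return Named list of [spectral_state()] objects
#'   (`ground`, `K540`, `M410`, `N525`, `O550`).
#' @export
retinal_states <- function() {
  list(
    ground = spectral_state("ground514", 514, fwhm = 90,  peak_amplitude = 1),
    K540   = spectral_state("K540",      540, fwhm = 90,  peak_amplitude = 1),
    M410   = spectral_state("M410",      410, fwhm = 70,  peak_amplitude = 0.8),
    N525   = spectral_state("N525",      525, fwhm = 90,  peak_amplitude = 0.95),
    O550   = spectral_state("O550",      550, fwhm = 95,  peak_amplitude = 1.05)
  )
}

#' Locate a spectral peak by parabolic interpolation
#'
#' Finds the grid maximum of a sampled spectrum and refines its position by
#' fitting a parabola through the three points around it. If the maximum
#' sits on a grid boundary the boundary wavelength is returned and the
#' result flagged.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm), >= 3 points.
#' @param absorbance Absorbance at each wavelength.
#' @return A list with `lambda_max` (nm), `value` (interpolated peak height)
#'   and `at_boundary` (logical).
#' @export
extract_lambda_max <- function(wavelengths, absorbance) {
  stopifnot(length(wavelengths) == length(absorbance),
            length(wavelengths) >= 3, all(diff(wavelengths) > 0))
  i <- which.max(absorbance)
  if (i == 1L || i == length(absorbance)) {
    warning("spectrum maximum at grid boundary; returning boundary wavelength")
    return(list(lambda_max = wavelengths[i], value = absorbance[i],
                at_boundary = TRUE))
  }
  x <- wavelengths[(i - 1):(i + 1)]
  y <- absorbance[(i - 1):(i + 1)]
  # vertex of the parabola through three points
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d2 - d1) / (x[3] - x[1])
  if (a >= 0) {  # degenerate (flat or convex): keep the grid point
    return(list(lambda_max = x[2], value = y[2], at_boundary = FALSE))
  }
  # Newton-form vertex: xv = (x1+x2)/2 - d1/(2a)
  xv <- (x[1] + x[2]) / 2 - d1 / (2 * a)
  yv <- y[1] + d1 * (xv - x[1]) + a * (xv - x[1]) * (xv - x[2])
  list(lambda_max = xv, value = yv, at_boundary = FALSE)
}
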