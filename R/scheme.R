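#' Kinetic intermediate as a mixture of spectral states
#'
#' Resolved kinetic intermediates of a rhodopsin photocycle need not be
#' spectrally pure: each is a fixed mixture of canonical spectral states
#' (fractions summing to one). A spectrally silent transition connects two
#' intermediates of identical mixtures.
#'
#' @param name Intermediate label, e.g. `"P1"`.
#' @param fractions Named numeric vector of state fractions in \[0, 1\];
#'   names must match states supplied to [photocycle_scheme()]; must sum
#'   to 1 within 1e-9.
#' @return An object of class `kinetic_intermediate`.
#' @export
kinetic_intermediate <- function(name, fractions) {
  stopifnot(is.character(name), is.numeric(fractions),
            !is.null(names(fractions)))
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (tolerance 1e-9)")
  structure(list(name = name, fractions = fractions),
            class = "kinetic_intermediate")
}

#' Sequential irreversible photocycle scheme
#'
#' An ordered chain P1 -> P2 -> ... -> Pn -> ground with one lifetime per
#' transition. Occupancies follow the Bateman solution of the irreversible
#' first-order chain ([bateman_concentrations()]); each intermediate's
#' spectrum is its state-fraction mixture.
#'
#' @param intermediates List of [kinetic_intermediate()] in temporal order.
#' @param taus Lifetimes in seconds, one per intermediate transition;
#'   strictly positive.
#' @param states Named list of [spectral_state()] used by the mixtures;
#'   defaults to [retinal_states()].
#' @param ground_state Name (in `states`) of the ground state.
#' @return An object of class `photocycle_scheme`.
#' @export
photocycle_scheme <- function(intermediates, taus, states = retinal_states(),
                              ground_state = "ground") {
  stopifnot(length(intermediates) == length(taus), length(taus) >= 1)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("taus must be strictly positive")
  if (!ground_state %in% names(states))
    stop("ground_state not found among states")
  for (im in intermediates) {
    stopifnot(inherits(im, "kinetic_intermediate"))
    if (!all(names(im$fractions) %in% names(states)))
      stop("intermediate '", im$name, "' references unknown states")
  }
  structure(list(intermediates = intermediates, taus = as.numeric(taus),
                 states = states, ground_state = ground_state),
            class = "photocycle_scheme")
}

#' The seven-intermediate OLPVRII photocycle scheme
#'
#' Sequential scheme with lifetimes 1, 16, 61 and 340 microseconds followed
#' by 10, 25 and 73 ms. P1 is a pure K540-like state; P2-P4 are K540/M410
#' mixtures with growing M content (Schiff-base deprotonation); P5-P7 are
#' M410/N525/O550 mixtures shifting toward O during ground-state recovery.
#' The mixing fractions beyond P1 are modeling assumptions (only the state
#' assignments, not the fractions, are experimentally constrained).
#'
#' @return A [photocycle_scheme()] with seven intermediates.
#' @export
olpvrii_photocycle_scheme <- function() {
  taus <- c(1e-6, 16e-6, 61e-6, 340e-6, 10e-3, 25e-3, 73e-3)
  ints <- list(
    kinetic_intermediate("P1", c(K540 = 1)),
    kinetic_intermediate("P2", c(K540 = 0.70, M410 = 0.30)),
    kinetic_intermediate("P3", c(K540 = 0.40, M410 = 0.60)),
    kinetic_intermediate("P4", c(K540 = 0.15, M410 = 0.85)),
    kinetic_intermediate("P5", c(M410 = 0.55, N525 = 0.25, O550 = 0.20)),
    kinetic_intermediate("P6", c(M410 = 0.30, N525 = 0.35, O550 = 0.35)),
    kinetic_intermediate("P7", c(M410 = 0.10, N525 = 0.30, O550 = 0.60))
  )
  photocycle_scheme(ints, taus)
}

# Spectrum (absorbance on `wavelengths`) of one intermediate of a scheme.
intermediate_spectrum <- function(scheme, index, wavelengths) {
  im <- scheme$intermediates[[index]]
  spec <- numeric(length(wavelengths))
  for (nm in names(im$fractions))
    spec <- spec + im$fractions[[nm]] *
      state_spectrum(scheme$states[[nm]], wavelengths)
  spec
}

#' Default measurement grids
#'
#' Logarithmic time grid with 10 points per decade from 700 ns (the first
#' usable delay after the laser pulse) to 1 s, and a 330-730 nm wavelength
#' grid in 10 nm steps.
#'
#' @return Numeric vector (seconds or nm).
#' @export
#' @rdname default_grids
default_time_grid <- function() {
  10^seq(log10(7e-7), 0, by = 0.1)
}

#' @export
#' @rdname default_grids
default_wavelength_grid <- function() {
  seq(330, 730, by = 10)
}
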