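#' Noise specification for simulated measurements
#'
#' Gaussian i.i.d. noise per data point, reduced by averaging over repeated
#' laser pulses: the effective standard deviation is
#' `sigma / sqrt(n_averages)`.
#'
#' @param sigma Single-acquisition noise standard deviation (>= 0).
#' @param seed Integer RNG seed, or `NULL` for the current RNG stream.
#' @param n_averages Number of averaged acquisitions (>= 1); defaults to
#'   25, the number of laser pulses averaged per trace in the
#'   flash-photolysis measurements this generator emulates.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = NULL, n_averages = 25L) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be non-negative")
  stopifnot(n_averages >= 1)
  structure(list(sigma = sigma, seed = seed,
                 n_averages = as.integer(n_averages)),
            class = "noise_spec")
}

#' Simulate a flash-photolysis transient-absorption matrix
#'
#' Builds \eqn{\Delta A(\lambda, t) = \sum_i [\epsilon_i(\lambda) -
#' \epsilon_g(\lambda)]\, c_i(t)} from the sequential scheme's Bateman
#' occupancies plus Gaussian noise, emulating a flash-photolysis
#' measurement of absorption changes.
#'
#' @param scheme A [photocycle_scheme()].
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param times Strictly increasing time grid (s).
#' @param noise A [noise_spec()].
#' @return An object of class `ta_dataset`: list with `wavelengths`,
#'   `times`, `delta_a` (matrix wavelengths x times) and `n_averages`.
#' @export
gen_photocycle_dataset <- function(scheme,
                                   wavelengths = default_wavelength_grid(),
                                   times = default_time_grid(),
                                   noise = noise_spec()) {
  stopifnot(inherits(scheme, "photocycle_scheme"),
            inherits(noise, "noise_spec"))
  if (length(wavelengths) == 0 || length(times) == 0)
    stop("grids must be nonempty")
  if (any(diff(wavelengths) <= 0) || any(diff(times) <= 0))
    stop("grids must be strictly increasing")
  n <- length(scheme$taus)
  eg <- state_spectrum(scheme$states[[scheme$ground_state]], wavelengths)
  D <- sapply(seq_len(n), function(i)
    intermediate_spectrum(scheme, i, wavelengths) - eg)  # |lambda| x n
  C <- bateman_concentrations(scheme$taus, times)        # n x |t|
  da <- D %*% C
  if (noise$sigma > 0) {
    eff <- noise$sigma / sqrt(noise$n_averages)
    da <- da + with_seed(noise$seed,
                         matrix(rnorm(length(da), sd = eff), nrow(da)))
  }
  ta_dataset(wavelengths, times, da, n_averages = noise$n_averages)
}

#' Transient-absorption dataset container
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param times Strictly increasing time grid (s).
#' @param delta_a Finite matrix `length(wavelengths)` x `length(times)`.
#' @param n_averages Number of averaged acquisitions.
#' @return An object of class `ta_dataset`.
#' @export
ta_dataset <- function(wavelengths, times, delta_a, n_averages = 1L) {
  delta_a <- as.matrix(delta_a)
  stopifnot(nrow(delta_a) == length(wavelengths),
            ncol(delta_a) == length(times))
  if (any(diff(wavelengths) <= 0) || any(diff(times) <= 0))
    stop("grids must be strictly increasing")
  if (!all(is.finite(delta_a))) stop("delta_a must be finite")
  structure(list(wavelengths = as.numeric(wavelengths),
                 times = as.numeric(times), delta_a = delta_a,
                 n_averages = as.integer(n_averages)),
            class = "ta_dataset")
}

# Boltzmann sigmoid: y_low at acidic end, y_high at alkaline end (dx > 0).
boltzmann_curve <- function(ph, pka, dx, y_low, y_high) {
  y_high + (y_low - y_high) / (1 + exp((ph - pka) / dx))
}

#' Simulate a pH titration series of a scalar observable
#'
#' Noiseless values lie exactly on the Boltzmann curve
#' \eqn{y = y_{high} + (y_{low} - y_{high}) / (1 + e^{(pH - pKa)/dx})}.
#'
#' @param pka Midpoint (pH units).
#' @param slope_dx Transition width dx in pH units (nonzero; sign sets the
#'   direction of the transition).
#' @param y_low,y_high Observable values at the acidic / alkaline plateau.
#' @param ph_grid Strictly increasing pH values.
#' @param noise_sigma Gaussian noise s.d. in observable units.
#' @param seed RNG seed (used only when `noise_sigma > 0`).
#' @param observable_kind `"lambda_max"` or `"absorbance_at"`.
#' @return An object of class `titration_series` with fields `ph`,
#'   `observable`, `observable_kind`.
#' @export
gen_titration_series <- function(pka, slope_dx, y_low, y_high, ph_grid,
                                 noise_sigma = 0, seed = NULL,
                                 observable_kind = "lambda_max") {
  if (length(ph_grid) == 0) stop("ph_grid must be nonempty")
  if (any(diff(ph_grid) <= 0)) stop("ph_grid must be strictly increasing")
  if (slope_dx == 0) stop("slope_dx must be nonzero")
  y <- boltzmann_curve(ph_grid, pka, slope_dx, y_low, y_high)
  if (noise_sigma > 0)
    y <- y + with_seed(seed, rnorm(length(y), sd = noise_sigma))
  titration_series(ph_grid, y, observable_kind)
}

#' Titration series container
#'
#' @param ph Strictly increasing pH values.
#' @param observable Observable values (same length as `ph`).
#' @param observable_kind `"lambda_max"` or `"absorbance_at"`.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(ph, observable,
                             observable_kind = c("lambda_max",
                                                 "absorbance_at")) {
  observable_kind <- match.arg(observable_kind)
  stopifnot(length(ph) == length(observable))
  if (any(diff(ph) <= 0)) stop("ph must be strictly increasing")
  structure(list(ph = as.numeric(ph), observable = as.numeric(observable),
                 observable_kind = observable_kind),
            class = "titration_series")
}

#' Simulate pH-dependent absorption spectra
#'
#' Two titration modes mirror the two spectroscopic transitions of a
#' proton-pumping rhodopsin:
#' * `"acceptor"` (acidic branch): a single visible band whose maximum
#'   shifts continuously between `lambda_acid` (548 nm, protonated
#'   counterion) and `lambda_base` (514 nm) along the Boltzmann curve.
#' * `"rsb"` (alkaline branch): the 514 nm band of the protonated Schiff
#'   base loses amplitude along the Boltzmann curve while a 367 nm band of
#'   the deprotonated chromophore grows in its place.
#'
#' @param pka Midpoint of the transition (pH units).
#' @param mode `"acceptor"` or `"rsb"`.
#' @param ph_grid Strictly increasing pH values (>= 5 for downstream fits).
#' @param wavelengths Wavelength grid (nm).
#' @param slope_dx Transition width (pH units, > 0).
#' @param lambda_acid,lambda_base Band maxima at the acidic / alkaline
#'   plateau (acceptor mode).
#' @param noise_sigma Gaussian noise s.d. in absorbance units.
#' @param seed RNG seed.
#' @return List with `ph`, `wavelengths` and `spectra` (matrix
#'   wavelengths x pH, columns named by pH).
#' @export
gen_titration_spectra <- function(pka, mode = c("acceptor", "rsb"),
                                  ph_grid,
                                  wavelengths = default_wavelength_grid(),
                                  slope_dx = 0.3,
                                  lambda_acid = 548, lambda_base = 514,
                                  noise_sigma = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (length(ph_grid) < 2) stop("ph_grid must have at least 2 points")
  if (any(diff(ph_grid) <= 0)) stop("ph_grid must be strictly increasing")
  spectra <- matrix(0, length(wavelengths), length(ph_grid))
  if (mode == "acceptor") {
    centers <- boltzmann_curve(ph_grid, pka, slope_dx, lambda_acid,
                               lambda_base)
    for (j in seq_along(ph_grid)) {
      st <- spectral_state("band", centers[j], fwhm = 90, peak_amplitude = 1)
      spectra[, j] <- state_spectrum(st, wavelengths)
    }
  } else {
    # protonated fraction falls from 1 (acidic) to 0 (alkaline)
    frac <- boltzmann_curve(ph_grid, pka, slope_dx, 1, 0)
    vis <- state_spectrum(spectral_state("ground514", 514, fwhm = 90),
                          wavelengths)
    uv <- state_spectrum(spectral_state("deprot367", 367, fwhm = 60,
                                        peak_amplitude = 0.9),
                         wavelengths)
    for (j in seq_along(ph_grid))
      spectra[, j] <- frac[j] * vis + (1 - frac[j]) * uv
  }
  if (noise_sigma > 0)
    spectra <- spectra + with_seed(
      seed, matrix(rnorm(length(spectra), sd = noise_sigma), nrow(spectra)))
  colnames(spectra) <- format(ph_grid, trim = TRUE)
  list(ph = as.numeric(ph_grid), wavelengths = as.numeric(wavelengths),
       spectra = spectra)
}

#' Simulate a flash-induced photocurrent trace
#'
#' Sum of signed exponential components
#' \eqn{I(t) = \sum_i a_i e^{-t/\tau_i}} plus Gaussian noise. Positive
#' amplitudes model the fast charge-displacement rise, negative ones the
#' capacitive discharge of the membrane system.
#'
#' @param components Two-column matrix or data.frame `(amplitude, tau)`;
#'   taus in seconds, strictly positive.
#' @param times Strictly increasing time grid (s), starting at >= 0.
#' @param noise_sigma Gaussian noise s.d. in current units.
#' @param seed RNG seed.
#' @return An object of class `photocurrent_trace` with `times`, `current`
#'   and `meta$illumination = "flash"`.
#' @export
gen_photocurrent <- function(components, times, noise_sigma = 0,
                             seed = NULL) {
  components <- as.matrix(components)
  stopifnot(ncol(components) == 2)
  a <- components[, 1]; tau <- components[, 2]
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("component taus must be strictly positive")
  if (any(diff(times) <= 0) || times[1] < 0)
    stop("times must be strictly increasing and start at >= 0")
  cur <- as.vector(exp(-outer(times, 1 / tau)) %*% a)
  if (noise_sigma > 0)
    cur <- cur + with_seed(seed, rnorm(length(cur), sd = noise_sigma))
  photocurrent_trace(times, cur)
}

#' Photocurrent trace container
#'
#' @param times Time from flash (s), strictly increasing, start >= 0.
#' @param current Signal values.
#' @param illumination `"flash"` or `"continuous"`.
#' @return An object of class `photocurrent_trace`.
#' @export
photocurrent_trace <- function(times, current,
                               illumination = c("flash", "continuous")) {
  illumination <- match.arg(illumination)
  stopifnot(length(times) == length(current))
  if (any(diff(times) <= 0) || times[1] < 0)
    stop("times must be strictly increasing and start at >= 0")
  structure(list(times = as.numeric(times), current = as.numeric(current),
                 meta = list(illumination = illumination)),
            class = "photocurrent_trace")
}

#' Simulate cylinder-confined particle ensembles with a prescribed
#' axial density
#'
#' Draws, for each frame, `n_particles` i.i.d. positions whose axial
#' coordinate follows the prescribed density profile and whose (x, y)
#' position is uniform over the cylinder cross-section. Emulates the
#' water/ion ensembles used for density-based potential-of-mean-force
#' analysis.
#'
#' @param z_edges Strictly increasing bin edges (Angstrom) of the target
#'   profile.
#' @param density Nonnegative relative density per bin
#'   (`length(z_edges) - 1` values, not all zero).
#' @param cylinder_radius Cylinder radius (Angstrom, > 0).
#' @param n_particles Particles per frame (>= 0).
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed.
#' @param species Particle species label.
#' @return An object of class `particle_samples`: data.frame with columns
#'   `frame`, `x`, `y`, `z` plus attributes `species` and
#'   `cylinder_radius`.
#' @export
gen_pore_particles <- function(z_edges, density, cylinder_radius,
                               n_particles, n_frames, seed = NULL,
                               species = "water") {
  stopifnot(length(density) == length(z_edges) - 1)
  if (any(diff(z_edges) <= 0)) stop("z_edges must be strictly increasing")
  if (any(density < 0)) stop("density must be nonnegative")
  if (sum(density) <= 0) stop("total density must be positive")
  if (cylinder_radius <= 0) stop("cylinder_radius must be positive")
  nb <- length(density)
  widths <- diff(z_edges)
  prob <- density * widths / sum(density * widths)
  ntot <- n_particles * n_frames
  df <- with_seed(seed, {
    if (ntot == 0) {
      data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0))
    } else {
      bins <- sample.int(nb, ntot, replace = TRUE, prob = prob)
      z <- z_edges[bins] + runif(ntot) * widths[bins]
      r <- cylinder_radius * sqrt(runif(ntot))
      th <- runif(ntot, 0, 2 * pi)
      data.frame(frame = rep(seq_len(n_frames), each = n_particles),
                 x = r * cos(th), y = r * sin(th), z = z)
    }
  })
  particle_samples(df, species = species, cylinder_radius = cylinder_radius,
                   n_frames = n_frames)
}

#' Particle-samples container
#'
#' @param df Data frame with columns `frame` and `z` (optionally `x`, `y`).
#' @param species Species label (`"water"`, `"cation"`, `"anion"`).
#' @param cylinder_radius Generating cylinder radius, if known.
#' @param n_frames Total number of frames (some may hold zero particles).
#' @return An object of class `particle_samples`.
#' @export
particle_samples <- function(df, species = "water", cylinder_radius = NA,
                             n_frames = NULL) {
  stopifnot(is.data.frame(df), all(c("frame", "z") %in% names(df)))
  if (nrow(df) > 0 && !all(is.finite(df$z))) stop("positions must be finite")
  if (is.null(n_frames))
    n_frames <- if (nrow(df) > 0) max(df$frame) else 0L
  if (n_frames < 1 && nrow(df) > 0) stop("frame count must be >= 1")
  structure(df, class = c("particle_samples", "data.frame"),
            species = species, cylinder_radius = cylinder_radius,
            n_frames = as.integer(n_frames))
}
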