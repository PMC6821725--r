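#' Reconstruct absolute intermediate spectra under the sequential scheme
#'
#' Given fitted lifetimes, the sequential irreversible scheme fixes the
#' occupancies \eqn{c_i(t)} ([bateman_concentrations()]), and the
#' difference spectra \eqn{d_i(\lambda) = \epsilon_i(\lambda) -
#' \epsilon_g(\lambda)} solve the linear system
#' \eqn{\Delta A(\lambda, t) = \sum_i d_i(\lambda) c_i(t)} in the
#' least-squares sense. Adding the ground spectrum yields absolute
#' intermediate spectra, each labelled by the canonical state nearest its
#' interpolated absorption maximum.
#'
#' @param fit A `global_fit` from [fit_global_exponentials()].
#' @param ds The fitted [ta_dataset()].
#' @param ground_spectrum Ground-state absorbance on `ds$wavelengths`.
#' @param max_condition Refuse reconstruction when the occupancy matrix
#'   condition number exceeds this threshold (default 1e8).
#' @param states Canonical states used for labelling (default
#'   [retinal_states()]).
#' @return An object of class `intermediate_spectra`: `spectra` (matrix
#'   wavelengths x n of absolute spectra), `difference_spectra`,
#'   `lambda_max`, `labels`, `condition_number`, `reconstruction_sse`.
#' @export
sequential_intermediate_spectra <- function(fit, ds, ground_spectrum,
                                            max_condition = 1e8,
                                            states = retinal_states()) {
  stopifnot(inherits(fit, "global_fit"), inherits(ds, "ta_dataset"),
            length(ground_spectrum) == length(ds$wavelengths))
  if (fit$degenerate) stop("cannot reconstruct spectra from a degenerate fit")
  C <- bateman_concentrations(fit$taus, ds$times)     # n x |t|
  kap <- kappa(C, exact = TRUE)
  if (kap > max_condition)
    stop(sprintf(
      "occupancy matrix ill-conditioned (condition number %.3g > %.3g)",
      kap, max_condition))
  qc <- qr(t(C))
  D <- t(qr.coef(qc, t(ds$delta_a)))                  # |lambda| x n
  recon <- D %*% C
  spectra <- D + ground_spectrum
  n <- length(fit$taus)
  lam <- numeric(n); lab <- character(n)
  canon <- vapply(states, function(s) s$lambda_max, numeric(1))
  for (i in seq_len(n)) {
    pk <- extract_lambda_max(ds$wavelengths, spectra[, i])
    lam[i] <- pk$lambda_max
    lab[i] <- names(states)[which.min(abs(canon - pk$lambda_max))]
  }
  colnames(spectra) <- colnames(D) <- paste0("P", seq_len(n))
  structure(list(spectra = spectra, difference_spectra = D,
                 lambda_max = lam, labels = lab,
                 condition_number = kap,
                 reconstruction_sse = sum((ds$delta_a - recon)^2),
                 wavelengths = ds$wavelengths),
            class = "intermediate_spectra")
}

#' Decompose a spectrum into nonnegative fractions of basis states
#'
#' Nonnegative least squares of the spectrum onto the Gaussian bands of the
#' basis states, renormalized to fractions summing to one. Used to express
#' a reconstructed intermediate as a mixture of canonical states (e.g. the
#' K540/M410 mixtures of the microsecond photocycle phase).
#'
#' @param wavelengths Wavelength grid (nm).
#' @param spectrum Absolute spectrum on that grid (not all zero).
#' @param basis Named list of [spectral_state()].
#' @return List with `fractions` (named, summing to 1), `coefficients`
#'   (raw NNLS coefficients) and `residual` (NNLS residual norm).
#' @export
decompose_spectrum <- function(wavelengths, spectrum, basis) {
  stopifnot(length(basis) >= 1, length(wavelengths) == length(spectrum))
  if (all(spectrum == 0)) stop("cannot decompose an all-zero spectrum")
  B <- sapply(basis, function(s) state_spectrum(s, wavelengths))
  nn <- pracma::lsqnonneg(B, as.numeric(spectrum))
  coef <- setNames(nn$x, names(basis))
  tot <- sum(coef)
  frac <- if (tot > 0) coef / tot else coef
  list(fractions = frac, coefficients = coef,
       residual = sqrt(sum((spectrum - B %*% nn$x)^2)))
}
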