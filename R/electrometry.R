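#' Decompose a flash-induced photocurrent into exponential components
#'
#' Fits \eqn{I(t) = \sum_i a_i e^{-t/\tau_i}} to a flash trace using the
#' same variable-projection engine as the photocycle global fit (a trace is
#' a one-wavelength transient matrix). Components are returned sorted by
#' lifetime.
#'
#' @param trace A [photocurrent_trace()] recorded after a laser flash.
#' @param n_components Number of exponential components (>= 1).
#' @param tau_init Optional lifetime start vector (s).
#' @return An object of class `current_fit`: data.frame `components` with
#'   `amplitude`, `tau`, `se_tau` (ascending tau), plus `residual_sse`.
#' @export
fit_current <- function(trace, n_components, tau_init = NULL) {
  stopifnot(inherits(trace, "photocurrent_trace"), n_components >= 1)
  if (trace$meta$illumination != "flash")
    stop("continuous-illumination traces cannot be fitted as flash decays")
  ds <- ta_dataset(wavelengths = 1,
                   times = trace$times,
                   delta_a = matrix(trace$current, nrow = 1))
  fit <- fit_global_exponentials(ds, n_components, tau_init = tau_init)
  comp <- data.frame(amplitude = as.numeric(fit$amplitude_spectra[1, ]),
                     tau = fit$taus, se_tau = fit$se_tau)
  structure(list(components = comp, residual_sse = fit$residual_sse,
                 degenerate = fit$degenerate),
            class = "current_fit")
}

#' Displaced charge per electrogenic component
#'
#' For a capacitively coupled membrane signal, each exponential component
#' displaces charge \eqn{q_i = a_i \tau_i} (the analytic time integral of
#' \eqn{a_i e^{-t/\tau_i}} over \eqn{[0, \infty)}); a purely capacitive
#' signal has zero net charge.
#'
#' @param fit A `current_fit` from [fit_current()].
#' @return List with `charges` (per component, signal x s) and
#'   `net_charge` (their sum).
#' @export
component_charges <- function(fit) {
  stopifnot(inherits(fit, "current_fit"))
  q <- fit$components$amplitude * fit$components$tau
  list(charges = q, net_charge = sum(q))
}

#' Assign photocurrent components to photocycle transitions
#'
#' Each photocurrent lifetime is matched to the photocycle lifetime
#' minimizing \eqn{|\log_{10}(\tau' / \tau)|} and inherits that
#' transition's label. By default the slowest component is excluded from
#' assignment: it reflects the unspecific discharge of the supporting
#' membrane, not a photocycle step.
#'
#' @param current_taus Photocurrent lifetimes (s).
#' @param photocycle_taus Photocycle lifetimes (s).
#' @param labels Transition labels, one per photocycle lifetime.
#' @param exclude_discharge Exclude the largest current lifetime from
#'   assignment (default `TRUE`).
#' @return Data frame with `current_tau`, `matched_tau`, `label`,
#'   `log10_distance`; excluded components carry label `"membrane
#'   discharge"` and `NA` distance.
#' @export
assign_to_photocycle <- function(current_taus, photocycle_taus, labels,
                                 exclude_discharge = TRUE) {
  stopifnot(length(current_taus) >= 1, length(photocycle_taus) >= 1,
            length(labels) == length(photocycle_taus))
  out <- data.frame(current_tau = current_taus,
                    matched_tau = NA_real_,
                    label = NA_character_,
                    log10_distance = NA_real_)
  skip <- if (exclude_discharge && length(current_taus) > 1)
    which.max(current_taus) else integer(0)
  for (i in seq_along(current_taus)) {
    if (i %in% skip) {
      out$label[i] <- "membrane discharge"
      next
    }
    d <- abs(log10(current_taus[i] / photocycle_taus))
    j <- which.min(d)
    out$matched_tau[i] <- photocycle_taus[j]
    out$label[i] <- labels[j]
    out$log10_distance[i] <- d[j]
  }
  out
}
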