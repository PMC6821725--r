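# Variable-projection engine for global multiexponential fitting.
#
# Model: Y(lambda, t) = sum_i A_i(lambda) exp(-t / tau_i).  The amplitude
# spectra A_i are linear given tau, so they are eliminated analytically
# (variable projection): for each candidate tau the exact conditional
# least-squares amplitudes are Y X (X'X)^{-1} with X[t, i] = exp(-t/tau_i),
# and only the n lifetimes are optimized nonlinearly (in log space, so
# positivity holds by construction).

# Exponential design matrix |t| x n.
exp_design <- function(times, taus) {
  exp(-outer(times, 1 / taus))
}

# Conditional-LS amplitudes and residual matrix for fixed tau.
# Returns list(amplitudes |lambda| x n, resid |lambda| x |t|, sse).
varpro_solve <- function(Y, times, taus) {
  X <- exp_design(times, taus)
  qx <- qr(X)
  A <- t(qr.coef(qx, t(Y)))         # |lambda| x n
  A[!is.finite(A)] <- 0             # rank-deficient columns contribute 0
  R <- Y - A %*% t(X)
  list(amplitudes = A, resid = R, sse = sum(R * R))
}

varpro_resid_vec <- function(logtau, Y, times) {
  as.vector(varpro_solve(Y, times, exp(logtau))$resid)
}

# Multistart initial lifetime vectors: log-spaced across the time window,
# plus shifted and compressed variants to escape local minima.
varpro_starts <- function(times, n_exp, n_starts = 8) {
  lo <- log10(min(times)); hi <- log10(max(times))
  base <- function(a, b) 10^seq(a, b, length.out = n_exp)
  shifts <- c(0, -0.4, 0.4, -0.8, 0.8)
  starts <- lapply(shifts, function(s) base(lo + s, hi + s))
  starts <- c(starts,
              list(base(lo + 0.5, hi - 0.5),
                   base(lo - 0.5, hi + 0.5),
                   base(lo + (hi - lo) / 4, hi)))
  starts[seq_len(min(n_starts, length(starts)))]
}

#' Global multiexponential fit of a transient-absorption matrix
#'
#' Fits \eqn{\Delta A(\lambda, t) \approx \sum_{i=1}^{n} A_i(\lambda)
#' e^{-t/\tau_i}} to the whole matrix at once. The amplitude spectra are
#' eliminated analytically (variable projection), so only the n lifetimes
#' are optimized, in log space, by Levenberg-Marquardt from several
#' log-spaced multistart vectors; the best sum of squares wins, ties broken
#' by the lexicographically smaller lifetime vector.
#'
#' @param ds A [ta_dataset()].
#' @param n_exp Number of exponentials (>= 1); `length(ds$times)` must
#'   exceed `2 * n_exp`.
#' @param tau_init Optional lifetime start vector (s); it is added to the
#'   multistart set, so the returned fit is never worse than this start.
#' @param n_starts Number of multistart vectors (default 8).
#' @return An object of class `global_fit`: `taus` (ascending, s),
#'   `amplitude_spectra` (matrix wavelengths x n, columns ordered like
#'   `taus`), `residual_sse`, `dof`, `se_tau` and `covariance_diag`
#'   (per-lifetime variance), `degenerate` flag, plus the grids.
#' @export
fit_global_exponentials <- function(ds, n_exp, tau_init = NULL,
                                    n_starts = 8) {
  stopifnot(inherits(ds, "ta_dataset"), n_exp >= 1)
  Y <- ds$delta_a; times <- ds$times
  if (length(times) <= 2 * n_exp)
    stop("too few time points for ", n_exp, " exponentials (identifiability)")
  if (all(Y == 0)) {
    return(structure(list(taus = rep(NA_real_, n_exp),
                          amplitude_spectra = matrix(0, nrow(Y), n_exp),
                          residual_sse = 0, dof = length(Y),
                          se_tau = rep(NA_real_, n_exp),
                          covariance_diag = rep(NA_real_, n_exp),
                          degenerate = TRUE,
                          wavelengths = ds$wavelengths, times = times),
                     class = "global_fit"))
  }
  starts <- varpro_starts(times, n_exp, n_starts)
  if (!is.null(tau_init)) {
    stopifnot(length(tau_init) == n_exp, all(tau_init > 0))
    starts <- c(list(as.numeric(tau_init)), starts)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(st), fn = varpro_resid_vec,
                         Y = Y, times = times,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- fit$deviance
    cand_tau <- sort(exp(fit$par))
    if (is.null(best) || sse < best$sse * (1 - 1e-12) ||
        (abs(sse - best$sse) <= 1e-12 * best$sse &&
         isTRUE(all(cand_tau <= best$tau)) && any(cand_tau < best$tau))) {
      best <- list(sse = sse, tau = cand_tau, fit = fit)
    }
  }
  if (is.null(best)) stop("all multistarts failed to converge")
  taus <- best$tau
  sol <- varpro_solve(Y, times, taus)
  N <- length(Y)
  p <- n_exp * (nrow(Y) + 1)
  dof <- N - p
  # lifetime covariance from the varpro Jacobian (Gauss-Newton, delta
  # method from log tau back to tau)
  sigma2 <- sol$sse / max(dof, 1)
  J <- numeric_jacobian(function(lt) varpro_resid_vec(lt, Y, times),
                        log(taus))
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) matrix(NA_real_, n_exp, n_exp))
  cov_diag <- diag(cov_log) * taus^2
  structure(list(taus = taus, amplitude_spectra = sol$amplitudes,
                 residual_sse = sol$sse, dof = dof,
                 se_tau = sqrt(pmax(cov_diag, 0)),
                 covariance_diag = cov_diag, degenerate = FALSE,
                 wavelengths = ds$wavelengths, times = times),
            class = "global_fit")
}

# Central-difference Jacobian of a vector-valued function.
numeric_jacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Choose the number of exponentials by a sequential F-test
#'
#' Fits n = 1, 2, ... components and stops when adding one more does not
#' reduce the residual sum of squares significantly (extra-sum-of-squares
#' F-test; one lifetime plus one amplitude spectrum per added component).
#' Returns 0 for data indistinguishable from noise (the one-component fit
#' itself is not significant against the zero model).
#'
#' A candidate order is also rejected when its fitted lifetime vector
#' contains a near-coincident pair (ratio below `min_tau_ratio`): two
#' coincident lifetimes are not separately identifiable — the pair acts as
#' a confluent \eqn{t e^{-t/\tau}} term that soaks up noise beyond what
#' the nominal F-test degrees of freedom account for.
#'
#' @param ds A [ta_dataset()].
#' @param n_max Largest model order to consider (>= 1).
#' @param alpha Significance level of each sequential test (default 0.01).
#' @param n_starts Multistarts per fit (passed to
#'   [fit_global_exponentials()]).
#' @param min_tau_ratio Smallest admissible ratio between adjacent fitted
#'   lifetimes (default 1.5); candidates below it are rejected as
#'   degenerate.
#' @return Integer model order in `0:n_max`.
#' @export
choose_num_exponentials <- function(ds, n_max, alpha = 0.01, n_starts = 8,
                                    min_tau_ratio = 1.5) {
  stopifnot(inherits(ds, "ta_dataset"), n_max >= 1)
  N <- length(ds$delta_a)
  p_of <- function(n) n * (nrow(ds$delta_a) + 1)
  sse <- sum(ds$delta_a^2)   # zero-component model
  n_cur <- 0L
  for (n_try in seq_len(n_max)) {
    if (length(ds$times) <= 2 * n_try) break
    fit <- fit_global_exponentials(ds, n_try, n_starts = n_starts)
    if (fit$degenerate) break
    if (n_try > 1 &&
        any(fit$taus[-1] / fit$taus[-n_try] < min_tau_ratio)) break
    dp <- p_of(n_try) - p_of(n_cur)
    df2 <- N - p_of(n_try)
    if (df2 <= 0) break
    Fstat <- ((sse - fit$residual_sse) / dp) / (fit$residual_sse / df2)
    if (!is.finite(Fstat) || pf(Fstat, dp, df2, lower.tail = FALSE) > alpha)
      break
    n_cur <- n_try
    sse <- fit$residual_sse
  }
  n_cur
}
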