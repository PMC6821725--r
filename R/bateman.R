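#' Bateman occupancies of a sequential irreversible photocycle
#'
#' Closed-form concentrations of the irreversible first-order chain
#' P1 -> P2 -> ... -> Pn -> ground with rate constants \eqn{k_i = 1/\tau_i},
#' initial condition \eqn{c_1(0) = 1}, all others zero:
#' \deqn{c_i(t) = \Big(\prod_{j<i} k_j\Big)
#'   \sum_{j \le i} \frac{e^{-k_j t}}{\prod_{l \le i, l \ne j} (k_l - k_j)}.}
#' Near-equal lifetimes are perturbed by one part in 1e6 instead of taking
#' the confluent limit; the result is numerically indistinguishable.
#'
#' @param taus Lifetimes in seconds (strictly positive).
#' @param times Time points in seconds.
#' @return Matrix `length(taus)` x `length(times)` of occupancies;
#'   rows sum to at most 1 at each time (the deficit is the recovered
#'   ground-state fraction).
#' @export
bateman_concentrations <- function(taus, times) {
  stopifnot(length(taus) >= 1, all(is.finite(taus)), all(taus > 0),
            all(is.finite(times)))
  n <- length(taus)
  k <- 1 / as.numeric(taus)
  # perturb ties so the partial-fraction denominators never vanish
  for (pass in 1:3) {
    for (i in seq_len(n)) {
      while (any(abs(k[-i] - k[i]) < 1e-6 * k[i])) k[i] <- k[i] * (1 + 1e-6)
    }
  }
  out <- matrix(0, n, length(times))
  E <- exp(-outer(k, times))      # n x |t|
  for (i in seq_len(n)) {
    pref <- prod(k[seq_len(i - 1)])
    ki <- k[seq_len(i)]
    for (j in seq_len(i)) {
      denom <- prod(ki[-j] - ki[j])
      if (i == 1) denom <- 1
      out[i, ] <- out[i, ] + pref * E[j, ] / denom
    }
  }
  rownames(out) <- paste0("P", seq_len(n))
  out
}
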