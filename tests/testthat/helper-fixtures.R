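# Shared fixtures: schemes, grids and small oracle helpers.

fig_scheme <- function() olpvrii_photocycle_scheme()

# Single-shot noise level giving the stated signal-to-noise ratio on a
# noiseless dataset (sd relative to the largest absorbance change).
sigma_for_snr <- function(ds, snr) max(abs(ds$delta_a)) / snr

# Two-step irreversible chain A -> B -> C with rates k1, k2:
# closed-form occupancy of B (Bateman oracle used by several tests).
two_step_cB <- function(t, k1, k2) k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))

# Dense normal-equations amplitude oracle: exact conditional LS amplitudes
# for fixed lifetimes, solved by an explicit dense solver.
normal_eq_amplitudes <- function(Y, times, taus) {
  X <- exp(-outer(times, 1 / taus))
  t(solve(crossprod(X), crossprod(X, t(Y))))
}

# Photocurrent component set with zero net displaced charge:
# amplitudes chosen so sum(a_i * tau_i) = 0.
zero_area_components <- function() {
  taus <- c(24e-6, 6e-3, 90e-3, 950e-3)
  a <- c(1, 0.5, -0.2)
  a4 <- -sum(a * taus[1:3]) / taus[4]
  cbind(c(a, a4), taus)
}

rigid_motion <- function(xyz, angles = c(0.3, -0.7, 1.1), shift = c(5, -3, 2)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), sin(angles[1]),
                 0, -sin(angles[1]), cos(angles[1])), 3, 3)
  ry <- matrix(c(cos(angles[2]), 0, -sin(angles[2]), 0, 1, 0,
                 sin(angles[2]), 0, cos(angles[2])), 3, 3)
  rz <- matrix(c(cos(angles[3]), sin(angles[3]), 0,
                 -sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3)
  sweep(as.matrix(xyz) %*% (rx %*% ry %*% rz), 2, shift, "+")
}

apply_rigid_motion <- function(s, angles = c(0.3, -0.7, 1.1),
                               shift = c(5, -3, 2)) {
  xyz <- rigid_motion(as.matrix(s[, c("x", "y", "z")]), angles, shift)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}
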