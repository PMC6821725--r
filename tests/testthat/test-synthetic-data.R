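# Synthetic-data generators: Bateman kinetics, titration curves,
# photocurrents, ideal pentamers and cylinder-confined particle ensembles.

test_that("Bateman occupancies conserve mass and match the two-step closed form", {
  taus <- fig_scheme()$taus
  times <- default_time_grid()
  C <- bateman_concentrations(taus, times)
  # total occupancy never exceeds the initial excitation; deficit is the
  # recovered ground state
  expect_true(all(colSums(C) <= 1 + 1e-9))
  expect_equal(as.numeric(bateman_concentrations(taus, 0)[, 1]),
               c(1, rep(0, 6)), tolerance = 1e-5)
  # n = 1: plain exponential decay
  expect_equal(as.numeric(bateman_concentrations(0.5, c(0, 0.5, 1))),
               exp(-c(0, 0.5, 1) / 0.5), tolerance = 1e-9)
  # n = 2, k1 = 1, k2 = 0.1: second species matches the closed form and
  # peaks at t* = ln(k1/k2) / (k1 - k2)
  tg <- seq(0.01, 30, by = 0.005)
  C2 <- bateman_concentrations(c(1, 10), tg)
  expect_equal(C2[2, ], two_step_cB(tg, 1, 0.1), tolerance = 1e-6)
  t_star <- log(1 / 0.1) / (1 - 0.1)
  expect_equal(tg[which.max(C2[2, ])], t_star, tolerance = 0.01)
})

test_that("Bateman solution agrees with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  taus <- c(2e-6, 5e-5, 8e-4, 3e-3)
  k <- 1 / taus
  times <- default_time_grid()
  rhs <- function(t, y, parms) {
    flows <- parms * y[seq_along(parms)]
    list(c(-flows[1], flows[-length(flows)] - flows[-1]))
  }
  ode <- deSolve::lsoda(c(1, 0, 0, 0), c(0, times), rhs, k,
                        rtol = 1e-10, atol = 1e-12)
  C <- bateman_concentrations(taus, times)
  expect_equal(as.numeric(t(ode[-1, -1])), as.numeric(C), tolerance = 1e-6)
})

test_that("photocycle generator reproduces the flash-photolysis signal structure", {
  scheme <- fig_scheme()
  ds <- gen_photocycle_dataset(scheme)
  expect_equal(dim(ds$delta_a),
               c(length(ds$wavelengths), length(ds$times)))
  # 410 nm trace: rises during the microsecond phase (M formation),
  # decays during the millisecond phase (ground-state recovery)
  tr410 <- ds$delta_a[ds$wavelengths == 410, ]
  i_rise <- ds$times >= 1e-5 & ds$times <= 3.4e-4
  i_decay <- ds$times >= 1e-2 & ds$times <= 7.3e-2
  expect_gt(tr410[max(which(i_rise))], tr410[min(which(i_rise))])
  expect_lt(tr410[max(which(i_decay))], tr410[min(which(i_decay))])
  # signal decays to nothing long after the slowest lifetime (73 ms;
  # t >= 2 s is 27+ lifetimes, so exp(-t/tau) < 2e-12)
  late <- gen_photocycle_dataset(scheme, times = c(2, 3, 5))
  expect_lt(max(abs(late$delta_a)), 1e-6 * max(abs(ds$delta_a)))
  # an intermediate spectrally identical to the ground state is invisible
  st <- retinal_states()
  silent <- photocycle_scheme(list(kinetic_intermediate("P1", c(ground = 1))),
                              taus = 1e-3, states = st)
  expect_equal(max(abs(gen_photocycle_dataset(silent)$delta_a)), 0)
  # errors: non-increasing grids, negative sigma
  expect_error(gen_photocycle_dataset(scheme, wavelengths = c(500, 400)),
               "increasing")
  expect_error(noise_spec(-1), "non-negative")
})

test_that("stochastic generators are bit-reproducible under a fixed seed", {
  scheme <- fig_scheme()
  ns <- noise_spec(0.01, seed = 77)
  expect_identical(gen_photocycle_dataset(scheme, noise = ns)$delta_a,
                   gen_photocycle_dataset(scheme, noise = ns)$delta_a)
  expect_identical(
    gen_titration_series(3.34, 0.3, 548, 514, 2:8, 0.5, seed = 5)$observable,
    gen_titration_series(3.34, 0.3, 548, 514, 2:8, 0.5, seed = 5)$observable)
  ps1 <- gen_pore_particles(0:10, rep(1, 10), 5, 50, 20, seed = 9)
  ps2 <- gen_pore_particles(0:10, rep(1, 10), 5, 50, 20, seed = 9)
  expect_identical(ps1$z, ps2$z)
})

test_that("titration generator lies on the Boltzmann curve and refits its own pKa", {
  ph <- seq(1.93, 7.58, length.out = 25)
  s0 <- gen_titration_series(3.34, 0.4, 548, 514, ph)
  expect_equal(s0$observable,
               514 + (548 - 514) / (1 + exp((ph - 3.34) / 0.4)),
               tolerance = 1e-12)
  expect_equal(s0$observable[which.min(abs(ph - 3.34))],
               (548 + 514) / 2, tolerance = 0.5)
  # degenerate sigmoid: equal plateaus give a constant series
  flat <- gen_titration_series(5, 0.4, 1, 1, ph)
  expect_equal(diff(range(flat$observable)), 0)
  # refit of the generator's own noisy output recovers the midpoint
  ph2 <- seq(8, 13, length.out = 25)
  noisy <- gen_titration_series(10.36, -0.35, 1, 0, ph2,
                                noise_sigma = 0.01, seed = 42,
                                observable_kind = "absorbance_at")
  fit <- fit_boltzmann(noisy)
  expect_lt(abs(fit$midpoint_pka - 10.36), 3 * fit$se_pka)
  expect_error(gen_titration_series(5, 0.4, 1, 0, numeric(0)), "nonempty")
})

test_that("photocurrent generator produces signed exponential sums", {
  tg <- 10^seq(-6, 1, by = 0.05)
  one <- gen_photocurrent(cbind(1, 1), tg)
  expect_equal(one$current[which.min(abs(tg - 1))], exp(-1),
               tolerance = 1e-3)
  zc <- zero_area_components()
  tr <- gen_photocurrent(zc, tg)
  # analytic net charge of the generating components is zero by construction
  expect_lt(abs(sum(zc[, 1] * zc[, 2])), 1e-12 * sum(abs(zc[, 1] * zc[, 2])))
  expect_error(gen_photocurrent(cbind(1, -2), tg), "positive")
  # noisy refit recovers each lifetime within 15%; the zero-net-area
  # construction forces the slowest component amplitude down to 0.016, so
  # the noise must be scaled to the weakest component (not the trace
  # peak) for all four lifetimes to stay identifiable
  trn <- gen_photocurrent(zc, tg, noise_sigma = min(abs(zc[, 1])) / 20,
                          seed = 12)
  fit <- fit_current(trn, 4)
  expect_true(all(abs(fit$components$tau / sort(zc[, 2]) - 1) < 0.15))
})

test_that("ideal pentamer has exact C5 symmetry and the prescribed water pentagon", {
  pent <- gen_ideal_pentamer(pentagon_radius = 2.212)
  # adjacent O-O distance of a regular pentagon: 2 r sin(36 deg)
  ax <- pore_axis(pent, LETTERS[1:5])
  rg <- ring_geometry(pent, atom_select(pent, chain = "W"), ax)
  expect_equal(rg$mean, 2 * 2.212 * sin(36 * pi / 180), tolerance = 1e-9)
  expect_equal(rg$sd, 0, tolerance = 1e-9)
  # chains are exact copies: pairwise RMSD 0
  expect_lt(max(pairwise_protomer_rmsd(pent, LETTERS[1:5])), 1e-9)
  # symmetry axis is the z axis (within 0.5 degrees)
  expect_gt(abs(ax$direction[3]), cos(0.5 * pi / 180))
  expect_error(gen_ideal_pentamer(pentagon_radius = -1), "positive")
})

test_that("pore-particle ensembles follow the prescribed axial density", {
  edges <- seq(-20, 20, by = 2)
  ps <- gen_pore_particles(edges, rep(1, 20), cylinder_radius = 8,
                           n_particles = 400, n_frames = 50, seed = 31)
  ad <- axial_density(ps, bin_width = 2, cylinder_radius = 8)
  # uniform profile: per-slice counts equal within 4 Poisson sd of the mean
  tot_per_bin <- ad$counts * ad$n_frames
  expect_true(all(abs(tot_per_bin - mean(tot_per_bin)) <
                  4 * sqrt(mean(tot_per_bin))))
  # a half-density slab recovers +RT ln 2 within bootstrap sd
  dens2 <- c(rep(1, 9), 0.5, rep(1, 10))
  ps2 <- gen_pore_particles(edges, dens2, 8, 800, 80, seed = 13)
  ad2 <- axial_density(ps2, bin_width = 2, cylinder_radius = 8)
  pm <- pmf_profile(ad2, temperature = 310)
  sdv <- block_bootstrap_sd(ad2, block_length = 1, n_resamples = 500,
                            seed = 14, temperature = 310)
  expect_lt(abs(pm$g[10] - 1.9872e-3 * 310 * log(2)), 3 * sdv[10])
  # degenerate: zero particles errors cleanly downstream
  empty <- gen_pore_particles(edges, rep(1, 20), 8, 0, 5, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(axial_density(empty), "no particles")
  expect_error(gen_pore_particles(edges, rep(0, 20), 8, 10, 5), "positive")
})
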