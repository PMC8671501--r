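# Stick spectra and TA-map synthesis

test_that("a static two-level trajectory gives one constant SE stick", {
  tr <- fake_trajectory(t_fs = 0:50, gaps_ev = rep(3.8, 51))
  sig <- trajectory_signals(tr)
  expect_true(all(sig$channel == "SE"))
  expect_true(all(sig$energy_ev == 3.8))
  expect_true(all(sig$weight == -1 * 3.8))   # -|mu|^2 * gap
})

test_that("a modulated gap moves the SE stick with the modulation period", {
  nu <- 600
  t <- seq(0, 400, 1)
  gaps <- 3.8 + 0.1 * cos(2 * pi * t / wavenumber_to_period(nu))
  tr <- fake_trajectory(t, gaps)
  sig <- trajectory_signals(tr)
  expect_equal(sig$energy_ev, gaps)
  # period read off the stick positions equals 33356.41 / nu
  peaks <- which(diff(sign(diff(sig$energy_ev))) == -2) + 1
  expect_equal(mean(diff(sig$t_fs[peaks])), wavenumber_to_period(nu),
               tolerance = 0.02)
})

test_that("ESA sticks appear for states above the active one", {
  tr <- fake_trajectory(0:10, rep(3.8, 11), n_states = 3, esa_gap_ev = 0.5)
  sig <- trajectory_signals(tr)
  esa <- sig[sig$channel == "ESA", ]
  expect_equal(nrow(esa), 11)
  expect_true(all(esa$energy_ev == 0.5))
  expect_true(all(esa$weight == 0.5))        # +|mu|^2 * (E_b - E_a)
})

test_that("hot-ground-state sticks recompute from the stored continuation", {
  ens <- pucker_light_ensemble()
  tr <- NULL
  for (cand in ens$trajectories) if (!is.na(cand$t_gs_fs)) { tr <- cand; break }
  expect_false(is.null(tr))
  tau_cool <- 1500
  sig <- trajectory_signals(tr, cooling_tau_fs = tau_cool)
  hot <- sig[sig$channel == "hotGS", ]
  expect_gt(nrow(hot), 0)
  idx <- match(hot$t_fs, tr$t_fs)
  gap <- tr$energies_ev[idx, 2] - tr$energies_ev[idx, 1]
  expect_equal(hot$energy_ev, gap, tolerance = 1e-12)
  damp <- exp(-(hot$t_fs - tr$t_gs_fs) / tau_cool)
  expect_equal(hot$weight, tr$dipoles[cbind(idx, 1, 2)]^2 * gap * damp,
               tolerance = 1e-12)
  expect_true(all(hot$t_fs >= tr$t_gs_fs))
})

test_that("a single static trajectory maps to a time-constant Gaussian band", {
  tr <- fake_trajectory(0:100, rep(3.8, 101))
  ens <- fake_ensemble(list(tr), static_two_level(3.8 / 27.211386))
  mp <- ensemble_ta_map(ens, sigma_e_ev = 0.15, irf_fwhm_fs = 0,
                        probe_ev = seq(3, 4.6, 0.02))
  expect_lt(max(apply(mp$delta_a, 2, function(x) diff(range(x)))), 1e-12)
  j <- which.min(abs(mp$probe_ev - 3.8))
  expect_equal(mp$delta_a[1, j], -3.8, tolerance = 1e-6)
  prof <- -mp$delta_a[1, ]
  expect_equal(prof / max(prof),
               exp(-(mp$probe_ev - 3.8)^2 / (2 * 0.15^2)), tolerance = 1e-9)
})

test_that("zero broadening and no IRF reproduce on-grid stick weights exactly", {
  tr <- fake_trajectory(0:10, rep(3.8, 11))
  ens <- fake_ensemble(list(tr), static_two_level(0.14))
  mp <- ensemble_ta_map(ens, sigma_e_ev = 0, irf_fwhm_fs = 0,
                        probe_ev = seq(3.0, 4.6, 0.1))
  j <- which(mp$probe_ev == 3.8)
  expect_equal(mp$delta_a[1, j], -1 * 3.8)
  expect_true(all(mp$delta_a[, -j] == 0))
})

test_that("IRF convolution commutes with the probe-energy integral", {
  mp0 <- pucker_light_map()
  raw <- ensemble_ta_map(pucker_light_ensemble(), irf_fwhm_fs = 0,
                         probe_ev = mp0$probe_ev)
  conv_then_int <- rowSums(mp0$delta_a)
  int_then_conv <- as.vector(hopta:::.irf_convolve(
    matrix(rowSums(raw$delta_a), ncol = 1), raw$delays_fs, 30))
  expect_equal(conv_then_int, int_then_conv, tolerance = 1e-10)
})

test_that("channel decomposition sums to the total with correct signs", {
  mp <- pucker_light_map()
  tot <- Reduce(`+`, mp$components)
  expect_lt(max(abs(tot - mp$delta_a)), 1e-10)
  expect_true(all(mp$components$SE <= 1e-12))
  expect_true(all(mp$components$ESA >= -1e-12))
  expect_true(all(mp$components$hotGS >= -1e-12))
})

test_that("photoselection weights match the classical closed forms", {
  expect_equal(polarization_weights(0, "parallel") /
                 polarization_weights(0, "orthogonal"), 3)
  betas <- seq(0, pi / 2, length.out = 5)
  expect_true(all(vapply(betas, polarization_weights, numeric(1),
                         geometry = "magic") == 1 / 9))
  # Monte-Carlo orientational average over random molecular orientations
  set.seed(2024)
  n <- 1e6
  beta <- 0.7
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))            # pump dipole directions
  # probe dipole at fixed angle beta from the pump dipole, random azimuth
  a <- matrix(rnorm(3 * n), n, 3)
  a <- a - rowSums(a * u) * u
  a <- a / sqrt(rowSums(a^2))
  v <- cos(beta) * u + sin(beta) * a
  mc_par <- mean(u[, 3]^2 * v[, 3]^2)
  mc_orth <- mean(u[, 3]^2 * v[, 1]^2)
  expect_lt(abs(mc_par - polarization_weights(beta, "parallel")), 1e-3)
  expect_lt(abs(mc_orth - polarization_weights(beta, "orthogonal")), 1e-3)
})
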