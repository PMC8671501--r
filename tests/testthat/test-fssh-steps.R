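# Elementary surface-hopping operations: amplitude propagation, hop
# decisions, momentum rescaling, decoherence damping

test_that("decoupled amplitudes keep their moduli and advance analytic phases", {
  E <- c(0, 0.05)
  p0 <- fake_point(E, sigma = 0)
  c0 <- c(sqrt(0.3) + 0i, sqrt(0.7) * exp(0.4i))
  dt_fs <- 1
  c1 <- tdse_step(c0, p0, p0, v0 = 0, v1 = 0, dt_fs = dt_fs)
  expect_equal(Mod(c1), Mod(c0), tolerance = 1e-10, ignore_attr = TRUE)
  # phases advance by exp(-i E dt / hbar), up to the removed global phase
  dt <- dt_fs * hopta_constants$au_per_fs
  expected <- c0 * exp(-1i * (E - mean(E)) * dt)
  expect_equal(as.complex(c1), expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("constant gap and coupling reproduce the two-level Rabi solution", {
  dE <- 0.01; sg <- 0.003
  p0 <- fake_point(c(0, dE), sigma = sg)
  c0 <- c(1 + 0i, 0i)
  dt_fs <- 2
  c1 <- tdse_step(c0, p0, p0, v0 = 1, v1 = 1, dt_fs = dt_fs, n_substeps = 400)
  t <- dt_fs * hopta_constants$au_per_fs
  Omega <- sqrt(sg^2 + (dE / 2)^2)
  P2_exact <- sg^2 / Omega^2 * sin(Omega * t)^2
  expect_equal(Mod(c1[2])^2, P2_exact, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("amplitude propagation is self-converged in the substep count", {
  dE <- 0.02; sg <- 0.004
  pa <- fake_point(c(0, dE), sigma = sg)
  pb <- fake_point(c(0.003, dE * 0.8), sigma = sg * 1.5)
  c0 <- c(sqrt(0.8) + 0i, sqrt(0.2) * exp(1i))
  a <- tdse_step(c0, pa, pb, 1, 1, dt_fs = 1, n_substeps = 600)
  b <- tdse_step(c0, pa, pb, 1, 1, dt_fs = 1, n_substeps = 1200)
  expect_lt(max(Mod(as.complex(a) - as.complex(b))), 1e-6)
  expect_lt(attr(a, "norm_drift"), 1e-8)
})

test_that("hop probabilities follow the fewest-switches prescription", {
  ns <- 2
  S <- matrix(0, 2, 2)
  c0 <- c(sqrt(0.6) + 0i, sqrt(0.4) + 0i)
  # zero coupling: no hop for any draw
  hd <- hop_decision(c0, 1, S, dt_fs = 1, random_draw = 0)
  expect_true(is.na(hd$target))
  expect_equal(sum(hd$g), 0)
  # finite coupling: g matches the flux formula; threshold behaviour
  S[1, 2] <- 2e-3; S[2, 1] <- -2e-3
  dt <- hopta_constants$au_per_fs
  g_expect <- max(0, 2 * dt * S[1, 2] * Re(Conj(c0[2]) * c0[1]) / Mod(c0[1])^2)
  hd <- hop_decision(c0, 1, S, 1, random_draw = 0.999)
  expect_equal(hd$g[2], g_expect, tolerance = 1e-12)
  expect_true(hd$g[2] < 0.999 && is.na(hd$target))   # draw above cumulative
  hd2 <- hop_decision(c0, 1, S, 1, random_draw = g_expect * 0.5)
  expect_identical(hd2$target, 2L)
  # depleted active state: warning, no hop
  expect_warning(hd3 <- hop_decision(c(1e-9 + 0i, 1 + 0i), 1, S, 1, 0.1))
  expect_true(is.na(hd3$target))
})

test_that("momentum rescaling conserves energy exactly on accepted hops", {
  set.seed(99)
  masses <- c(1822.9, 10937, 10937)
  for (i in 1:100) {
    p <- rnorm(3, sd = 8)
    d <- rnorm(3)
    dE <- runif(1, -0.1, 0.02)
    rs <- rescale_momentum(p, masses, d, dE)
    ke0 <- sum(p^2 / (2 * masses))
    ke1 <- sum(rs$p^2 / (2 * masses))
    if (rs$accepted) {
      expect_lt(abs((ke1 + dE) - ke0), 1e-10)
    } else {
      expect_equal(rs$p, p)      # default: no velocity reversal
      expect_gt(rs$kinetic_deficit_ev, 0)
    }
  }
})

test_that("downward hops are always accepted; upward hops can frustrate", {
  p <- c(1.0); masses <- 2000; d <- c(0.5)
  dn <- rescale_momentum(p, masses, d, -0.05)
  expect_true(dn$accepted)
  ke_gain <- sum(dn$p^2 / (2 * masses)) - sum(p^2 / (2 * masses))
  expect_equal(ke_gain, 0.05, tolerance = 1e-12)
  up <- rescale_momentum(p, masses, d, 0.05)   # KE available = 2.5e-4 only
  expect_false(up$accepted)
  expect_equal(up$p, p)
  # frustrated with reversal flips the velocity component along d
  rev <- rescale_momentum(p, masses, d, 0.05, reverse_frustrated = TRUE)
  expect_equal(rev$p, -p, tolerance = 1e-12)
  # zero-norm NAC falls back to the velocity direction
  fb <- rescale_momentum(p, masses, c(0), -0.01)
  expect_true(fb$accepted)
  expect_identical(fb$direction, "velocity")
})

test_that("decoherence damps non-active amplitudes and restores the norm", {
  # strong-decoherence limit
  c0 <- c(sqrt(0.5) + 0i, sqrt(0.5) + 0i)
  out <- decoherence_step(c0, active = 1, energies = c(0, 10), ekin = 1,
                          dt_fs = 1e4, C = 0)
  expect_equal(Mod(out[1])^2, 1, tolerance = 1e-12)
  expect_lt(Mod(out[2])^2, 1e-12)

  # hand-computed step: dt/tau = ln 2 damps |c| by 1/2, population to 1/4,
  # and the active amplitude is rescaled to restore unit norm
  gap <- 0.05; ekin <- 0.02; C <- 0.1
  tau <- (1 / gap) * (1 + C / ekin)          # a.u.
  dt_fs <- log(2) * tau / hopta_constants$au_per_fs
  out2 <- decoherence_step(c0, 1, c(0, gap), ekin, dt_fs, C)
  expect_equal(Mod(out2[2])^2, 0.5 / 4, tolerance = 1e-10)
  expect_equal(sum(Mod(out2)^2), 1, tolerance = 1e-12)

  # degenerate states are left untouched
  out3 <- decoherence_step(c0, 1, c(0.2, 0.2), ekin, 10, C)
  expect_equal(out3, c0)
})
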