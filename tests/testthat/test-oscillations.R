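# Band-pass residual extraction, 2D Fourier maps, node and phase analysis

# map with per-energy traces: kinetics + optional injected cosines
osc_map <- function(t = seq(0, 1048, 2), E = seq(3.2, 4.4, 0.02),
                    kinetics = function(tt) exp(-tt / 300),
                    modes = list()) {
  A <- matrix(0, length(t), length(E))
  base <- kinetics(t)
  for (j in seq_along(E)) {
    x <- base
    for (md in modes) {
      amp <- if (is.function(md$amp)) md$amp(E[j]) else md$amp
      phi <- if (!is.null(md$phase_fn)) md$phase_fn(E[j]) else 0
      x <- x + amp * cos(2 * pi * t / wavenumber_to_period(md$nu) + phi)
    }
    A[, j] <- x
  }
  ta_map(t, E, A)
}

test_that("a smooth biexponential leaves almost no band-passed residual", {
  mp <- osc_map(kinetics = function(t) 0.7 * exp(-t / 120) + 0.3 * exp(-t / 600))
  r <- extract_oscillations(mp, c(450, 900), t_start_fs = 50)
  expect_lt(sqrt(mean(r$residuals^2)) / sqrt(mean(mp$delta_a^2)), 1e-3)
})

test_that("an injected 750 cm^-1 cosine is recovered in amplitude and phase", {
  mp <- osc_map(modes = list(list(nu = 750, amp = 0.1)))
  r <- extract_oscillations(mp, c(450, 900), t_start_fs = 50)
  om <- ftmap_2d(r)
  j <- 10
  kpk <- which.max(om$amplitude[j, ])
  expect_equal(om$amplitude[j, kpk], 0.1, tolerance = 0.05)
  # zero-phase filter: residual aligns with the injected cosine at zero lag
  t <- r$delays_fs
  injected <- 0.1 * cos(2 * pi * t / wavenumber_to_period(750))
  lagcor <- stats::ccf(r$residuals[, j], injected, lag.max = 5, plot = FALSE)
  expect_equal(as.numeric(lagcor$lag[which.max(lagcor$acf)]), 0)
})

test_that("the band-pass filter is an idempotent projection", {
  mp <- osc_map(modes = list(list(nu = 700, amp = 0.08)))
  r1 <- extract_oscillations(mp, c(450, 900), t_start_fs = 50)
  m2 <- ta_map(r1$delays_fs, r1$probe_ev, r1$residuals)
  r2 <- extract_oscillations(m2, c(450, 900), t_start_fs = r1$delays_fs[1])
  expect_lt(max(abs(r2$residuals - r1$residuals)), 1e-10)
})

test_that("degenerate passbands and out-of-range bands are rejected", {
  mp <- osc_map()
  expect_error(extract_oscillations(mp, c(700, 700)), "degenerate")
  expect_error(extract_oscillations(mp, c(450, 99000)), "Nyquist")
})

test_that("2D FT resolves the injected modes within one padded bin", {
  mp <- osc_map(modes = list(list(nu = 600, amp = 0.05),
                             list(nu = 750, amp = 0.08)))
  r <- extract_oscillations(mp, c(400, 1000), t_start_fs = 50)
  om <- ftmap_2d(r, zero_pad_factor = 4)
  prof <- colMeans(om$amplitude)
  dbin <- diff(om$wavenumbers_cm)[1]
  # two resolved peaks (1 ps window, Rayleigh-separated modes)
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  pk <- pk[order(prof[pk], decreasing = TRUE)][1:2]
  expect_equal(sort(om$wavenumbers_cm[pk]), c(600, 750), tolerance = dbin / 600)
})

test_that("the rectangular-window FT satisfies Parseval", {
  mp <- osc_map(modes = list(list(nu = 700, amp = 0.1)))
  r <- extract_oscillations(mp, c(450, 900), t_start_fs = 50)
  om <- ftmap_2d(r, window_fn = "rect", zero_pad_factor = 1)
  n <- om$n_time
  nk <- length(om$wavenumbers_cm)
  for (j in c(1, 15)) {
    # reconstruct the full-spectrum power (DC vanishes for detrended traces,
    # the Nyquist bin is not doubled) and compare with the time-domain energy
    X2 <- (om$amplitude[j, ] / om$scale)^2
    lhs <- 2 * sum(X2[-nk]) + X2[nk]
    rhs <- n * sum(r$residuals[, j]^2)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("a gap-modulated band shows a node at the mean gap with a pi flip", {
  # SE band whose centre oscillates: dA(E, t) = -G(E - Ebar(t)),
  # Ebar = 3.80 + 0.05 cos(w t); linearization gives amplitude ~ |G'| with a
  # sign change (pi phase jump) across E = 3.80
  t <- seq(0, 1048, 2)
  E <- seq(3.2, 4.4, 0.02)
  ctr <- 3.80 + 0.05 * cos(2 * pi * t / wavenumber_to_period(600))
  A <- -exp(-outer(ctr, E, function(c, e) (e - c)^2) / (2 * 0.15^2))
  mp <- ta_map(t, E, A)
  r <- extract_oscillations(mp, c(450, 750), t_start_fs = 50)
  om <- ftmap_2d(r)
  nd <- node_phase_analysis(om, 600)
  expect_true(nd$found)
  expect_equal(nd$node_ev, 3.80, tolerance = 0.021 / 3.8)   # one grid step
  expect_equal(abs(nd$phase_jump_rad), pi, tolerance = 0.2 / pi)
})

test_that("constant-amplitude oscillations yield no node", {
  mp <- osc_map(modes = list(list(nu = 600, amp = 0.1)))
  r <- extract_oscillations(mp, c(450, 750), t_start_fs = 50)
  om <- ftmap_2d(r)
  nd <- node_phase_analysis(om, 600)
  expect_false(nd$found)
})

test_that("mirroring the energy axis keeps the node and flips the phase jump", {
  t <- seq(0, 1048, 2)
  E <- seq(3.2, 4.4, 0.02)
  ctr <- 3.80 + 0.05 * cos(2 * pi * t / wavenumber_to_period(600))
  A <- -exp(-outer(ctr, E, function(c, e) (e - c)^2) / (2 * 0.15^2))
  mp <- ta_map(t, E, A)
  mirrored <- ta_map(t, E, A[, rev(seq_along(E))])
  nd1 <- node_phase_analysis(ftmap_2d(extract_oscillations(mp, c(450, 750), 50)), 600)
  nd2 <- node_phase_analysis(ftmap_2d(extract_oscillations(mirrored, c(450, 750), 50)), 600)
  expect_true(nd1$found && nd2$found)
  # node at 3.80 eV sits symmetric on this grid; mirrored position matches
  expect_equal(max(E) + min(E) - nd2$node_ev, nd1$node_ev, tolerance = 0.021)
  expect_equal(nd2$phase_jump_rad, -nd1$phase_jump_rad, tolerance = 0.1)
})

test_that("wavenumber-period conversion uses the fixed constant", {
  expect_equal(wavenumber_to_period(600), 55.6, tolerance = 0.001)
  expect_lt(abs(wavenumber_to_period(600) - 55), 1)   # "ca. 55 fs"
  expect_equal(wavenumber_to_period(33356.41), 1.0)
  expect_equal(wavenumber_to_period(750), 44.5, tolerance = 0.001)
  expect_error(wavenumber_to_period(0))
  expect_error(wavenumber_to_period(-10))
})
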