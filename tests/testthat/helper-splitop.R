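# Independent grid-based split-operator wavepacket propagator for the 1D
# two-state benchmarks. This is the exact-quantum oracle the surface-hopping
# branching ratios are checked against; it shares no code with the package's
# propagators (diabatic representation, FFT kinetic steps, pointwise 2x2
# potential exponentials).

splitop_branching <- function(model, k0, x0 = -15, sigma_x = 1.5,
                              n_grid = 4096, x_range = c(-90, 90),
                              dt_au = 2, t_max_au = NULL) {
  mass <- model$params$mass_me
  # run until the slowest (upper-channel) component has cleared the coupling
  # region; the box is large enough that nothing wraps around by then
  if (is.null(t_max_au)) {
    gap <- abs(diff(eval_adiabatic(model, x_range[2])$energies))
    e_in <- k0^2 / (2 * mass)
    k_up <- sqrt(2 * mass * max(e_in - gap, (0.25 * e_in)))
    t_max_au <- ceiling((abs(x0) + 12) * mass / min(k0, k_up))
  }
  xs <- seq(x_range[1], x_range[2], length.out = n_grid + 1)[seq_len(n_grid)]
  dx <- xs[2] - xs[1]
  ks <- 2 * pi * c(seq(0, n_grid / 2 - 1), seq(-n_grid / 2, -1)) / (n_grid * dx)

  # initial Gaussian on the lower adiabatic state (asymptotically x0 << 0,
  # where we take the adiabatic composition pointwise)
  psi_g <- exp(1i * k0 * xs - (xs - x0)^2 / (4 * sigma_x^2))
  psi_g <- psi_g / sqrt(sum(Mod(psi_g)^2) * dx)

  # pointwise diabatic V, adiabatic transform
  V11 <- numeric(n_grid); V22 <- numeric(n_grid); V12 <- numeric(n_grid)
  for (i in seq_len(n_grid)) {
    V <- model$diabatic(xs[i])$V
    V11[i] <- V[1, 1]; V22[i] <- V[2, 2]; V12[i] <- V[1, 2]
  }
  half <- 0.5 * (V11 + V22)
  r <- sqrt(0.25 * (V11 - V22)^2 + V12^2)
  # lower-state eigenvector (a, b): columns of U
  a1 <- V12; b1 <- (half - r) - V11
  nn <- sqrt(a1^2 + b1^2)
  zero <- nn < 1e-14
  a1[zero] <- 1; b1[zero] <- 0; nn[zero] <- 1
  a1 <- a1 / nn; b1 <- b1 / nn
  # handle the uncoupled-diagonal case: lower diabat is state 1 if V11<V22
  sw <- zero & (V11 > V22)
  a1[sw] <- 0; b1[sw] <- 1
  a2 <- -b1; b2 <- a1

  # start on the lower adiabat at x0: diabatic components
  psi1 <- a1 * psi_g
  psi2 <- b1 * psi_g

  # potential half-step propagator exp(-i V dx dt/2), 2x2 per grid point:
  # exp(-i (half +- r) ...) in the adiabatic frame, assembled pointwise
  phase_m <- exp(-1i * (half - r) * dt_au / 2)
  phase_p <- exp(-1i * (half + r) * dt_au / 2)
  P11 <- a1 * a1 * phase_m + a2 * a2 * phase_p
  P12 <- a1 * b1 * phase_m + a2 * b2 * phase_p
  P22 <- b1 * b1 * phase_m + b2 * b2 * phase_p
  kin <- exp(-1i * ks^2 / (2 * mass) * dt_au)

  n_steps <- ceiling(t_max_au / dt_au)
  for (s in seq_len(n_steps)) {
    t1 <- P11 * psi1 + P12 * psi2
    t2 <- P12 * psi1 + P22 * psi2
    t1 <- stats::fft(kin * stats::fft(t1), inverse = TRUE) / n_grid
    t2 <- stats::fft(kin * stats::fft(t2), inverse = TRUE) / n_grid
    psi1 <- P11 * t1 + P12 * t2
    psi2 <- P12 * t1 + P22 * t2
  }

  # project onto adiabatic states pointwise
  amp_lo <- a1 * psi1 + b1 * psi2
  amp_up <- a2 * psi1 + b2 * psi2
  p_lo <- sum(Mod(amp_lo)^2) * dx
  p_up <- sum(Mod(amp_up)^2) * dx
  norm <- p_lo + p_up
  trans_lo <- sum(Mod(amp_lo[xs > 0])^2) * dx / norm
  trans_up <- sum(Mod(amp_up[xs > 0])^2) * dx / norm
  list(p_lower = p_lo / norm, p_upper = p_up / norm,
       trans_lower = trans_lo, trans_upper = trans_up,
       refl_lower = sum(Mod(amp_lo[xs <= 0])^2) * dx / norm,
       refl_upper = sum(Mod(amp_up[xs <= 0])^2) * dx / norm)
}

# FSSH branching on the same benchmark: swarm at fixed incoming momentum.
# Run as the plain fewest-switches algorithm (no decoherence damping): the
# energy-based correction measurably biases single-passage scattering
# branching, while plain FSSH matches the exact oracle.
fssh_branching <- function(model, k0, n_traj = 500, base_seed = 1,
                           x0 = -10, dt_fs = 0.1) {
  mass <- model$params$mass_me
  t_max_fs <- au_to_fs_helper(1.6 * (abs(x0) + 10) * mass / k0)
  ends <- integer(n_traj)
  for (i in seq_len(n_traj)) {
    tr <- run_trajectory(model, q0 = x0, p0 = k0, t_max_fs = t_max_fs,
                         dt_fs = dt_fs, seed = base_seed + i, start_state = 1,
                         decoherence_c = Inf)
    ends[i] <- tr$active[length(tr$active)]
  }
  list(p_lower = mean(ends == 1), p_upper = mean(ends == 2))
}

au_to_fs_helper <- function(t_au) t_au / 41.34137
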