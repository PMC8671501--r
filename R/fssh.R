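## Fewest-switches surface hopping: classical nuclei on the active adiabatic
## surface (velocity Verlet with automatic sub-stepping on stiff segments),
## quantum amplitudes by the TDSE with energies and time-derivative couplings
## linearly interpolated across the nuclear step, stochastic hops with
## momentum rescaling along the nonadiabatic coupling vector, and an
## energy-based decoherence correction.

## sigma matrix (time-derivative coupling) from NAC vectors and velocities:
## sigma_ij = sum_m v_m * d_ij,m = <i | d/dt j>
.sigma_matrix <- function(nac, v) {
  ns <- dim(nac)[2]
  S <- matrix(0, ns, ns)
  for (m in seq_along(v)) if (v[m] != 0) S <- S + v[m] * nac[m, , ]
  S
}

## lean adiabatic evaluation used inside Verlet substeps: energies,
## eigenvectors, gradient of one state only
.force_eval <- function(model, q, state, u_prev = NULL) {
  d2 <- model$diabatic2
  if (!is.null(d2)) {
    ## flat two-state fast path: closed-form diagonalization, no matrices
    f <- d2(q)
    a <- f$v11; b <- f$v22; cc <- f$v12
    half <- 0.5 * (a + b)
    r <- sqrt(0.25 * (a - b)^2 + cc * cc)
    w1 <- cc; w2 <- (half - r) - a
    nw <- sqrt(w1 * w1 + w2 * w2)
    if (nw < 1e-150) {
      u11 <- 1; u12 <- 0
    } else {
      u11 <- w1 / nw; u12 <- w2 / nw
    }
    u21 <- -u12; u22 <- u11
    if (!is.null(u_prev)) {
      if (u11 * u_prev[1] + u12 * u_prev[2] < 0) { u11 <- -u11; u12 <- -u12 }
      if (u21 * u_prev[3] + u22 * u_prev[4] < 0) { u21 <- -u21; u22 <- -u22 }
    }
    grad <- if (state == 1L) {
      u11 * u11 * f$d11 + 2 * u11 * u12 * f$d12 + u12 * u12 * f$d22
    } else {
      u21 * u21 * f$d11 + 2 * u21 * u22 * f$d12 + u22 * u22 * f$d22
    }
    return(list(E = c(half - r, half + r),
                U = c(u11, u12, u21, u22), grad = grad))
  }
  d <- model$diabatic(q)
  V <- d$V
  ns <- model$n_states
  if (ns == 1L) {
    E <- V[1, 1]; U <- matrix(1, 1, 1)
  } else if (ns == 2L) {
    a <- V[1, 1]; b <- V[2, 2]; cc <- V[1, 2]
    half <- 0.5 * (a + b)
    r <- sqrt(0.25 * (a - b)^2 + cc * cc)
    E <- c(half - r, half + r)
    if (r < .Machine$double.eps) {
      U <- diag(2)
    } else {
      th <- 0.5 * atan2(2 * cc, a - b)
      U <- matrix(c(-sin(th), cos(th), cos(th), sin(th)), 2, 2)
      if (sum(U[, 1] * (V %*% U[, 1])) > sum(U[, 2] * (V %*% U[, 2]))) U <- U[, 2:1]
    }
  } else {
    eg <- eigen(V, symmetric = TRUE)
    ord <- order(eg$values)
    E <- eg$values[ord]
    U <- eg$vectors[, ord, drop = FALSE]
  }
  if (!is.null(u_prev)) {
    s <- colSums(U * u_prev)
    flip <- s < 0
    if (any(flip)) U[, flip] <- -U[, flip]
  }
  ua <- U[, state]
  nm <- model$n_modes
  grad <- numeric(nm)
  for (m in seq_len(nm)) {
    grad[m] <- sum(ua * (matrix(d$dV[m, , ], ns, ns) %*% ua))
  }
  list(E = E, U = U, grad = grad)
}

#' Propagate electronic amplitudes across one nuclear step
#'
#' Integrates \eqn{\dot c_i = -i E_i c_i - \sum_j \sigma_{ij} c_j} (atomic
#' units) with energies linearly interpolated between the two adiabatic
#' points and time-derivative couplings \eqn{\sigma_{ij} = d_{ij} \cdot v}
#' interpolated between the endpoint values, using a fixed-substep 4th-order
#' Runge-Kutta scheme. When `sigma_ths` (the overlap-derived step-average
#' coupling, \eqn{(U_0^T U_1 - U_1^T U_0)/(2\Delta t)}) is supplied, the
#' in-step coupling is corrected by a parabolic term so that its time
#' integral matches the overlap value; this Tully-Hammes-Schiffer-style
#' treatment transfers the correct amplitude even when the coupling spike is
#' narrower than the nuclear step. The mean energy is removed before
#' propagation (a global phase); the substep count is raised automatically so
#' that the largest phase advance per substep stays below 0.025 rad, keeping
#' the norm conserved to 1e-8.
#'
#' @param amplitudes complex state vector at the step start.
#' @param point0,point1 `adiabatic_point`s at the step endpoints (from
#'   [eval_adiabatic()], with consistent eigenvector signs).
#' @param v0,v1 nuclear velocities (bohr / a.u. time) at the endpoints.
#' @param dt_fs nuclear time step (fs).
#' @param n_substeps minimum number of inner steps (>= 20 recommended).
#' @param norm_tol hard-error tolerance on the norm drift (default 1e-8).
#' @param sigma_ths optional overlap-derived step-average coupling matrix
#'   (a.u.); default: the mean of the endpoint couplings (plain linear
#'   interpolation).
#' @param active active state index for which the fewest-switches hop
#'   probability is accumulated substep-by-substep (0 = none).
#' @return the propagated complex amplitude vector; attribute `norm_drift`
#'   carries the raw norm deviation and attribute `hop_g` the accumulated
#'   per-state hop probabilities out of `active`.
#' @export
tdse_step <- function(amplitudes, point0, point1, v0, v1, dt_fs,
                      n_substeps = 40, norm_tol = 1e-8,
                      sigma_ths = NULL, active = 0L) {
  dt <- fs_to_au(dt_fs)
  S0 <- .sigma_matrix(point0$nac, v0)
  S1 <- .sigma_matrix(point1$nac, v1)
  if (is.null(sigma_ths)) sigma_ths <- 0.5 * (S0 + S1)
  ebar <- mean(c(point0$energies, point1$energies))
  E0 <- point0$energies - ebar
  E1 <- point1$energies - ebar
  theta <- max(abs(c(E0, E1)), max(abs(S0)), max(abs(S1)),
               max(abs(sigma_ths)), 1e-12)
  nsub <- max(n_substeps, ceiling(theta * dt / 0.025))
  res <- tdse_rk4_adiabatic(amplitudes, E0, E1, S0, S1, sigma_ths,
                            dt, nsub, as.integer(active))
  c1 <- res$c
  drift <- abs(sum(Mod(c1)^2) - sum(Mod(amplitudes)^2))
  if (drift > norm_tol) {
    stop(sprintf(
      "TDSE norm drift %.3e exceeds tolerance %.1e (dt = %g fs, %d substeps)",
      drift, norm_tol, dt_fs, nsub))
  }
  attr(c1, "norm_drift") <- drift
  attr(c1, "hop_g") <- res$g
  c1
}

#' Fewest-switches hop decision
#'
#' Hop probabilities out of the active state `a` follow the fewest-switches
#' prescription: \eqn{g_{a \to j} = \max(0, 2 \Delta t\, \sigma_{aj}
#' \mathrm{Re}(c_j^* c_a) / |c_a|^2)}, the positive part of the population
#' flux out of `a` into `j`. The target is chosen by comparing the cumulative
#' probabilities against a uniform random draw.
#'
#' @param amplitudes complex state vector.
#' @param active active state index.
#' @param sigma time-derivative coupling matrix (a.u.).
#' @param dt_fs nuclear time step (fs).
#' @param random_draw uniform draw in `[0, 1)`.
#' @return list with `target` (state index or `NA` for no hop) and the
#'   probability vector `g`.
#' @export
hop_decision <- function(amplitudes, active, sigma, dt_fs, random_draw) {
  if (random_draw < 0 || random_draw >= 1) stop("random_draw must be in [0, 1)")
  ns <- length(amplitudes)
  ca <- amplitudes[active]
  pa <- Mod(ca)^2
  g <- numeric(ns)
  if (pa < 1e-12) {
    warning("active-state population below 1e-12; no hop evaluated")
    return(list(target = NA_integer_, g = g))
  }
  dt <- fs_to_au(dt_fs)
  for (j in seq_len(ns)) {
    if (j == active) next
    g[j] <- max(0, 2 * dt * sigma[active, j] * Re(Conj(amplitudes[j]) * ca) / pa)
  }
  cum <- cumsum(g)
  target <- which(random_draw < cum)[1]
  if (!is.na(target) && g[target] == 0) target <- NA_integer_
  list(target = if (is.na(target)) NA_integer_ else as.integer(target), g = g)
}

#' Rescale momentum at a hop
#'
#' Adjusts the momentum along the nonadiabatic coupling vector so that total
#' energy is conserved across the hop. If the kinetic energy in that
#' direction is insufficient for an upward hop, the hop is frustrated and the
#' momentum is returned unchanged (optionally with the component along the
#' NAC reversed).
#'
#' @param p momenta (a.u.).
#' @param masses_me masses (electron masses).
#' @param nac_vec coupling vector \eqn{d_{a \to j}} (per mode); a zero-norm
#'   vector falls back to rescaling along the full velocity.
#' @param delta_e `E_target - E_active` (hartree) at the hop geometry.
#' @param reverse_frustrated reverse the velocity component along the NAC on
#'   frustrated hops (default `FALSE`).
#' @return list with `accepted`, `p` (updated momenta),
#'   `kinetic_deficit_ev` (0 when accepted) and `direction`
#'   (`"nac"` or `"velocity"`).
#' @export
rescale_momentum <- function(p, masses_me, nac_vec, delta_e,
                             reverse_frustrated = FALSE) {
  dirn <- "nac"
  d <- nac_vec
  if (sqrt(sum(d^2)) < 1e-12) {
    d <- p / masses_me       # velocity direction fallback
    dirn <- "velocity"
    if (sqrt(sum(d^2)) < 1e-30) {
      return(list(accepted = FALSE, p = p,
                  kinetic_deficit_ev = hartree_to_ev(max(delta_e, 0)),
                  direction = dirn))
    }
  }
  a <- sum(d^2 / (2 * masses_me))
  b <- sum(p * d / masses_me)
  disc <- b^2 - 4 * a * delta_e
  if (disc < 0) {
    deficit <- delta_e - b^2 / (4 * a)
    if (reverse_frustrated) {
      gam <- -b / a   # reverses the velocity component along d
      p <- p + gam * d
    }
    return(list(accepted = FALSE, p = p,
                kinetic_deficit_ev = hartree_to_ev(deficit), direction = dirn))
  }
  ## root of a g^2 + b g + delta_e = 0 with smaller |g|
  g1 <- (-b + sqrt(disc)) / (2 * a)
  g2 <- (-b - sqrt(disc)) / (2 * a)
  gam <- if (abs(g1) <= abs(g2)) g1 else g2
  list(accepted = TRUE, p = p + gam * d, kinetic_deficit_ev = 0,
       direction = dirn)
}

#' Energy-based decoherence damping
#'
#' Damps the non-active amplitudes with the energy-gap- and kinetic-energy-
#' dependent time constant \eqn{\tau_i = \frac{\hbar}{|E_i - E_a|}\left(1 +
#' \frac{C}{E_{kin}}\right)} (each \eqn{|c_i|} multiplied by
#' \eqn{e^{-\Delta t/\tau_i}}), then rescales the active amplitude to restore
#' unit norm. Pairs degenerate with the active state are left untouched.
#'
#' @param amplitudes complex state vector (unit norm).
#' @param active active state index.
#' @param energies adiabatic energies (hartree).
#' @param ekin nuclear kinetic energy (hartree).
#' @param dt_fs time step (fs).
#' @param C decoherence constant (hartree), default 0.1.
#' @return damped, renormalized amplitude vector.
#' @export
decoherence_step <- function(amplitudes, active, energies, ekin, dt_fs, C = 0.1) {
  if (C < 0) stop("C must be >= 0")
  ns <- length(amplitudes)
  dt <- fs_to_au(dt_fs)
  fac <- if (ekin > 0) (1 + C / ekin) else Inf
  out <- amplitudes
  for (i in seq_len(ns)) {
    if (i == active) next
    gap <- abs(energies[i] - energies[active])
    if (gap == 0 || !is.finite(fac)) next
    tau <- fac / gap
    out[i] <- out[i] * exp(-dt / tau)
  }
  pa_target <- 1 - sum(Mod(out[-active])^2)
  pa <- Mod(out[active])^2
  if (pa > 0 && pa_target >= 0) {
    out[active] <- out[active] * sqrt(pa_target / pa)
  }
  out
}

#' Run one surface-hopping trajectory
#'
#' Velocity-Verlet propagation of the nuclei on the active adiabatic surface
#' (with automatic sub-stepping so that no inner step moves any coordinate by
#' more than `max_step_bohr`), electronic amplitudes by [tdse_step()], hop
#' decisions by [hop_decision()], momentum rescaling by [rescale_momentum()]
#' and decoherence damping by [decoherence_step()] at every nuclear step.
#' Overdamped model modes carry no momentum and relax exponentially toward
#' their target. With `irreversible_gs = TRUE`, hopping is switched off after
#' the first arrival in the lowest state and the trajectory continues on the
#' ground state for `gs_window_fs` (default: to `t_max_fs`) to feed the
#' hot-ground-state spectra.
#'
#' @param model an `electronic_model`.
#' @param q0,p0 initial coordinates (bohr) and momenta (a.u.).
#' @param t_max_fs propagation time (fs).
#' @param dt_fs nuclear time step, default 1.0 fs.
#' @param seed integer seed; the trajectory is fully reproducible from it.
#' @param start_state initial adiabatic state (default: the model's bright
#'   state, else the highest state).
#' @param n_substeps minimum TDSE substeps per nuclear step.
#' @param decoherence_c decoherence constant (hartree).
#' @param reverse_frustrated frustrated-hop velocity reversal policy.
#' @param gs_window_fs post-hop ground-state continuation window (fs);
#'   `Inf` continues to `t_max_fs`.
#' @param irreversible_gs if `TRUE`, hopping is switched off after the first
#'   accepted hop into the lowest state (irreversible internal conversion;
#'   appropriate for photochemical funnel models whose hot ground-state
#'   trajectory re-traverses the coupling region). Default `FALSE` (plain
#'   fewest-switches dynamics, as in the scattering benchmarks).
#' @param max_step_bohr displacement cap per Verlet inner step.
#' @param drift_tol_h energy-drift tolerance between hops (hartree); a
#'   trajectory exceeding it is flagged invalid.
#' @return an object of class `trajectory`: time grid `t_fs`, matrices `q`,
#'   `p`, integer vector `active`, complex matrix `amps`, matrix `energies`
#'   (hartree; `energies_ev` in eV), dipole array `dipoles`
#'   (`n_t` x `n_states` x `n_states`), data.frame `events` (columns
#'   `t_fs, from, to, accepted, kinetic_deficit_ev`, plus hop geometry in
#'   `q_at_hop`), `seed`, `valid`, `max_drift_h`, and `t_gs_fs` (time of the
#'   accepted hop to the lowest state, `NA` if none). `n_recorded` marks the
#'   last propagated step when a finite `gs_window_fs` truncates the record.
#' @export
run_trajectory <- function(model, q0, p0, t_max_fs, dt_fs = 1.0, seed = 1,
                           start_state = NULL, n_substeps = 40,
                           decoherence_c = 0.1, reverse_frustrated = FALSE,
                           gs_window_fs = Inf, irreversible_gs = FALSE,
                           max_step_bohr = 0.05, drift_tol_h = 1e-4) {
  if (dt_fs <= 0) stop("dt_fs must be positive")
  nm <- model$n_modes
  ns <- model$n_states
  if (length(q0) != nm || length(p0) != nm) stop("sample dimensions do not match model")
  if (is.null(start_state)) start_state <- if (!is.na(model$bright)) model$bright else ns
  masses <- model$masses_me
  dyn <- !model$overdamped
  over <- which(model$overdamped)
  tau_s <- fs_to_au(model$relax_tau_fs)
  dt <- fs_to_au(dt_fs)
  n_steps <- as.integer(round(t_max_fs / dt_fs))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  ## storage
  tq <- matrix(0, n_steps + 1L, nm)
  tp <- matrix(0, n_steps + 1L, nm)
  tact <- integer(n_steps + 1L)
  tamp <- matrix(0 + 0i, n_steps + 1L, ns)
  tE <- matrix(0, n_steps + 1L, ns)
  tdip <- array(0, c(n_steps + 1L, ns, ns))
  tg <- numeric(n_steps + 1L)        # summed hop probability per step (diagnostic)
  events <- list()

  q <- as.numeric(q0); p <- as.numeric(p0)
  p[over] <- 0
  active <- as.integer(start_state)
  c_amp <- rep(0 + 0i, ns); c_amp[active] <- 1 + 0i
  pt <- eval_adiabatic(model, q)
  hop_enabled <- ns > 1L
  t_gs <- NA_real_
  n_recorded <- n_steps + 1L

  local_hmax <- model$local_hmax
  ekin_dyn <- function(pv) sum(pv[dyn]^2 / (2 * masses[dyn]))
  e_ref <- pt$energies[active] + ekin_dyn(p)
  max_drift <- 0

  tq[1L, ] <- q; tp[1L, ] <- p; tact[1L] <- active
  tamp[1L, ] <- c_amp; tE[1L, ] <- pt$energies; tdip[1L, , ] <- pt$dipoles

  for (step in seq_len(n_steps)) {
    v0 <- p / masses
    if (length(over)) v0[over] <- (model$relax_target - q[over]) / tau_s
    pt0 <- pt
    grad <- pt0$gradients[, active]

    ## --- nuclear step: velocity Verlet with locally adaptive sub-stepping
    ## (inner step capped so no coordinate moves more than max_step_bohr,
    ## re-evaluated as the velocity grows, e.g. while falling through the
    ## crossing region) ---
    u_run <- pt0$U
    g_run <- grad
    sol_work <- 0
    t_rem <- dt
    repeat {
      vmax <- max(abs(p[dyn] / masses[dyn]))
      amax <- max(abs(g_run[dyn] / masses[dyn]))
      h <- min(t_rem,
               max_step_bohr / max(vmax, 1e-12),
               sqrt(2 * max_step_bohr / max(amax, 1e-16)))
      if (!is.null(local_hmax)) h <- min(h, local_hmax(q))
      h <- max(h, dt / 4096)
      p_half <- p
      p_half[dyn] <- p[dyn] - 0.5 * h * g_run[dyn]
      q[dyn] <- q[dyn] + h * p_half[dyn] / masses[dyn]
      if (length(over)) {
        dq_s <- (model$relax_target - q[over]) * (1 - exp(-h / tau_s))
        ## work done on the active surface by the driven solvent coordinate
        sol_work <- sol_work + sum(g_run[over] * dq_s)
        q[over] <- q[over] + dq_s
      }
      fe <- .force_eval(model, q, active, u_prev = u_run)
      u_run <- fe$U; g_run <- fe$grad
      p[dyn] <- p_half[dyn] - 0.5 * h * g_run[dyn]
      t_rem <- t_rem - h
      if (t_rem <= 1e-12) break
    }
    e_ref <- e_ref + sol_work
    pt <- eval_adiabatic(model, q, u_prev = pt0$U)
    v1 <- p / masses
    if (length(over)) v1[over] <- (model$relax_target - q[over]) / tau_s

    ## --- electronic propagation, hop decision, decoherence ---
    if (ns > 1L) {
      S_ths <- (crossprod(matrix(pt0$U, ns, ns), matrix(pt$U, ns, ns)) -
                crossprod(matrix(pt$U, ns, ns), matrix(pt0$U, ns, ns))) / (2 * dt)
      c_amp <- tdse_step(c_amp, pt0, pt, v0, v1, dt_fs, n_substeps,
                         sigma_ths = S_ths,
                         active = if (hop_enabled) active else 0L)
      if (hop_enabled) {
        gvec <- attr(c_amp, "hop_g")
        tg[step + 1L] <- sum(gvec)
        cum <- cumsum(gvec)
        tsel <- which(stats::runif(1) < cum)[1]
        if (!is.na(tsel) && gvec[tsel] == 0) tsel <- NA_integer_
        if (!is.na(tsel)) {
          j <- as.integer(tsel)
          rs <- rescale_momentum(p, masses, pt$nac[, active, j],
                                 pt$energies[j] - pt$energies[active],
                                 reverse_frustrated)
          events[[length(events) + 1L]] <- list(
            t_fs = step * dt_fs, from = active, to = j,
            accepted = rs$accepted, kinetic_deficit_ev = rs$kinetic_deficit_ev,
            q_at_hop = q)
          if (rs$accepted) {
            p <- rs$p
            active <- j
            e_ref <- pt$energies[active] + ekin_dyn(p)
            if (active == 1L) {
              if (is.na(t_gs)) t_gs <- step * dt_fs
              if (irreversible_gs) hop_enabled <- FALSE
            }
          }
        }
      }
      c_amp <- decoherence_step(c_amp, active, pt$energies, ekin_dyn(p),
                                dt_fs, decoherence_c)
    }

    drift <- abs(pt$energies[active] + ekin_dyn(p) - e_ref)
    if (drift > max_drift) max_drift <- drift

    tq[step + 1L, ] <- q; tp[step + 1L, ] <- p; tact[step + 1L] <- active
    tamp[step + 1L, ] <- c_amp; tE[step + 1L, ] <- pt$energies
    tdip[step + 1L, , ] <- pt$dipoles

    if (!is.na(t_gs) && is.finite(gs_window_fs) &&
        step * dt_fs >= t_gs + gs_window_fs) {
      n_recorded <- step + 1L
      ## freeze the remaining record at the last state (population bookkeeping)
      if (step < n_steps) {
        idx <- seq.int(step + 2L, n_steps + 1L)
        tact[idx] <- active
        tE[idx, ] <- rep(pt$energies, each = length(idx))
      }
      break
    }
  }

  ev <- if (length(events)) {
    data.frame(
      t_fs = vapply(events, `[[`, numeric(1), "t_fs"),
      from = vapply(events, `[[`, integer(1), "from"),
      to = vapply(events, `[[`, integer(1), "to"),
      accepted = vapply(events, `[[`, logical(1), "accepted"),
      kinetic_deficit_ev = vapply(events, `[[`, numeric(1), "kinetic_deficit_ev")
    )
  } else {
    data.frame(t_fs = numeric(0), from = integer(0), to = integer(0),
               accepted = logical(0), kinetic_deficit_ev = numeric(0))
  }
  if (length(events)) {
    ev$q_at_hop <- I(lapply(events, `[[`, "q_at_hop"))
  }

  structure(list(
    t_fs = (0:n_steps) * dt_fs,
    q = tq, p = tp, active = tact, amps = tamp,
    energies = tE, energies_ev = hartree_to_ev(tE), dipoles = tdip,
    hop_g = tg,
    events = ev, seed = as.integer(seed), dt_fs = dt_fs,
    model_family = model$family, bright = model$bright,
    n_states = ns, masses_me = masses,
    valid = max_drift <= drift_tol_h, max_drift_h = max_drift,
    t_gs_fs = t_gs, n_recorded = n_recorded
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s, %d states, %.0f fs @ %.2g fs, seed %d>\n",
              x$model_family, x$n_states, max(x$t_fs), x$dt_fs, x$seed))
  cat(sprintf("  hops: %d accepted / %d proposed; ground-state arrival: %s\n",
              sum(x$events$accepted), nrow(x$events),
              if (is.na(x$t_gs_fs)) "none" else sprintf("%.0f fs", x$t_gs_fs)))
  cat(sprintf("  max energy drift between hops: %.2e hartree (%s)\n",
              x$max_drift_h, if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Run a swarm of surface-hopping trajectories
#'
#' Propagates one trajectory per phase-space sample with per-trajectory seeds
#' `base_seed + index`, collects them into an ensemble and computes the
#' per-state population traces \eqn{P_i(t)} (fraction of trajectories with
#' active state `i`). Individual trajectory failures are recorded, not fatal;
#' an all-failed ensemble is an error.
#'
#' @param model an `electronic_model`.
#' @param samples a `phase_space_samples` object.
#' @param t_max_fs,dt_fs,base_seed,... passed to [run_trajectory()].
#' @return an object of class `ensemble`: `trajectories` (list), `model`,
#'   `populations` (data.frame `time_fs`, one `P_<label>` column per state),
#'   `base_seed`, `failures` (character messages), `n_invalid`.
#' @export
run_ensemble <- function(model, samples, t_max_fs, dt_fs = 1.0, base_seed = 1, ...) {
  n <- nrow(samples$q)
  if (n < 1) stop("need at least one sample")
  trajs <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    trajs[[i]] <- tryCatch(
      run_trajectory(model, samples$q[i, ], samples$p[i, ], t_max_fs,
                     dt_fs = dt_fs, seed = base_seed + i, ...),
      error = function(e) {
        failures <<- c(failures, sprintf("trajectory %d: %s", i, conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(trajs, is.null, logical(1))
  if (!any(ok)) stop("all trajectories failed: ", paste(failures, collapse = "; "))
  trajs <- trajs[ok]
  ens <- structure(list(
    trajectories = trajs, model = model, base_seed = base_seed,
    failures = failures,
    n_invalid = sum(!vapply(trajs, `[[`, logical(1), "valid"))
  ), class = "ensemble")
  ens$populations <- ensemble_populations(ens)
  ens
}

#' Population traces of an ensemble
#'
#' Recounts \eqn{P_i(t)} from the trajectories' active-state series.
#'
#' @param ensemble an `ensemble`.
#' @return data.frame with `time_fs` and one `P_<label>` column per state;
#'   rows sum to 1.
#' @export
ensemble_populations <- function(ensemble) {
  trajs <- ensemble$trajectories
  t_fs <- trajs[[1]]$t_fs
  ns <- trajs[[1]]$n_states
  act <- vapply(trajs, `[[`, integer(length(t_fs)), "active")
  P <- vapply(seq_len(ns), function(s) rowMeans(act == s), numeric(length(t_fs)))
  df <- data.frame(time_fs = t_fs, P)
  names(df)[-1] <- paste0("P_", gsub("[^A-Za-z0-9]", "", ensemble$model$labels))
  df
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble: %d trajectories on %s, base seed %d>\n",
              length(x$trajectories), x$model$family, x$base_seed))
  decayed <- sum(!is.na(vapply(x$trajectories, `[[`, numeric(1), "t_gs_fs")))
  cat(sprintf("  decayed to the ground state: %d / %d; invalid: %d; failed: %d\n",
              decayed, length(x$trajectories), x$n_invalid, length(x$failures)))
  invisible(x)
}

#' Upper bound on transfer out of the bright state (diabatic re-hop)
#'
#' Re-integrates the electronic amplitudes in the *diabatic* basis of an
#' extended model (which adds at least one state, e.g. a dark state, to the
#' propagated basis) along the frozen nuclear paths of an ensemble, making
#' fewest-switches hop decisions from the bright diabat at every step, without
#' re-propagating the nuclei and without momentum rescaling or decoherence.
#' The fraction of trajectories that would depart from the bright state to
#' another excited diabat before their adiabatic ground-state hop is an upper
#' bound on the yield of nonadiabatic transfer.
#'
#' @param ensemble an `ensemble` (typically propagated on the two-state model).
#' @param extended_model an `electronic_model` with the same mode count and at
#'   least as many states as the ensemble's model.
#' @param seed RNG seed for the re-hop decisions.
#' @return list with `fraction`, `ci` (95% binomial confidence interval),
#'   `n`, `departed` (logical per trajectory) and `t_depart_fs`.
#' @export
diabatic_rehop <- function(ensemble, extended_model, seed = 1) {
  mod0 <- ensemble$model
  if (extended_model$n_modes != mod0$n_modes) {
    stop("extended model inconsistent with stored geometry dimension")
  }
  if (extended_model$n_states < mod0$n_states) {
    stop("extended model must have at least as many states as the propagated model")
  }
  ns <- extended_model$n_states
  bright <- extended_model$bright
  if (is.na(bright)) stop("extended model has no bright state defined")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  trajs <- ensemble$trajectories
  departed <- logical(length(trajs))
  t_dep <- rep(NA_real_, length(trajs))
  excited <- setdiff(seq_len(ns), c(1L, bright))
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    set.seed(as.integer(seed) + k)
    n_t <- tr$n_recorded
    stop_t <- if (is.na(tr$t_gs_fs)) Inf else tr$t_gs_fs
    c_amp <- rep(0 + 0i, ns); c_amp[bright] <- 1 + 0i
    Vprev <- extended_model$diabatic(tr$q[1L, ])$V
    dt <- fs_to_au(tr$dt_fs)
    for (i in seq.int(2L, n_t)) {
      t_now <- tr$t_fs[i]
      if (t_now > stop_t) break
      Vnow <- extended_model$diabatic(tr$q[i, ])$V
      ebar <- mean(c(diag(Vprev), diag(Vnow)))
      nsub <- max(20L, ceiling(max(abs(c(Vprev - diag(ebar, ns),
                                         Vnow - diag(ebar, ns)))) * dt / 0.04))
      res <- tdse_rk4_diabatic(c_amp, Vprev - diag(ebar, ns),
                               Vnow - diag(ebar, ns), dt, nsub, bright)
      c_amp <- res$c
      ## fewest-switches decision on the substep-accumulated diabatic fluxes
      cum <- cumsum(res$g)
      tsel <- which(stats::runif(1) < cum)[1]
      if (!is.na(tsel) && res$g[tsel] > 0) {
        if (tsel %in% excited) {
          departed[k] <- TRUE
          t_dep[k] <- t_now
        }
        break   # departure to a dark diabat, or internal conversion
      }
      Vprev <- Vnow
    }
  }
  n <- length(trajs)
  ci <- as.numeric(stats::binom.test(sum(departed), n)$conf.int)
  list(fraction = mean(departed), ci = ci, n = n,
       departed = departed, t_depart_fs = t_dep)
}
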