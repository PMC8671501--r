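## Analytic diabatic vibronic models: the desk-scale stand-in for on-the-fly
## electronic structure. A model knows its diabatic potential matrix V(q), the
## analytic gradient dV/dq, and a (diabatic) transition-dipole matrix; the
## adiabatic picture (energies, gradients, nonadiabatic couplings, dipoles)
## is obtained by diagonalization in eval_adiabatic().
##
## Internal units everywhere: hartree, bohr, electron mass, a.u. of time.
## Constructor arguments are in eV / cm^-1 / amu and are converted once.

#' Construct an electronic model
#'
#' Low-level constructor for analytic multi-state, multi-mode diabatic models.
#' Most users should call [make_tully_model()] or [make_pucker_model()].
#'
#' @param n_states number of electronic states.
#' @param n_modes number of nuclear modes.
#' @param masses_amu per-mode effective masses (amu).
#' @param diabatic function `q -> list(V, dV)` with `V` an `n_states` x
#'   `n_states` symmetric matrix (hartree) and `dV` an array
#'   `c(n_modes, n_states, n_states)` of analytic derivatives
#'   (hartree/bohr). Coordinates `q` are in bohr.
#' @param dipole either a constant symmetric `n_states` x `n_states` matrix of
#'   diabatic transition dipole magnitudes (a.u.) or a function `q -> matrix`.
#' @param labels per-state tags, e.g. `c("S0", "pipi*", "npi*")`.
#' @param params named list of the scalars that define the model (reported
#'   units: eV, cm^-1, amu, fs).
#' @param bright index of the spectroscopically bright state (adiabatic index
#'   at the Franck-Condon point), or `NA`.
#' @param sample_wavenumbers_cm per-mode ground-state wavenumbers used for
#'   Wigner sampling (`NA` for modes that are not sampled).
#' @param overdamped logical per-mode flag; overdamped modes carry no momentum
#'   and relax exponentially toward `relax_target` with time constant
#'   `relax_tau_fs` instead of obeying Newtonian dynamics.
#' @param relax_tau_fs,relax_target relaxation parameters for overdamped modes.
#' @param channel_coords named list mapping decay-channel names to
#'   `list(mode = <index>, threshold = <bohr>)`, used by the channel
#'   classifier.
#' @param local_hmax optional function `q -> h` giving a local upper bound
#'   (a.u. of time) on the inner Verlet step, used to resolve stiff regions
#'   (walls, avoided-crossing kinks) that a displacement cap alone misses.
#' @param diabatic2 optional flat fast path for two-state models: function
#'   `q -> list(v11, v22, v12, d11, d22, d12)` (scalars and per-mode
#'   derivative vectors) avoiding matrix allocation in the propagation hot
#'   loop; must agree with `diabatic`.
#' @param family internal tag used for config round-trips.
#' @return an object of class `electronic_model`.
#' @export
electronic_model <- function(n_states, n_modes, masses_amu, diabatic, dipole,
                             labels = paste0("S", seq_len(n_states) - 1L),
                             params = list(), bright = NA_integer_,
                             sample_wavenumbers_cm = rep(NA_real_, n_modes),
                             overdamped = rep(FALSE, n_modes),
                             relax_tau_fs = NA_real_, relax_target = NA_real_,
                             channel_coords = list(), family = "custom",
                             local_hmax = NULL, diabatic2 = NULL) {
  stopifnot(n_states >= 1, n_modes >= 1, length(masses_amu) == n_modes)
  if (any(!is.finite(masses_amu)) || any(masses_amu <= 0)) {
    stop("masses must be positive and finite")
  }
  if (!is.function(dipole)) {
    dmat <- as.matrix(dipole)
    if (any(dmat < 0)) stop("dipole magnitudes must be non-negative")
    if (max(abs(dmat - t(dmat))) > 1e-12) stop("dipole matrix must be symmetric")
    dipole_fn <- function(q) dmat
  } else {
    dipole_fn <- dipole
  }
  m <- structure(list(
    n_states = as.integer(n_states),
    n_modes = as.integer(n_modes),
    masses_amu = as.numeric(masses_amu),
    masses_me = amu_to_me(as.numeric(masses_amu)),
    diabatic = diabatic,
    dipole = dipole_fn,
    labels = labels,
    params = params,
    bright = as.integer(bright),
    sample_wavenumbers_cm = sample_wavenumbers_cm,
    overdamped = overdamped,
    relax_tau_fs = relax_tau_fs,
    relax_target = relax_target,
    channel_coords = channel_coords,
    local_hmax = local_hmax,
    diabatic2 = diabatic2,
    family = family
  ), class = "electronic_model")
  m
}

#' @export
print.electronic_model <- function(x, ...) {
  cat(sprintf("<electronic_model: %s>\n", x$family))
  cat(sprintf("  states: %d (%s)\n", x$n_states, paste(x$labels, collapse = ", ")))
  cat(sprintf("  modes:  %d, masses [amu]: %s\n", x$n_modes,
              paste(signif(x$masses_amu, 4), collapse = ", ")))
  if (length(x$params)) {
    cat("  params:\n")
    for (nm in names(x$params)) {
      v <- x$params[[nm]]
      if (is.numeric(v)) cat(sprintf("    %s = %s\n", nm, paste(signif(v, 5), collapse = ", ")))
    }
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Tully 1D two-state benchmarks (standard parameter sets, atomic units)
## ---------------------------------------------------------------------------

#' Canonical 1D two-state scattering benchmarks
#'
#' The three standard one-dimensional avoided-crossing models used to
#' benchmark fewest-switches surface hopping against exact wavepacket
#' propagation. Parameters are the published standard sets (atomic units);
#' the nuclear mass is 2000 electron masses.
#'
#' @param model_id one of `"simple_avoided_crossing"`,
#'   `"dual_avoided_crossing"`, `"extended_coupling"`.
#' @return an `electronic_model` with one mode and two states.
#' @examples
#' m <- make_tully_model("simple_avoided_crossing")
#' pt <- eval_adiabatic(m, 0)
#' diff(pt$energies)  # adiabatic gap at the crossing = 2*V12(0) = 0.01
#' @export
make_tully_model <- function(model_id = c("simple_avoided_crossing",
                                          "dual_avoided_crossing",
                                          "extended_coupling")) {
  model_id <- match.arg(model_id)
  mass_me <- 2000
  if (model_id == "simple_avoided_crossing") {
    A <- 0.01; B <- 1.6; C <- 0.005; D <- 1.0
    diab <- function(q) {
      x <- q[1]
      v11 <- if (x >= 0) A * (1 - exp(-B * x)) else -A * (1 - exp(B * x))
      d11 <- A * B * exp(-B * abs(x))
      v12 <- C * exp(-D * x^2)
      d12 <- -2 * D * x * v12
      V <- matrix(c(v11, v12, v12, -v11), 2, 2)
      dV <- array(c(d11, d12, d12, -d11), c(1, 2, 2))
      list(V = V, dV = dV)
    }
    diab2 <- function(q) {
      x <- q[1]
      v11 <- if (x >= 0) A * (1 - exp(-B * x)) else -A * (1 - exp(B * x))
      d11 <- A * B * exp(-B * abs(x))
      v12 <- C * exp(-D * x^2)
      list(v11 = v11, v22 = -v11, v12 = v12,
           d11 = d11, d22 = -d11, d12 = -2 * D * x * v12)
    }
    params <- list(A = A, B = B, C = C, D = D, mass_me = mass_me)
  } else if (model_id == "dual_avoided_crossing") {
    A <- 0.10; B <- 0.28; C <- 0.015; D <- 0.06; E0 <- 0.05
    diab <- function(q) {
      x <- q[1]
      v22 <- -A * exp(-B * x^2) + E0
      d22 <- 2 * A * B * x * exp(-B * x^2)
      v12 <- C * exp(-D * x^2)
      d12 <- -2 * D * x * v12
      V <- matrix(c(0, v12, v12, v22), 2, 2)
      dV <- array(c(0, d12, d12, d22), c(1, 2, 2))
      list(V = V, dV = dV)
    }
    diab2 <- function(q) {
      x <- q[1]
      v22 <- -A * exp(-B * x^2) + E0
      v12 <- C * exp(-D * x^2)
      list(v11 = 0, v22 = v22, v12 = v12,
           d11 = 0, d22 = 2 * A * B * x * exp(-B * x^2),
           d12 = -2 * D * x * v12)
    }
    params <- list(A = A, B = B, C = C, D = D, E0 = E0, mass_me = mass_me)
  } else {
    A <- 6e-4; B <- 0.10; C <- 0.90
    diab <- function(q) {
      x <- q[1]
      if (x < 0) {
        v12 <- B * exp(C * x); d12 <- C * v12
      } else {
        v12 <- B * (2 - exp(-C * x)); d12 <- B * C * exp(-C * x)
      }
      V <- matrix(c(A, v12, v12, -A), 2, 2)
      dV <- array(c(0, d12, d12, 0), c(1, 2, 2))
      list(V = V, dV = dV)
    }
    diab2 <- function(q) {
      x <- q[1]
      if (x < 0) {
        v12 <- B * exp(C * x); d12 <- C * v12
      } else {
        v12 <- B * (2 - exp(-C * x)); d12 <- B * C * exp(-C * x)
      }
      list(v11 = A, v22 = -A, v12 = v12, d11 = 0, d22 = 0, d12 = d12)
    }
    params <- list(A = A, B = B, C = C, mass_me = mass_me)
  }
  electronic_model(
    n_states = 2, n_modes = 1,
    masses_amu = mass_me / hopta_constants$me_per_amu,
    diabatic = diab,
    dipole = matrix(c(0, 1, 1, 0), 2, 2),
    labels = c("lower", "upper"),
    params = c(params, list(model_id = model_id)),
    diabatic2 = diab2,
    family = paste0("tully_", model_id)
  )
}

## ---------------------------------------------------------------------------
## Single- or multi-mode harmonic model (oracle surface for integrator and
## normal-mode tests)
## ---------------------------------------------------------------------------

#' Harmonic single-surface model
#'
#' Uncoupled harmonic oscillators on a single electronic state, used as the
#' closed-form oracle surface for the nuclear integrator and for normal-mode
#' round trips.
#'
#' @param wavenumbers_cm per-mode wavenumbers (cm^-1).
#' @param masses_amu per-mode masses (amu).
#' @param centers_bohr per-mode equilibrium positions (default 0).
#' @param e0_ev energy offset at the minimum (eV).
#' @return an `electronic_model` with one state.
#' @export
make_harmonic_model <- function(wavenumbers_cm, masses_amu = rep(1, length(wavenumbers_cm)),
                                centers_bohr = rep(0, length(wavenumbers_cm)),
                                e0_ev = 0) {
  if (any(wavenumbers_cm <= 0) || any(masses_amu <= 0)) {
    stop("wavenumbers and masses must be positive")
  }
  n <- length(wavenumbers_cm)
  w <- cm_to_au_freq(wavenumbers_cm)
  mm <- amu_to_me(masses_amu)
  k <- mm * w^2
  e0 <- ev_to_hartree(e0_ev)
  ctr <- centers_bohr
  diab <- function(q) {
    dq <- q - ctr
    V <- matrix(e0 + sum(0.5 * k * dq^2), 1, 1)
    dV <- array(k * dq, c(n, 1, 1))
    list(V = V, dV = dV)
  }
  electronic_model(
    n_states = 1, n_modes = n, masses_amu = masses_amu,
    diabatic = diab, dipole = matrix(0, 1, 1), labels = "S0",
    params = list(wavenumbers_cm = wavenumbers_cm, centers_bohr = centers_bohr,
                  e0_ev = e0_ev),
    sample_wavenumbers_cm = wavenumbers_cm,
    family = "harmonic"
  )
}

## ---------------------------------------------------------------------------
## Nucleoside-mimetic "pucker" model
## ---------------------------------------------------------------------------

#' Nucleoside-mimetic conical-intersection model
#'
#' A linear-vibronic-coupling-style construction reproducing the mechanistic
#' ingredients of pyrimidine nucleoside photophysics at desk scale: a bright
#' state that decays to the ground state through a barrier-controlled crossing
#' along a ring-puckering coordinate, gap-modulating tuning modes near 600 and
#' 750 cm^-1, an optional nearby dark state, and an overdamped solvent
#' coordinate that gates the barrier.
#'
#' Modes (in order): 1 = puckering (mass `mass_pucker_amu`), 2-3 = tuning
#' modes, 4 = solvent. Along the puckering coordinate \eqn{q_p} (with
#' \eqn{u = q_p^2}) the bright diabat is
#' \deqn{V_b = E_b + B_{eff}(q_s)\, g(u) - D\,[h(u)-h(0)] - \lambda_{shift} q_s
#'       + W(u) + \textstyle\sum_t [\tfrac12 m_t \omega_t^2 q_t^2 + \kappa_t q_t],}
#' where \eqn{g(u) = (u/u_c) e^{1-u/u_c}} is a unit-height barrier bump at
#' \eqn{q_p = q_c}, \eqn{h} is a smooth switch that drops the surface by `D`
#' beyond the barrier so that it crosses the rising ground-state diabat, and
#' \eqn{W = k_4 u^2} is a common confining wall added to every diagonal
#' element (it cancels in all gaps). The effective barrier height is
#' \deqn{B_{eff} = \Delta E^\ddagger + \lambda_s (1 - q_s),}
#' so relaxation of the solvent coordinate \eqn{q_s : 0 \to 1} (overdamped,
#' time constant `solvent_tau_fs`) lowers the barrier; `solvent_shift_ev`
#' additionally lowers the bright state as the solvent relaxes (the
#' stimulated-emission red-shift). The diabatic bright/ground coupling is a
#' Gaussian in \eqn{u} centred at the crossing, located numerically at build
#' time.
#'
#' @param mass_pucker_amu effective mass of the puckering mode; ~1 amu for a
#'   hydrogen out-of-plane motion, ~15 amu for a methyl-carrying one.
#' @param barrier_ev static barrier height \eqn{\Delta E^\ddagger} (eV),
#'   physically 0-0.3.
#' @param solvent_coupling_ev \eqn{\lambda_s \ge 0}: barrier contribution of
#'   the unrelaxed solvent (eV).
#' @param solvent_tau_fs solvent relaxation time constant (fs).
#' @param solvent_shift_ev stabilisation of the bright state by the relaxed
#'   solvent (eV); produces the SE red-shift.
#' @param tuning_wavenumbers_cm wavenumbers of the two gap-modulating modes.
#' @param tuning_masses_amu their effective masses.
#' @param tuning_kappa_ev_bohr linear (gap-modulating) couplings on the bright
#'   state (eV/bohr).
#' @param pucker_wavenumber_cm ground-state wavenumber of the puckering mode.
#' @param e_bright_ev vertical excitation energy of the bright state at the
#'   Franck-Condon point (eV).
#' @param coupling_ev diabatic bright/ground coupling amplitude (eV); sets the
#'   hop probability per crossing passage.
#' @param coupling_width_u Gaussian width of the coupling in \eqn{u = q_p^2}
#'   (bohr^2).
#' @param drop_ev depth `D` of the post-barrier drop (eV).
#' @param drop_center_bohr,drop_width_u location (bohr) and width (bohr^2) of
#'   the switch `h`.
#' @param bump_center_bohr barrier position \eqn{q_c} (bohr).
#' @param tilt_ev gentle downhill slope of the bright surface along
#'   \eqn{u = q_p^2} (eV/bohr^2); guarantees that the barrierless surface is
#'   strictly downhill toward the crossing (the ballistic limit).
#' @param wall_gs_ev ground-state confining wall coefficient (eV/bohr^4;
#'   quartic in \eqn{q_p}, added to the ground diabat only so that the bright
#'   surface and the scanned barrier are untouched).
#' @param wall_es_ev excited-state confining wall coefficient (eV/bohr^6;
#'   sextic, late-onset, added to the excited diabats; keeps the
#'   hot-ground-state trajectory bound and its vertical gap inside the probe
#'   window).
#' @param include_dark if `TRUE` (default) include the dark state in the
#'   propagated basis; `FALSE` gives the two-state (ground + bright) model
#'   used for production dynamics, with the dark state reserved for the
#'   diabatic re-hop analysis.
#' @param dark_offset_ev vertical offset of the dark state above the bright
#'   state at the FC point (eV; positive = above, as in aqueous solution).
#' @param dark_coupling_ev constant diabatic bright/dark coupling (eV).
#' @param mu_bright,mu_dark,mu_esa diabatic transition dipole magnitudes
#'   (a.u.): ground-bright, ground-dark, bright-dark.
#' @return an `electronic_model`; modes carry `channel_coords` entries for
#'   `puckering` (mode 1), `ring_opening` (mode 2) and `O_oop` (mode 3).
#' @export
make_pucker_model <- function(mass_pucker_amu = 1,
                              barrier_ev = 0,
                              solvent_coupling_ev = 0,
                              solvent_tau_fs = 300,
                              solvent_shift_ev = 0.15,
                              tuning_wavenumbers_cm = c(600, 750),
                              tuning_masses_amu = c(6, 6),
                              tuning_kappa_ev_bohr = c(-0.55, 0.75),
                              pucker_wavenumber_cm = 400,
                              e_bright_ev = 4.52,
                              coupling_ev = 0.5,
                              coupling_width_u = 0.6,
                              drop_ev = 8,
                              drop_center_bohr = 1.4,
                              drop_width_u = 0.3,
                              bump_center_bohr = 0.8,
                              tilt_ev = 0.01,
                              wall_gs_ev = 0.02,
                              wall_es_ev = 0.002,
                              include_dark = TRUE,
                              dark_offset_ev = 0.15,
                              dark_coupling_ev = 0.05,
                              mu_bright = 1.0, mu_dark = 0.05, mu_esa = 0.3) {
  if (mass_pucker_amu <= 0 || any(tuning_masses_amu <= 0)) {
    stop("masses must be positive")
  }
  if (pucker_wavenumber_cm <= 0 || any(tuning_wavenumbers_cm <= 0)) {
    stop("wavenumbers must be positive")
  }
  if (solvent_coupling_ev < 0) stop("solvent_coupling must be >= 0")
  if (barrier_ev < 0 || barrier_ev > 0.3) {
    stop("barrier_ev outside the supported range [0, 0.3] eV")
  }

  n_states <- if (include_dark) 3L else 2L
  ## converted constants (hartree / bohr / me)
  Eb   <- ev_to_hartree(e_bright_ev)
  B0   <- ev_to_hartree(barrier_ev)
  lam  <- ev_to_hartree(solvent_coupling_ev)
  shf  <- ev_to_hartree(solvent_shift_ev)
  D    <- ev_to_hartree(drop_ev)
  c12  <- ev_to_hartree(coupling_ev)
  cbd  <- ev_to_hartree(dark_coupling_ev)
  Ed   <- Eb + ev_to_hartree(dark_offset_ev)
  tlt  <- ev_to_hartree(tilt_ev)
  k4   <- ev_to_hartree(wall_gs_ev)
  k6   <- ev_to_hartree(wall_es_ev)
  kap  <- ev_to_hartree(tuning_kappa_ev_bohr)
  mp   <- amu_to_me(mass_pucker_amu)
  mt   <- amu_to_me(tuning_masses_amu)
  wp   <- cm_to_au_freq(pucker_wavenumber_cm)
  wt   <- cm_to_au_freq(tuning_wavenumbers_cm)
  kp   <- mp * wp^2
  kt   <- mt * wt^2
  uc   <- bump_center_bohr^2
  uh   <- drop_center_bohr^2
  wu   <- drop_width_u
  h0   <- 0.5 * (1 + tanh(-uh / wu))

  ## bright-minus-ground diabatic gap along the pucker coordinate at
  ## q_t = 0, q_s = 0 (used to locate the crossing for the coupling centre)
  gap_p <- function(qp) {
    u <- qp^2
    g <- (u / uc) * exp(1 - u / uc)
    h <- 0.5 * (1 + tanh((u - uh) / wu))
    (Eb + (B0 + lam) * g - D * (h - h0) - tlt * u) - 0.5 * kp * u
  }
  x_hi <- drop_center_bohr + 4
  if (gap_p(x_hi) >= 0) stop("drop_ev too small: bright diabat never crosses the ground state")
  q_x <- stats::uniroot(gap_p, c(bump_center_bohr, x_hi), tol = 1e-10)$root
  ux  <- q_x^2
  su  <- coupling_width_u

  diab <- function(q) {
    qp <- q[1]; q1 <- q[2]; q2 <- q[3]; qs <- q[4]
    u  <- qp * qp
    g  <- (u / uc) * exp(1 - u / uc)
    dg <- (1 / uc) * exp(1 - u / uc) * (1 - u / uc)      # dg/du
    th <- tanh((u - uh) / wu)
    h  <- 0.5 * (1 + th)
    dh <- 0.5 * (1 - th * th) / wu                       # dh/du
    Wg  <- k4 * u * u                                    # ground-state wall
    dWg <- 2 * k4 * u
    We  <- k6 * u * u * u                                # excited-state wall
    dWe <- 3 * k6 * u * u
    Beff <- B0 + lam * (1 - qs)
    ht   <- 0.5 * kt[1] * q1^2 + 0.5 * kt[2] * q2^2      # tuning harmonics
    v12  <- c12 * exp(-(u - ux)^2 / (2 * su^2))
    dv12 <- v12 * (-(u - ux) / su^2)                     # d v12 / du

    V11 <- 0.5 * kp * u + ht + Wg
    V22 <- Eb + ht + kap[1] * q1 + kap[2] * q2 +
      Beff * g - D * (h - h0) - tlt * u - shf * qs + We
    ## derivatives wrt q (chain rule du/dqp = 2 qp)
    dV11 <- c((0.5 * kp + dWg) * 2 * qp, kt[1] * q1, kt[2] * q2, 0)
    dV22 <- c((Beff * dg - D * dh - tlt + dWe) * 2 * qp,
              kt[1] * q1 + kap[1], kt[2] * q2 + kap[2],
              -lam * g - shf)
    dV12 <- c(dv12 * 2 * qp, 0, 0, 0)

    if (n_states == 2L) {
      V <- matrix(c(V11, v12, v12, V22), 2, 2)
      dV <- array(0, c(4, 2, 2))
      dV[, 1, 1] <- dV11; dV[, 2, 2] <- dV22
      dV[, 1, 2] <- dV12; dV[, 2, 1] <- dV12
    } else {
      V33 <- Ed + ht + 0.5 * (kap[1] * q1 + kap[2] * q2) +
        0.5 * kp * u - shf * qs + We
      dV33 <- c((0.5 * kp + dWe) * 2 * qp,
                kt[1] * q1 + 0.5 * kap[1], kt[2] * q2 + 0.5 * kap[2], -shf)
      V <- matrix(c(V11, v12, 0,
                    v12, V22, cbd,
                    0,   cbd, V33), 3, 3)
      dV <- array(0, c(4, 3, 3))
      dV[, 1, 1] <- dV11; dV[, 2, 2] <- dV22; dV[, 3, 3] <- dV33
      dV[, 1, 2] <- dV12; dV[, 2, 1] <- dV12
    }
    list(V = V, dV = dV)
  }

  diab2 <- if (n_states == 2L) function(q) {
    qp <- q[1]; q1 <- q[2]; q2 <- q[3]; qs <- q[4]
    u  <- qp * qp
    g  <- (u / uc) * exp(1 - u / uc)
    dg <- (1 / uc) * exp(1 - u / uc) * (1 - u / uc)
    th <- tanh((u - uh) / wu)
    dh <- 0.5 * (1 - th * th) / wu
    Beff <- B0 + lam * (1 - qs)
    ht   <- 0.5 * kt[1] * q1^2 + 0.5 * kt[2] * q2^2
    v12  <- c12 * exp(-(u - ux)^2 / (2 * su^2))
    list(v11 = 0.5 * kp * u + ht + k4 * u * u,
         v22 = Eb + ht + kap[1] * q1 + kap[2] * q2 + Beff * g -
           D * (0.5 * (1 + th) - h0) - tlt * u - shf * qs + k6 * u^3,
         v12 = v12,
         d11 = c((0.5 * kp + 2 * k4 * u) * 2 * qp, kt[1] * q1, kt[2] * q2, 0),
         d22 = c((Beff * dg - D * dh - tlt + 3 * k6 * u * u) * 2 * qp,
                 kt[1] * q1 + kap[1], kt[2] * q2 + kap[2], -lam * g - shf),
         d12 = c(v12 * (-(u - ux) / su^2) * 2 * qp, 0, 0, 0))
  } else NULL

  ## local stiffness bound for the nuclear integrator: harmonic + walls +
  ## the avoided-crossing kink (curvature ~ slope^2 / gap at the crossing)
  kink_slope <- D * (0.5 / wu) * 2 * sqrt(uh)
  kappa_kink <- kink_slope^2 / (2 * max(c12, 1e-4))
  local_hmax_fn <- function(q) {
    u <- q[1] * q[1]
    kappa <- kp + 30 * k6 * u * u + 12 * k4 * u +
      kappa_kink * exp(-(u - ux)^2 / (2 * su^2))
    0.03 / sqrt(kappa / mp)
  }

  dip <- if (include_dark) {
    matrix(c(0, mu_bright, mu_dark,
             mu_bright, 0, mu_esa,
             mu_dark, mu_esa, 0), 3, 3)
  } else {
    matrix(c(0, mu_bright, mu_bright, 0), 2, 2)
  }

  electronic_model(
    n_states = n_states, n_modes = 4,
    masses_amu = c(mass_pucker_amu, tuning_masses_amu, 1),
    diabatic = diab, dipole = dip, diabatic2 = diab2,
    labels = if (include_dark) c("S0", "pipi*", "npi*") else c("S0", "pipi*"),
    params = list(
      mass_pucker_amu = mass_pucker_amu, barrier_ev = barrier_ev,
      solvent_coupling_ev = solvent_coupling_ev, solvent_tau_fs = solvent_tau_fs,
      solvent_shift_ev = solvent_shift_ev,
      tuning_wavenumbers_cm = tuning_wavenumbers_cm,
      tuning_masses_amu = tuning_masses_amu,
      tuning_kappa_ev_bohr = tuning_kappa_ev_bohr,
      pucker_wavenumber_cm = pucker_wavenumber_cm,
      e_bright_ev = e_bright_ev, coupling_ev = coupling_ev,
      coupling_width_u = coupling_width_u, drop_ev = drop_ev,
      drop_center_bohr = drop_center_bohr, drop_width_u = drop_width_u,
      bump_center_bohr = bump_center_bohr, tilt_ev = tilt_ev,
      wall_gs_ev = wall_gs_ev,
      wall_es_ev = wall_es_ev,
      include_dark = include_dark, dark_offset_ev = dark_offset_ev,
      dark_coupling_ev = dark_coupling_ev,
      mu_bright = mu_bright, mu_dark = mu_dark, mu_esa = mu_esa,
      crossing_bohr = q_x
    ),
    bright = 2L,
    sample_wavenumbers_cm = c(pucker_wavenumber_cm, tuning_wavenumbers_cm, NA),
    overdamped = c(FALSE, FALSE, FALSE, TRUE),
    relax_tau_fs = solvent_tau_fs, relax_target = 1,
    channel_coords = list(
      puckering    = list(mode = 1L, threshold = 0.5 * q_x),
      ring_opening = list(mode = 2L, threshold = 1.0),
      O_oop        = list(mode = 3L, threshold = 1.0)
    ),
    local_hmax = local_hmax_fn,
    family = "pucker"
  )
}

## ---------------------------------------------------------------------------
## Adiabatic evaluation
## ---------------------------------------------------------------------------

#' Evaluate a model in the adiabatic representation
#'
#' Diagonalizes the diabatic potential at geometry `q` and returns adiabatic
#' energies (ascending), analytic Hellmann-Feynman gradients, nonadiabatic
#' coupling vectors \eqn{d_{ij} = \langle i | \nabla V | j \rangle / (E_j -
#' E_i)} and adiabatic transition dipole magnitudes. Near-degenerate pairs
#' (gap below `degeneracy_tol`) have their couplings magnitude-capped and are
#' flagged.
#'
#' @param model an `electronic_model`.
#' @param q geometry, length `n_modes` (bohr).
#' @param u_prev optional eigenvector matrix from a previous call; eigenvector
#'   signs are aligned against it for continuity along a path.
#' @param degeneracy_tol adiabatic gap (hartree) below which the pair is
#'   flagged degenerate; default 1e-5.
#' @return an object of class `adiabatic_point`: list with `energies`
#'   (hartree), `energies_ev`, `gradients` (`n_modes` x `n_states`,
#'   hartree/bohr), `nac` (array `n_modes` x `n_states` x `n_states`,
#'   antisymmetric in the state indices), `dipoles` (magnitudes, a.u.),
#'   `U` (eigenvector columns), `degenerate` (logical state-pair matrix) and
#'   `V` (the diabatic matrix).
#' @export
eval_adiabatic <- function(model, q, u_prev = NULL, degeneracy_tol = 1e-5) {
  if (length(q) != model$n_modes || any(!is.finite(q))) {
    stop("q must be finite with length n_modes")
  }
  d <- model$diabatic(q)
  V <- d$V
  ns <- model$n_states
  if (ns == 1L) {
    E <- V[1, 1]
    U <- matrix(1, 1, 1)
  } else if (ns == 2L) {
    ## closed-form symmetric 2x2 diagonalization (hot path)
    a <- V[1, 1]; b <- V[2, 2]; c <- V[1, 2]
    half <- 0.5 * (a + b)
    r <- sqrt(0.25 * (a - b)^2 + c * c)
    E <- c(half - r, half + r)
    if (r < .Machine$double.eps) {
      U <- diag(2)
    } else {
      ## eigenvector of lower state
      th <- 0.5 * atan2(2 * c, a - b)
      U <- matrix(c(-sin(th), cos(th), cos(th), sin(th)), 2, 2)
      ## columns ordered ascending: check
      if (sum(U[, 1] * (V %*% U[, 1])) > sum(U[, 2] * (V %*% U[, 2]))) {
        U <- U[, 2:1]
      }
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
  nm <- model$n_modes
  grad <- matrix(0, nm, ns)
  nac <- array(0, c(nm, ns, ns))
  degen <- matrix(FALSE, ns, ns)
  for (m in seq_len(nm)) {
    G <- crossprod(U, matrix(d$dV[m, , ], ns, ns) %*% U)
    grad[m, ] <- diag(G)
    if (ns > 1L) {
      for (i in seq_len(ns - 1L)) {
        for (j in seq.int(i + 1L, ns)) {
          dEji <- E[j] - E[i]
          if (abs(dEji) < degeneracy_tol) {
            degen[i, j] <- degen[j, i] <- TRUE
            dEji <- sign(dEji + (dEji == 0)) * degeneracy_tol
          }
          dij <- G[i, j] / dEji
          nac[m, i, j] <- dij
          nac[m, j, i] <- -dij
        }
      }
    }
  }
  mu_d <- model$dipole(q)
  mu_a <- abs(crossprod(U, mu_d %*% U))
  structure(list(
    energies = E, energies_ev = hartree_to_ev(E),
    gradients = grad, nac = nac, dipoles = mu_a, U = U,
    degenerate = degen, V = V, q = q
  ), class = "adiabatic_point")
}

#' Scan the minimum-energy barrier on an adiabatic surface
#'
#' Scans one coordinate (others held at `q_ref`) on a chosen adiabatic
#' surface and reports the effective barrier: the maximum of the profile
#' between the Franck-Condon region (the scan origin) and the first local
#' minimum (or the profile minimum) on the crossing side, relative to the
#' origin energy.
#'
#' @param model an `electronic_model`.
#' @param state adiabatic state index (default: bright state).
#' @param coord coordinate index to scan (default 1).
#' @param q_ref reference geometry (default all zero).
#' @param range scan range in bohr, default `c(0, 1.2 * crossing)` for the
#'   pucker family, else `c(0, 3)`.
#' @param n number of scan points.
#' @return list with `barrier_ev`, `q_top`, and the scanned `profile`
#'   (data.frame `q`, `energy_ev`).
#' @export
surface_barrier <- function(model, state = model$bright, coord = 1,
                            q_ref = rep(0, model$n_modes), range = NULL, n = 801) {
  if (is.null(range)) {
    range <- if (!is.null(model$params$crossing_bohr)) {
      c(0, 0.98 * model$params$crossing_bohr)
    } else c(0, 3)
  }
  qs <- seq(range[1], range[2], length.out = n)
  e <- vapply(qs, function(x) {
    q <- q_ref; q[coord] <- x
    eval_adiabatic(model, q)$energies[state]
  }, numeric(1))
  e_ev <- hartree_to_ev(e)
  ## barrier: max between origin and the subsequent minimum of the profile
  i_min <- which.min(e_ev)
  seg <- if (i_min > 1) seq_len(i_min) else seq_along(e_ev)
  i_top <- seg[which.max(e_ev[seg])]
  list(barrier_ev = e_ev[i_top] - e_ev[1], q_top = qs[i_top],
       profile = data.frame(q = qs, energy_ev = e_ev))
}

## ---------------------------------------------------------------------------
## Config round trip (built-in families only)
## ---------------------------------------------------------------------------

#' Write / read a model definition as a YAML config
#'
#' Built-in model families (`tully_*`, `harmonic`, `pucker`) serialize their
#' defining parameters to a YAML document with the summary keys `states`,
#' `modes`, `masses_amu`, `barrier_eV`, `solvent_coupling`, `dipoles` plus a
#' `family`/`params` block sufficient to rebuild the model exactly.
#'
#' @param model a built-in `electronic_model`.
#' @param path file path.
#' @return `write_model_config` returns `path` invisibly; `read_model_config`
#'   returns the reconstructed `electronic_model`.
#' @export
write_model_config <- function(model, path) {
  if (identical(model$family, "custom")) {
    stop("only built-in model families can be serialized")
  }
  doc <- list(
    family = model$family,
    states = model$n_states,
    modes = model$n_modes,
    masses_amu = model$masses_amu,
    barrier_eV = if (!is.null(model$params$barrier_ev)) model$params$barrier_ev else 0,
    solvent_coupling = if (!is.null(model$params$solvent_coupling_ev)) {
      model$params$solvent_coupling_ev
    } else 0,
    dipoles = as.vector(model$dipole(rep(0, model$n_modes))),
    params = model$params[!vapply(model$params, is.function, logical(1))]
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- yaml::read_yaml(path)
  fam <- doc$family
  p <- doc$params
  if (startsWith(fam, "tully_")) {
    make_tully_model(p$model_id)
  } else if (fam == "harmonic") {
    make_harmonic_model(unlist(p$wavenumbers_cm), doc$masses_amu,
                        unlist(p$centers_bohr), p$e0_ev)
  } else if (fam == "pucker") {
    keep <- setdiff(names(p), "crossing_bohr")
    args <- p[keep]
    args$tuning_wavenumbers_cm <- unlist(args$tuning_wavenumbers_cm)
    args$tuning_masses_amu <- unlist(args$tuning_masses_amu)
    args$tuning_kappa_ev_bohr <- unlist(args$tuning_kappa_ev_bohr)
    do.call(make_pucker_model, args)
  } else {
    stop("unknown model family: ", fam)
  }
}
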