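## Pump-probe transient-absorption synthesis from trajectory ensembles:
## per-step stick spectra (stimulated emission, excited-state absorption,
## hot-ground-state absorption), Gaussian energy broadening, trajectory
## averaging, and instrument-response convolution along the delay axis.

#' Per-step stick spectra of one trajectory
#'
#' While the trajectory is in the bright state `a`: a stimulated-emission
#' stick at \eqn{E_a - E_0} with weight \eqn{-|\mu_{a0}|^2 (E_a - E_0)} and
#' excited-state-absorption sticks at \eqn{E_b - E_a} (states `b` above `a`)
#' with weight \eqn{+|\mu_{ab}|^2 (E_b - E_a)}. After the hop to the ground
#' state: a hot-ground-state absorption stick at \eqn{E_1 - E_0} with weight
#' \eqn{+|\mu_{10}|^2 (E_1 - E_0)}, damped by an exponential
#' vibrational-cooling factor with time constant `cooling_tau_fs`.
#' Signal strength is \eqn{|\mu|^2 \times} transition energy; the
#' cubic-frequency emission prefactor is deliberately omitted (recorded in
#' the map metadata).
#'
#' @param traj a `trajectory`.
#' @param cooling_tau_fs vibrational-cooling damping of the hot-ground-state
#'   absorption (fs; default 2000, a "few ps" scale).
#' @return data.frame with columns `t_fs`, `energy_ev`, `weight`, `channel`
#'   (`"SE"`, `"ESA"`, `"hotGS"`).
#' @export
trajectory_signals <- function(traj, cooling_tau_fs = 2000) {
  if (is.null(traj$dipoles)) stop("trajectory has no stored dipoles")
  ns <- traj$n_states
  bright <- traj$bright
  n_t <- traj$n_recorded
  Ee <- traj$energies_ev
  out_t <- numeric(0); out_e <- numeric(0); out_w <- numeric(0); out_c <- character(0)
  for (i in seq_len(n_t)) {
    act <- traj$active[i]
    mu <- traj$dipoles[i, , ]
    if (any(!is.finite(mu))) stop("missing dipoles at step ", i)
    if (!is.na(bright) && act == bright) {
      gap <- Ee[i, act] - Ee[i, 1]
      out_t <- c(out_t, traj$t_fs[i]); out_e <- c(out_e, gap)
      out_w <- c(out_w, -mu[act, 1]^2 * gap); out_c <- c(out_c, "SE")
      if (act < ns) {
        for (b in seq.int(act + 1L, ns)) {
          de <- Ee[i, b] - Ee[i, act]
          out_t <- c(out_t, traj$t_fs[i]); out_e <- c(out_e, de)
          out_w <- c(out_w, mu[act, b]^2 * de); out_c <- c(out_c, "ESA")
        }
      }
    } else if (act == 1L && !is.na(traj$t_gs_fs) && traj$t_fs[i] >= traj$t_gs_fs) {
      gap <- Ee[i, 2] - Ee[i, 1]
      damp <- exp(-(traj$t_fs[i] - traj$t_gs_fs) / cooling_tau_fs)
      out_t <- c(out_t, traj$t_fs[i]); out_e <- c(out_e, gap)
      out_w <- c(out_w, mu[1, 2]^2 * gap * damp); out_c <- c(out_c, "hotGS")
    }
  }
  data.frame(t_fs = out_t, energy_ev = out_e, weight = out_w, channel = out_c)
}

#' Construct a transient-absorption map object
#'
#' @param delays_fs strictly increasing delay grid (fs).
#' @param probe_ev strictly increasing probe photon energy grid (eV).
#' @param delta_a signed matrix (`length(delays_fs)` x `length(probe_ev)`);
#'   negative = stimulated emission / bleach, positive = photoinduced
#'   absorption.
#' @param components optional named list of per-channel matrices summing to
#'   `delta_a`.
#' @param metadata named list (broadening, IRF width, conventions).
#' @return an object of class `ta_map`.
#' @export
ta_map <- function(delays_fs, probe_ev, delta_a, components = NULL,
                   metadata = list()) {
  if (any(diff(delays_fs) <= 0) || any(diff(probe_ev) <= 0)) {
    stop("delay and probe grids must be strictly increasing")
  }
  stopifnot(nrow(delta_a) == length(delays_fs), ncol(delta_a) == length(probe_ev))
  if (!is.null(components)) {
    tot <- Reduce(`+`, components)
    if (max(abs(tot - delta_a)) > 1e-10) {
      stop("component sum does not reproduce the total map")
    }
  }
  structure(list(delays_fs = delays_fs, probe_ev = probe_ev,
                 delta_a = delta_a, components = components,
                 metadata = metadata), class = "ta_map")
}

#' @export
print.ta_map <- function(x, ...) {
  cat(sprintf("<ta_map: %d delays (%.0f..%.0f fs) x %d probe energies (%.2f..%.2f eV)>\n",
              length(x$delays_fs), min(x$delays_fs), max(x$delays_fs),
              length(x$probe_ev), min(x$probe_ev), max(x$probe_ev)))
  if (!is.null(x$components))
    cat("  channels:", paste(names(x$components), collapse = ", "), "\n")
  invisible(x)
}

## Gaussian IRF convolution along the delay axis; kernel renormalized at the
## edges so a time-constant map is left unchanged
.irf_convolve <- function(mat, delays, fwhm) {
  if (fwhm <= 0) return(mat)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  n <- length(delays)
  K <- outer(delays, delays, function(a, b) exp(-(a - b)^2 / (2 * sig^2)))
  K <- K / rowSums(K)
  K %*% mat
}

#' Synthesize a transient-absorption map from an ensemble
#'
#' Collects all trajectory stick spectra, broadens each stick with a Gaussian
#' of width `sigma_e_ev` in probe energy, averages over trajectories, and
#' convolves the result along the delay axis with a Gaussian instrument
#' response of the stated FWHM (default 30 fs). The per-channel decomposition
#' (SE / ESA / hotGS) is retained and sums exactly to the total.
#'
#' @param ensemble an `ensemble`.
#' @param sigma_e_ev Gaussian energy broadening (eV), > 0 (0 assigns sticks
#'   to the nearest grid point unbroadened).
#' @param irf_fwhm_fs instrument-response FWHM (fs), >= 0.
#' @param probe_ev probe energy grid (eV); default `seq(1.8, 5, 0.02)`.
#' @param delays_fs delay grid; default: the trajectory time grid thinned to
#'   <= 501 points.
#' @param cooling_tau_fs hot-ground-state cooling constant (fs).
#' @return a `ta_map`; metadata records the broadening, IRF, the convention
#'   `signal ~ |mu|^2 * energy` and a tally of sticks outside the probe
#'   window.
#' @export
ensemble_ta_map <- function(ensemble, sigma_e_ev = 0.15, irf_fwhm_fs = 30,
                            probe_ev = seq(1.8, 5, 0.02), delays_fs = NULL,
                            cooling_tau_fs = 2000) {
  if (sigma_e_ev < 0) stop("sigma_e_ev must be >= 0")
  if (irf_fwhm_fs < 0) stop("irf_fwhm_fs must be >= 0")
  trajs <- ensemble$trajectories
  t_grid <- trajs[[1]]$t_fs
  if (is.null(delays_fs)) {
    stride <- max(1L, ceiling((length(t_grid) - 1L) / 500L))
    delays_fs <- t_grid[seq(1, length(t_grid), by = stride)]
  }
  nd <- length(delays_fs); ne <- length(probe_ev)
  chan <- c("SE", "ESA", "hotGS")
  comps <- setNames(lapply(chan, function(.) matrix(0, nd, ne)), chan)
  dropped <- 0L
  e_lo <- probe_ev[1] - 4 * sigma_e_ev
  e_hi <- probe_ev[ne] + 4 * sigma_e_ev
  inv2s2 <- if (sigma_e_ev > 0) 1 / (2 * sigma_e_ev^2) else NA_real_

  for (tr in trajs) {
    sig <- trajectory_signals(tr, cooling_tau_fs = cooling_tau_fs)
    if (!nrow(sig)) next
    ## snap stick times to the delay grid
    di <- findInterval(sig$t_fs, delays_fs + c(diff(delays_fs) / 2, Inf)) + 1L
    keep_t <- sig$t_fs <= delays_fs[nd] + 1e-9
    for (r in which(keep_t)) {
      E <- sig$energy_ev[r]
      if (E < e_lo || E > e_hi) { dropped <- dropped + 1L; next }
      ch <- sig$channel[r]
      if (sigma_e_ev > 0) {
        comps[[ch]][di[r], ] <- comps[[ch]][di[r], ] +
          sig$weight[r] * exp(-(probe_ev - E)^2 * inv2s2)
      } else {
        j <- which.min(abs(probe_ev - E))
        comps[[ch]][di[r], j] <- comps[[ch]][di[r], j] + sig$weight[r]
      }
    }
  }
  n_traj <- length(trajs)
  comps <- lapply(comps, function(mm) .irf_convolve(mm / n_traj, delays_fs, irf_fwhm_fs))
  total <- Reduce(`+`, comps)
  ta_map(delays_fs, probe_ev, total, components = comps,
         metadata = list(sigma_e_ev = sigma_e_ev, irf_fwhm_fs = irf_fwhm_fs,
                         cooling_tau_fs = cooling_tau_fs,
                         weight_convention = "mu^2 * transition energy (no nu^3 prefactor)",
                         sticks_outside_window = dropped,
                         n_trajectories = n_traj))
}

#' Photoselection weight for a pump-probe polarization geometry
#'
#' Classical photoselection factor for isotropically oriented molecules:
#' with `beta` the angle between pump and probe transition dipoles, the
#' orientational average of \eqn{\cos^2\theta_{pump}\cos^2\theta_{probe}}
#' equals \eqn{(1 + 2\cos^2\beta)/15} for parallel and
#' \eqn{(2 - \cos^2\beta)/15} for orthogonal pump-probe polarizations; at
#' magic angle the weight is the isotropic 1/9 for every `beta`.
#'
#' @param angle_bright_probe angle `beta` (rad) between the pump-excited and
#'   probed transition dipoles.
#' @param geometry `"parallel"`, `"magic"`, or `"orthogonal"`.
#' @return scalar weight.
#' @examples
#' polarization_weights(0, "parallel") / polarization_weights(0, "orthogonal")  # 3
#' @export
polarization_weights <- function(angle_bright_probe,
                                 geometry = c("parallel", "magic", "orthogonal")) {
  geometry <- match.arg(geometry)
  c2 <- cos(angle_bright_probe)^2
  switch(geometry,
         parallel = (1 + 2 * c2) / 15,
         orthogonal = (2 - c2) / 15,
         magic = 1 / 9)
}
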