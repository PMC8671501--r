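## Excited-state minimum location, numerical normal-mode analysis on the
## adiabatic surfaces, and per-mode vibrational energy partitioning along
## trajectories.

#' Locate a minimum on an adiabatic surface
#'
#' Gradient-norm minimization on the chosen adiabatic surface starting from
#' `q0`, using BFGS with the analytic (Hellmann-Feynman) gradients.
#'
#' @param model an `electronic_model`.
#' @param state adiabatic state index.
#' @param q0 starting geometry (bohr).
#' @param grad_tol convergence threshold on the gradient norm
#'   (hartree/bohr), default 1e-7.
#' @param maxit iteration budget.
#' @return list with `q_min`, `energy_ev`, `grad_norm`, `converged`.
#' @export
locate_minimum <- function(model, state = model$bright, q0 = rep(0, model$n_modes),
                           grad_tol = 1e-7, maxit = 500) {
  if (any(!is.finite(q0))) stop("q0 must be finite")
  ## overdamped (driven) coordinates are held fixed: they are bath variables,
  ## not vibrational degrees of freedom
  free <- !model$overdamped
  expand <- function(qf) { q <- q0; q[free] <- qf; q }
  fn <- function(qf) eval_adiabatic(model, expand(qf))$energies[state]
  gr <- function(qf) eval_adiabatic(model, expand(qf))$gradients[free, state]
  o <- stats::optim(q0[free], fn, gr, method = "BFGS",
                    control = list(maxit = maxit, reltol = 1e-16))
  gnorm <- sqrt(sum(gr(o$par)^2))
  if (gnorm > grad_tol) {
    ## polish with a few explicit Newton-like steepest-descent steps
    q <- o$par
    for (it in seq_len(200)) {
      g <- gr(q)
      gnorm <- sqrt(sum(g^2))
      if (gnorm <= grad_tol) break
      q <- q - g * 0.5 / max(1, gnorm * 50)
    }
    if (gnorm > grad_tol) {
      stop(sprintf("minimization did not reach gradient tolerance (|g| = %.2e at q = %s)",
                   gnorm, paste(signif(q, 4), collapse = ", ")))
    }
    o$par <- q
  }
  list(q_min = expand(o$par), energy_ev = hartree_to_ev(fn(o$par)),
       grad_norm = gnorm, converged = TRUE)
}

#' Normal-mode analysis on an adiabatic surface
#'
#' Central-difference Hessian of the adiabatic energy at a stationary point
#' (built from analytic gradient differences), mass-weighted and
#' diagonalized. Frequencies are returned in cm^-1 with imaginary
#' frequencies reported as negative numbers.
#'
#' @param model an `electronic_model`.
#' @param state adiabatic state index.
#' @param q_min stationary geometry (bohr); the gradient norm is checked
#'   against `grad_tol` unless `force = TRUE`.
#' @param fd_step finite-difference displacement (bohr).
#' @param grad_tol gradient-norm tolerance for accepting `q_min`.
#' @param force skip the stationarity check.
#' @return an object of class `normal_modes`: `frequencies_cm` (ascending),
#'   `mode_vectors` (columns, orthonormal in mass-weighted coordinates),
#'   `q_ref`, `state`, `masses_amu`, `hessian_asym` (max |H - H^T| before
#'   symmetrization).
#' @export
normal_modes <- function(model, state, q_min, fd_step = 1e-3,
                         grad_tol = 1e-6, force = FALSE) {
  nm <- model$n_modes
  free <- which(!model$overdamped)
  g0 <- eval_adiabatic(model, q_min)$gradients[free, state]
  if (!force && sqrt(sum(g0^2)) > grad_tol) {
    stop("q_min is not a stationary point (|g| = ", signif(sqrt(sum(g0^2)), 3),
         "); refusing normal-mode analysis off-minimum (use force = TRUE)")
  }
  nf <- length(free)
  H <- matrix(0, nf, nf)
  for (jj in seq_len(nf)) {
    j <- free[jj]
    qp <- q_min; qp[j] <- qp[j] + fd_step
    qm <- q_min; qm[j] <- qm[j] - fd_step
    gp <- eval_adiabatic(model, qp)$gradients[free, state]
    gm <- eval_adiabatic(model, qm)$gradients[free, state]
    H[, jj] <- (gp - gm) / (2 * fd_step)
  }
  asym <- max(abs(H - t(H)))
  H <- 0.5 * (H + t(H))
  sm <- sqrt(model$masses_me[free])
  Hmw <- H / outer(sm, sm)
  eg <- eigen(Hmw, symmetric = TRUE)
  lam <- eg$values
  freq <- ifelse(lam >= 0, sqrt(lam), -sqrt(-lam)) * hopta_constants$cm_per_hartree
  ord <- order(freq)
  ## overdamped (driven) coordinates appear as zero-frequency unit modes
  vec <- matrix(0, nm, nm)
  vec[free, seq_len(nf)] <- eg$vectors[, ord, drop = FALSE]
  freqs <- c(freq[ord], rep(0, nm - nf))
  over <- which(model$overdamped)
  for (k in seq_along(over)) vec[over[k], nf + k] <- 1
  ford <- order(freqs)
  structure(list(frequencies_cm = freqs[ford],
                 mode_vectors = vec[, ford, drop = FALSE],
                 q_ref = q_min, state = state,
                 masses_amu = model$masses_amu,
                 fd_step = fd_step, hessian_asym = asym),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes: state %d, %d modes>\n  frequencies (cm^-1): %s\n",
              x$state, length(x$frequencies_cm),
              paste(sprintf("%.1f", x$frequencies_cm), collapse = ", ")))
  invisible(x)
}

#' Export a normal-mode set as tables
#'
#' Writes a frequency table (mode index, wavenumber) and the matrix of
#' mass-weighted mode vectors as tab-separated text.
#'
#' @param modes a `normal_modes` object.
#' @param path_freq,path_vectors output files.
#' @return invisibly, the two paths.
#' @export
write_normal_modes <- function(modes, path_freq, path_vectors) {
  utils::write.table(
    data.frame(mode = seq_along(modes$frequencies_cm),
               wavenumber_cm = modes$frequencies_cm),
    path_freq, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(modes$mode_vectors, path_vectors, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(path_freq, path_vectors))
}

#' Per-mode vibrational energy along a trajectory
#'
#' Projects each frame onto the (mass-weighted) normal-mode vectors relative
#' to the reference geometry and returns the harmonic mode energies
#' \eqn{E_i(t) = \tfrac12 P_i^2 + \tfrac12 \omega_i^2 Q_i^2} (reported in
#' eV).
#'
#' @param traj a `trajectory`.
#' @param modes a `normal_modes` object on a matching model.
#' @return data.frame with `t_fs` and one `mode<i>_ev` column per mode, plus
#'   `total_ev`.
#' @export
mode_energy_partition <- function(traj, modes) {
  nm <- length(modes$frequencies_cm)
  if (ncol(traj$q) != nm) stop("dimension mismatch between trajectory and modes")
  sm <- sqrt(amu_to_me(modes$masses_amu))
  w <- modes$frequencies_cm / hopta_constants$cm_per_hartree
  n_t <- traj$n_recorded
  dq <- sweep(traj$q[seq_len(n_t), , drop = FALSE], 2, modes$q_ref)
  Qmw <- sweep(dq, 2, sm, `*`) %*% modes$mode_vectors
  Pmw <- sweep(traj$p[seq_len(n_t), , drop = FALSE], 2, sm, `/`) %*% modes$mode_vectors
  Ei <- 0.5 * Pmw^2 + 0.5 * sweep(Qmw^2, 2, w^2, `*`)
  out <- data.frame(t_fs = traj$t_fs[seq_len(n_t)], hartree_to_ev(Ei))
  names(out)[-1] <- paste0("mode", seq_len(nm), "_ev")
  out$total_ev <- rowSums(out[, -1, drop = FALSE])
  out
}
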