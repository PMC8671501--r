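## Ground-state Wigner sampling of initial conditions and the pump-window
## excitation filter.

#' Sample the ground-state Wigner distribution
#'
#' Draws phase-space samples from the T = 0 Wigner function of uncoupled
#' harmonic modes: per mode, `q` and `p` are independent Gaussians with
#' \eqn{\mathrm{Var}(q) = \hbar / (2 m \omega)} and
#' \eqn{\mathrm{Var}(p) = \hbar m \omega / 2} (atomic units: bohr and a.u.
#' momentum). Reproducible for a given seed.
#'
#' @param frequencies_cm per-mode wavenumbers (cm^-1), all positive.
#' @param masses_amu per-mode masses (amu).
#' @param n number of samples (>= 1).
#' @param seed integer RNG seed.
#' @return an object of class `phase_space_samples`: list with matrices `q`,
#'   `p` (`n` x `n_modes`), `weights` (all 1), and the sampling metadata
#'   (`frequencies_cm`, `masses_amu`, `seed`).
#' @examples
#' s <- wigner_sample(c(600, 750), c(6, 6), n = 100, seed = 1)
#' apply(s$q, 2, var)  # ~ hbar / (2 m omega)
#' @export
wigner_sample <- function(frequencies_cm, masses_amu, n, seed) {
  if (any(!is.finite(frequencies_cm)) || any(frequencies_cm <= 0)) {
    stop("frequencies must be positive (no free-rotor handling)")
  }
  if (length(masses_amu) != length(frequencies_cm)) {
    stop("frequencies and masses must have equal length")
  }
  if (n < 1) stop("n must be >= 1")
  nm <- length(frequencies_cm)
  w <- cm_to_au_freq(frequencies_cm)
  m <- amu_to_me(masses_amu)
  sq <- sqrt(1 / (2 * m * w))
  sp <- sqrt(m * w / 2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  q <- matrix(stats::rnorm(n * nm), n, nm) * rep(sq, each = n)
  p <- matrix(stats::rnorm(n * nm), n, nm) * rep(sp, each = n)
  structure(list(
    q = q, p = p, weights = rep(1, n),
    frequencies_cm = frequencies_cm, masses_amu = masses_amu,
    seed = as.integer(seed), vertical_gaps_ev = NULL
  ), class = "phase_space_samples")
}

#' Sample initial conditions for a model
#'
#' Convenience wrapper: Wigner-samples the modes of a model that carry
#' ground-state wavenumbers (`sample_wavenumbers_cm`); unsampled modes
#' (e.g. the overdamped solvent coordinate) are set to zero position and
#' momentum.
#'
#' @param model an `electronic_model`.
#' @param n,seed passed to [wigner_sample()].
#' @return a `phase_space_samples` object with `n_modes` columns.
#' @export
sample_model <- function(model, n, seed) {
  idx <- which(!is.na(model$sample_wavenumbers_cm))
  if (!length(idx)) stop("model has no sampleable modes")
  s <- wigner_sample(model$sample_wavenumbers_cm[idx], model$masses_amu[idx],
                     n, seed)
  q <- matrix(0, n, model$n_modes)
  p <- matrix(0, n, model$n_modes)
  q[, idx] <- s$q
  p[, idx] <- s$p
  s$q <- q
  s$p <- p
  s$masses_amu <- model$masses_amu
  s
}

#' Filter samples by a vertical-excitation energy window
#'
#' Keeps the samples whose bright-state vertical gap (bright minus ground
#' adiabatic energy at the sampled geometry) falls inside `window`,
#' emulating selective excitation by a finite-bandwidth pump pulse.
#'
#' @param samples a `phase_space_samples` object.
#' @param model an `electronic_model` with a defined bright state.
#' @param window numeric `c(E_lo, E_hi)` in eV, `E_lo < E_hi`.
#' @return the filtered `phase_space_samples`; the computed gaps are stored in
#'   `$vertical_gaps_ev` and the acceptance ratio in `$acceptance_ratio`.
#'   An empty selection produces a warning, not an error.
#' @export
excitation_window <- function(samples, model, window) {
  if (length(window) != 2 || !(window[1] < window[2])) {
    stop("window must be c(E_lo, E_hi) with E_lo < E_hi")
  }
  if (is.na(model$bright)) stop("model has no bright state defined")
  n <- nrow(samples$q)
  gaps <- vapply(seq_len(n), function(i) {
    pt <- eval_adiabatic(model, samples$q[i, ])
    pt$energies_ev[model$bright] - pt$energies_ev[1]
  }, numeric(1))
  keep <- gaps >= window[1] & gaps <= window[2]
  if (!any(keep)) warning("excitation window rejected every sample")
  out <- samples
  out$q <- samples$q[keep, , drop = FALSE]
  out$p <- samples$p[keep, , drop = FALSE]
  out$weights <- samples$weights[keep]
  out$vertical_gaps_ev <- gaps[keep]
  out$acceptance_ratio <- mean(keep)
  out$window_ev <- window
  out
}

#' Thin a sample set to a fixed size
#'
#' Uniform thinning (every k-th accepted sample) down to `n_keep` samples,
#' the strategy used to select the propagated subset out of a larger
#' Wigner-sampled pool.
#'
#' @param samples a `phase_space_samples` object.
#' @param n_keep target count.
#' @return the thinned `phase_space_samples`.
#' @export
thin_samples <- function(samples, n_keep) {
  n <- nrow(samples$q)
  if (n_keep > n) stop("n_keep exceeds available samples")
  idx <- unique(round(seq(1, n, length.out = n_keep)))
  out <- samples
  out$q <- samples$q[idx, , drop = FALSE]
  out$p <- samples$p[idx, , drop = FALSE]
  out$weights <- samples$weights[idx]
  if (!is.null(out$vertical_gaps_ev)) out$vertical_gaps_ev <- samples$vertical_gaps_ev[idx]
  out
}

#' Write / read phase-space samples as a tabular file
#'
#' One row per sample: mode coordinates (bohr), momenta (a.u.) and, when
#' available, the bright-state vertical gap (eV). The seed is recorded in a
#' header comment.
#'
#' @param samples a `phase_space_samples` object.
#' @param path file path (tab-separated text).
#' @return `write_samples` returns `path` invisibly; `read_samples` returns a
#'   `phase_space_samples` object.
#' @export
write_samples <- function(samples, path) {
  nm <- ncol(samples$q)
  df <- data.frame(samples$q, samples$p)
  names(df) <- c(paste0("q", seq_len(nm)), paste0("p", seq_len(nm)))
  if (!is.null(samples$vertical_gaps_ev)) df$gap_eV <- samples$vertical_gaps_ev
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", samples$seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  first <- readLines(path, n = 1)
  seed <- if (grepl("^# seed:", first)) as.integer(sub("^# seed:\\s*", "", first)) else NA_integer_
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  qcols <- grep("^q[0-9]+$", names(df))
  pcols <- grep("^p[0-9]+$", names(df))
  structure(list(
    q = as.matrix(df[, qcols, drop = FALSE]),
    p = as.matrix(df[, pcols, drop = FALSE]),
    weights = rep(1, nrow(df)),
    frequencies_cm = NULL, masses_amu = NULL, seed = seed,
    vertical_gaps_ev = if ("gap_eV" %in% names(df)) df$gap_eV else NULL
  ), class = "phase_space_samples")
}
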