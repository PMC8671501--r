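## Decay-channel classification of ground-state-hop events, channel yields
## with binomial confidence intervals, survival fractions, and the
## ensemble-resolved effective barrier along a reaction coordinate.

#' Classify the decay channel of one trajectory
#'
#' Labels a trajectory by the geometry at its ground-state hop: each decay
#' channel defined in the model's `channel_coords` (e.g. `puckering`,
#' `ring_opening`, `O_oop`) trips when the absolute displacement of its
#' coordinate exceeds the channel threshold. When several thresholds trip,
#' the largest normalized displacement (|q| / threshold) wins; ties break in
#' the fixed order puckering > ring_opening > O_oop. Trajectories that never
#' reach the ground state are labelled `undecayed`; tripping no threshold
#' gives `other`.
#'
#' @param traj a `trajectory`.
#' @param model the `electronic_model` it was propagated on (supplies
#'   `channel_coords`).
#' @param thresholds optional named vector overriding the per-channel
#'   thresholds (bohr).
#' @return the label (character scalar) with attribute `normalized`
#'   (displacement / threshold per channel).
#' @export
classify_hop <- function(traj, model, thresholds = NULL) {
  if (is.na(traj$t_gs_fs)) return("undecayed")
  cc <- model$channel_coords
  if (!length(cc)) stop("model defines no channel coordinates")
  precedence <- c("puckering", "ring_opening", "O_oop")
  nms <- names(cc)
  th <- vapply(cc, function(x) x$threshold, numeric(1))
  if (!is.null(thresholds)) {
    miss <- setdiff(names(thresholds), nms)
    if (length(miss)) stop("unknown channel in thresholds: ", paste(miss, collapse = ", "))
    th[names(thresholds)] <- thresholds
  }
  i_hop <- which.min(abs(traj$t_fs - traj$t_gs_fs))
  q <- traj$q[i_hop, ]
  disp <- vapply(seq_along(cc), function(k) {
    mode <- cc[[k]]$mode
    if (mode > length(q)) stop("missing coordinate for channel ", nms[k])
    abs(q[mode])
  }, numeric(1))
  normed <- disp / th
  names(normed) <- nms
  tripped <- which(normed >= 1)
  label <- if (!length(tripped)) "other" else {
    cand <- tripped[normed[tripped] == max(normed[tripped])]
    if (length(cand) > 1) {
      ord <- order(match(nms[cand], precedence))
      cand <- cand[ord]
    }
    nms[cand[1]]
  }
  attr(label, "normalized") <- normed
  label
}

## Wilson score interval for a binomial proportion
.wilson <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Decay-channel yields of an ensemble
#'
#' Classifies every trajectory and reports per-channel counts, fractions
#' over the decayed trajectories, and 95% Wilson confidence intervals.
#'
#' @param ensemble an `ensemble`.
#' @param thresholds optional named threshold overrides (see
#'   [classify_hop()]).
#' @return an object of class `channel_report`: data.frame `channels`
#'   (channel, count, fraction, ci_lo, ci_hi), `labels` (per trajectory),
#'   `n_decayed`, `n_total`, `thresholds`.
#' @export
channel_yields <- function(ensemble, thresholds = NULL) {
  labels <- vapply(ensemble$trajectories, classify_hop, character(1),
                   model = ensemble$model, thresholds = thresholds)
  decayed <- labels != "undecayed"
  nd <- sum(decayed)
  chan <- c(names(ensemble$model$channel_coords), "other")
  counts <- vapply(chan, function(ch) sum(labels == ch), integer(1))
  frac <- if (nd > 0) counts / nd else rep(NA_real_, length(chan))
  ci <- t(vapply(counts, .wilson, numeric(2), n = nd))
  th <- vapply(ensemble$model$channel_coords, function(x) x$threshold, numeric(1))
  if (!is.null(thresholds)) th[names(thresholds)] <- thresholds
  structure(list(
    channels = data.frame(channel = chan, count = counts, fraction = frac,
                          ci_lo = ci[, 1], ci_hi = ci[, 2], row.names = NULL),
    labels = labels, n_decayed = nd,
    n_total = length(labels), thresholds = th,
    fractions_defined = nd > 0
  ), class = "channel_report")
}

#' @export
print.channel_report <- function(x, ...) {
  cat(sprintf("<channel_report: %d / %d trajectories decayed>\n",
              x$n_decayed, x$n_total))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' Excited-state survival fraction at a time
#'
#' Fraction of trajectories not yet in the ground state at delay `t_fs`,
#' with a 95% Wilson interval.
#'
#' @param ensemble an `ensemble`.
#' @param t_fs query time; must lie within the trajectory span unless
#'   `extrapolate = TRUE` (then trajectories are assumed to stay in their
#'   final state).
#' @param extrapolate allow `t_fs` beyond the simulated span.
#' @return list with `fraction`, `ci`, `n`.
#' @export
survival_fraction <- function(ensemble, t_fs, extrapolate = FALSE) {
  tmax <- min(vapply(ensemble$trajectories, function(tr) max(tr$t_fs), numeric(1)))
  if (t_fs > tmax && !extrapolate) {
    stop("t beyond the shortest trajectory (", tmax, " fs); set extrapolate = TRUE")
  }
  alive <- vapply(ensemble$trajectories, function(tr) {
    i <- which.min(abs(tr$t_fs - min(t_fs, max(tr$t_fs))))
    tr$active[i] != 1L
  }, logical(1))
  n <- length(alive)
  list(fraction = mean(alive), ci = .wilson(sum(alive), n), n = n)
}

#' Ensemble-resolved effective barrier along a coordinate
#'
#' For each time window, bins all visited geometries along the chosen
#' coordinate and records the minimum bright-state energy per bin (the
#' ensemble-sampled potential profile). The effective barrier of a window
#' is the maximum of that profile between the Franck-Condon region (the bin
#' containing the origin) and the profile minimum on the crossing side,
#' relative to the Franck-Condon value. With a relaxing solvent gate the
#' barrier decreases over successive windows.
#'
#' @param ensemble an `ensemble`.
#' @param coordinate mode index of the reaction coordinate (default: the
#'   puckering channel's mode).
#' @param n_bins number of coordinate bins.
#' @param time_windows list of `c(t_lo, t_hi)` fs windows (>= 2).
#' @param state adiabatic state whose energy is profiled (default: bright).
#' @param spectator_rest if `TRUE` (default), each visited geometry is
#'   re-evaluated with all coordinates other than the reaction coordinate and
#'   the driven (overdamped) ones set to rest. This projects out the large
#'   diagonal energy carried by the spectator (tuning) modes, which would
#'   otherwise swamp a ~0.1 eV barrier; with `FALSE` the stored frame
#'   energies are used as-is.
#' @param frame_stride use every `frame_stride`-th stored frame.
#' @param coord_max frames beyond this coordinate value are excluded from the
#'   profile (default: just inside the crossing for models that know their
#'   crossing position). Keeps the pre-crossing barrier region from being
#'   polluted by post-conversion geometries on the far side of the funnel.
#' @return an object of class `barrier_map`: data.frame `windows`
#'   (`t_lo, t_hi, barrier_ev, q_top, interpolated`), plus the per-window
#'   binned profiles.
#' @export
ensemble_barrier_map <- function(ensemble, coordinate = NULL, n_bins = 24,
                                 time_windows, state = NULL,
                                 spectator_rest = TRUE, frame_stride = 4L,
                                 coord_max = NULL) {
  if (length(ensemble$trajectories) == 0) stop("empty ensemble")
  if (length(time_windows) < 2) stop("need at least two time windows")
  model <- ensemble$model
  if (is.null(coordinate)) {
    coordinate <- if (length(model$channel_coords)) {
      model$channel_coords[[1]]$mode
    } else 1L
  }
  if (is.null(state)) state <- model$bright
  if (is.null(coord_max)) {
    coord_max <- if (!is.null(model$params$crossing_bohr)) {
      0.98 * model$params$crossing_bohr
    } else Inf
  }
  trajs <- ensemble$trajectories
  keep_free <- c(coordinate, which(model$overdamped))
  profiles <- list()
  rows <- list()
  for (wi in seq_along(time_windows)) {
    tw <- time_windows[[wi]]
    qc <- numeric(0); ee <- numeric(0)
    for (tr in trajs) {
      sel <- which(tr$t_fs >= tw[1] & tr$t_fs <= tw[2] &
                     seq_along(tr$t_fs) <= tr$n_recorded &
                     abs(tr$q[, coordinate]) <= coord_max)
      sel <- sel[seq(1, length(sel), by = frame_stride)]
      if (!length(sel)) next
      qc <- c(qc, abs(tr$q[sel, coordinate]))
      if (spectator_rest) {
        ee <- c(ee, vapply(sel, function(i) {
          q <- rep(0, model$n_modes)
          q[keep_free] <- tr$q[i, keep_free]
          eval_adiabatic(model, q)$energies_ev[state]
        }, numeric(1)))
      } else {
        ee <- c(ee, tr$energies_ev[sel, state])
      }
    }
    if (!length(qc)) stop("window ", wi, " contains no frames")
    brk <- seq(0, max(qc) * (1 + 1e-9), length.out = n_bins + 1)
    bin <- findInterval(qc, brk, rightmost.closed = TRUE)
    prof <- rep(NA_real_, n_bins)
    for (b in unique(bin)) prof[b] <- min(ee[bin == b])
    interpolated <- any(is.na(prof[seq_len(max(bin))]))
    if (interpolated) {
      idx <- which(!is.na(prof))
      prof <- stats::approx(idx, prof[idx], xout = seq_len(n_bins), rule = 2)$y
    }
    ctr <- (brk[-1] + brk[-(n_bins + 1)]) / 2
    ## effective barrier: highest point of the visited profile relative to
    ## the Franck-Condon bin; a lower bound when the ensemble has not yet
    ## sampled beyond the turning point
    i_top <- which.max(prof)
    rows[[wi]] <- data.frame(t_lo = tw[1], t_hi = tw[2],
                             barrier_ev = prof[i_top] - prof[1],
                             q_top = ctr[i_top], interpolated = interpolated)
    profiles[[wi]] <- data.frame(q = ctr, energy_ev = prof)
  }
  structure(list(windows = do.call(rbind, rows), profiles = profiles,
                 coordinate = coordinate, state = state),
            class = "barrier_map")
}

#' @export
print.barrier_map <- function(x, ...) {
  cat("<barrier_map>\n")
  print(x$windows, row.names = FALSE)
  invisible(x)
}
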