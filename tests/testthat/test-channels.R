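# Decay-channel classification, yields, survival, ensemble barrier mapping

# fabricated decayed trajectory with a chosen hop geometry (4 modes)
decayed_traj <- function(q_hop, t_gs = 100) {
  n <- 11
  tr <- fake_trajectory(seq(0, 200, 20), rep(4, n), q = matrix(0, n, 4),
                        t_gs_fs = t_gs)
  tr$active <- c(rep(2L, 5), rep(1L, 6))
  i_hop <- which.min(abs(tr$t_fs - t_gs))
  tr$q[i_hop, ] <- q_hop
  tr$p <- matrix(0, n, 4)
  tr$masses_me <- rep(1822.888, 4)
  tr
}

test_that("hop geometries classify by the dominant tripped coordinate", {
  m <- pucker_light_model()
  thr_p <- m$channel_coords$puckering$threshold
  expect_identical(as.character(classify_hop(decayed_traj(c(2 * thr_p, 0, 0, 0)), m)),
                   "puckering")
  expect_identical(as.character(classify_hop(decayed_traj(c(0, 1.5, 0, 0)), m)),
                   "ring_opening")
  expect_identical(as.character(classify_hop(decayed_traj(c(0, 0, 1.5, 0)), m)),
                   "O_oop")
  # largest normalized displacement wins
  lab <- classify_hop(decayed_traj(c(1.2 * thr_p, 3, 0, 0)), m)
  expect_identical(as.character(lab), "ring_opening")
  # nothing tripped
  expect_identical(as.character(classify_hop(decayed_traj(c(0, 0, 0, 0)), m)),
                   "other")
  # undecayed trajectory
  undec <- fake_trajectory(0:5, rep(4, 6), q = matrix(0, 6, 4))
  expect_identical(as.character(classify_hop(undec, m)), "undecayed")
})

test_that("labels equal an independent re-classification from raw geometries", {
  ens <- pucker_light_ensemble()
  rep_ <- channel_yields(ens)
  m <- ens$model
  th <- vapply(m$channel_coords, function(x) x$threshold, numeric(1))
  manual <- vapply(ens$trajectories, function(tr) {
    if (is.na(tr$t_gs_fs)) return("undecayed")
    q <- tr$q[which.min(abs(tr$t_fs - tr$t_gs_fs)), ]
    normed <- abs(q[vapply(m$channel_coords, `[[`, integer(1), "mode")]) / th
    if (all(normed < 1)) "other" else names(m$channel_coords)[which.max(normed)]
  }, character(1))
  expect_identical(unname(rep_$labels), unname(manual))
})

test_that("channel fractions account for every trajectory exactly once", {
  ens <- pucker_light_ensemble()
  rep_ <- channel_yields(ens)
  expect_identical(sum(rep_$channels$count) +
                     sum(rep_$labels == "undecayed"), length(ens$trajectories))
  if (rep_$n_decayed > 0) {
    expect_equal(sum(rep_$channels$fraction), 1, tolerance = 1e-12)
  }
})

test_that("a 90/10 generative mix is recovered within the Wilson interval", {
  m <- pucker_light_model()
  thr_p <- m$channel_coords$puckering$threshold
  set.seed(314)
  trajs <- lapply(1:200, function(i) {
    if (runif(1) < 0.9) decayed_traj(c(thr_p * runif(1, 1.2, 2), 0, 0, 0))
    else decayed_traj(c(0, runif(1, 1.2, 2), 0, 0))
  })
  rep_ <- channel_yields(fake_ensemble(trajs, m))
  row <- rep_$channels[rep_$channels$channel == "puckering", ]
  expect_true(row$ci_lo <= 0.9 && 0.9 <= row$ci_hi)
  expect_identical(rep_$n_decayed, 200L)
})

test_that("a single rare channel out of 57 reports the 1/57 convention", {
  m <- pucker_light_model()
  thr_p <- m$channel_coords$puckering$threshold
  trajs <- c(lapply(1:56, function(i) decayed_traj(c(1.5 * thr_p, 0, 0, 0))),
             list(decayed_traj(c(0, 1.5, 0, 0))))
  rep_ <- channel_yields(fake_ensemble(trajs, m))
  ro <- rep_$channels[rep_$channels$channel == "ring_opening", ]
  expect_identical(ro$count, 1L)
  expect_equal(ro$fraction, 1 / 57, tolerance = 1e-12)
  expect_true(ro$ci_lo < 1 / 57 && ro$ci_hi > 1 / 57)
})

test_that("an ensemble with no decayed trajectory flags undefined fractions", {
  m <- pucker_light_model()
  trajs <- lapply(1:5, function(i) fake_trajectory(0:5, rep(4, 6), q = matrix(0, 6, 4)))
  rep_ <- channel_yields(fake_ensemble(trajs, m))
  expect_false(rep_$fractions_defined)
  expect_true(all(is.na(rep_$channels$fraction)))
})

test_that("survival fractions match the exponential closed form and recount", {
  ens <- pucker_light_ensemble()
  expect_equal(survival_fraction(ens, 0)$fraction, 1)
  # recount oracle against the stored populations
  sv <- survival_fraction(ens, 200)
  pop <- ens$populations
  expect_equal(sv$fraction, 1 - pop$P_S0[which.min(abs(pop$time_fs - 200))])
  expect_error(survival_fraction(ens, 1e6), "extrapolate")
  expect_equal(survival_fraction(ens, 1e6, extrapolate = TRUE)$fraction,
               1 - pop$P_S0[nrow(pop)])

  # large fabricated mono-exponential ensemble, tau = 750 fs
  m <- pucker_light_model()
  set.seed(7)
  hops <- rexp(2000, 1 / 750)
  t_grid <- seq(0, 1100, 10)
  trajs <- lapply(hops, function(h) {
    act <- ifelse(t_grid < h, 2L, 1L)
    tr <- fake_trajectory(t_grid, rep(4, length(t_grid)),
                          active = act, q = matrix(0, length(t_grid), 4),
                          t_gs_fs = if (h <= 1100) t_grid[which(t_grid >= h)[1]] else NA_real_)
    tr
  })
  ens2 <- fake_ensemble(trajs, m)
  sv2 <- survival_fraction(ens2, 1000)
  expect_equal(sv2$fraction, exp(-1000 / 750), tolerance = 0.12)
  expect_lt(abs(sv2$fraction - exp(-1000 / 750)), 3 * sqrt(0.26 * 0.74 / 2000) + 0.01)
})

test_that("the ensemble barrier estimator recovers an analytic barrier", {
  m <- make_pucker_model(barrier_ev = 0.15, include_dark = FALSE)
  # fabricated dense sweep of the puckering coordinate on the static surface
  qs <- seq(0, 0.97 * m$params$crossing_bohr, length.out = 400)
  E2 <- vapply(qs, function(x) eval_adiabatic(m, c(x, 0, 0, 0))$energies_ev[2],
               numeric(1))
  n <- length(qs)
  tr <- fake_trajectory(seq(0, n - 1), rep(4, n), q = cbind(qs, 0, 0, 0))
  tr$energies_ev[, 2] <- E2
  tr$energies_ev[, 1] <- 0
  bm <- ensemble_barrier_map(fake_ensemble(list(tr, tr), m), coordinate = 1,
                             n_bins = 40,
                             time_windows = list(c(0, n), c(0, n)))
  expect_equal(bm$windows$barrier_ev[1], 0.15, tolerance = 0.02 / 0.15)
  expect_error(ensemble_barrier_map(fake_ensemble(list(), m),
                                    time_windows = list(c(0, 1), c(1, 2))))
})
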