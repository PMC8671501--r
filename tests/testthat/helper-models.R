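# Shared fixtures: small analytic models built in code, and a lazy cache for
# the ensembles several test files reuse (computed once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# static two-level model: constant diabatic gap and coupling (hartree)
static_two_level <- function(gap_h, coupling_h = 0, mu = 1) {
  electronic_model(
    n_states = 2, n_modes = 1, masses_amu = 1,
    diabatic = function(q) list(
      V = matrix(c(0, coupling_h, coupling_h, gap_h), 2, 2),
      dV = array(0, c(1, 2, 2))),
    dipole = matrix(c(0, mu, mu, 0), 2, 2),
    labels = c("S0", "S1"), bright = 2L,
    family = "custom")
}

# fabricate adiabatic_point objects for direct tdse_step tests
fake_point <- function(energies_h, sigma = 0) {
  ns <- length(energies_h)
  nac <- array(0, c(1, ns, ns))
  if (ns >= 2) { nac[1, 1, 2] <- sigma; nac[1, 2, 1] <- -sigma }
  structure(list(energies = energies_h, nac = nac,
                 U = diag(ns)), class = "adiabatic_point")
}

# light (hydrogen-out-of-plane-like) and heavy (methyl-like, solvent-gated)
# nucleoside-mimetic models under the preset study conditions
pucker_light_model <- function() make_pucker_model(include_dark = FALSE)
pucker_heavy_model <- function() {
  make_pucker_model(mass_pucker_amu = 15, solvent_coupling_ev = 0.10,
                    solvent_tau_fs = 150, solvent_shift_ev = 0.15,
                    include_dark = FALSE)
}

# small light-model ensemble reused by spectroscopy / channel / mode tests
pucker_light_ensemble <- function() cached("light_ens", {
  m <- pucker_light_model()
  s <- sample_model(m, 60, seed = 42)
  s <- excitation_window(s, m, c(4.43, 4.60))
  s <- thin_samples(s, min(24, nrow(s$q)))
  run_ensemble(m, s, t_max_fs = 400, dt_fs = 0.25, base_seed = 1100,
               irreversible_gs = TRUE)
})

pucker_light_map <- function() cached("light_map", {
  ensemble_ta_map(pucker_light_ensemble(), probe_ev = seq(1.8, 5, 0.025))
})

# fabricate a minimal trajectory object for spectroscopy / channel tests
fake_trajectory <- function(t_fs, gaps_ev, active = NULL, mu = 1,
                            t_gs_fs = NA_real_, n_states = 2,
                            esa_gap_ev = NULL, q = NULL) {
  n <- length(t_fs)
  if (is.null(active)) active <- rep(2L, n)
  E <- matrix(0, n, n_states)
  E[, 2] <- gaps_ev
  if (n_states >= 3 && !is.null(esa_gap_ev)) E[, 3] <- gaps_ev + esa_gap_ev
  dip <- array(mu, c(n, n_states, n_states))
  for (i in seq_len(n)) diag(dip[i, , ]) <- 0
  if (is.null(q)) q <- matrix(0, n, 1)
  structure(list(
    t_fs = t_fs, q = q, p = matrix(0, n, ncol(q)),
    active = as.integer(active),
    amps = matrix(0 + 0i, n, n_states),
    energies = E / 27.211386, energies_ev = E,
    dipoles = dip, events = data.frame(),
    seed = 0L, dt_fs = diff(t_fs)[1], model_family = "fake",
    bright = 2L, n_states = as.integer(n_states),
    masses_me = rep(1822.888, ncol(q)),
    valid = TRUE, max_drift_h = 0, t_gs_fs = t_gs_fs, n_recorded = n
  ), class = "trajectory")
}

fake_ensemble <- function(trajs, model) {
  ens <- structure(list(trajectories = trajs, model = model,
                        base_seed = 0L, failures = character(0),
                        n_invalid = 0L), class = "ensemble")
  ens$populations <- ensemble_populations(ens)
  ens
}
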