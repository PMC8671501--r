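# Excited-state minima, normal-mode analysis, mode-energy partitioning

test_that("minimum location recovers harmonic centres", {
  m0 <- make_harmonic_model(c(400, 700), masses_amu = c(1, 6))
  set.seed(6)
  r <- locate_minimum(m0, state = 1, q0 = rnorm(2, sd = 0.5))
  expect_lt(max(abs(r$q_min)), 1e-8)
  ms <- make_harmonic_model(500, masses_amu = 2, centers_bohr = 0.3)
  r2 <- locate_minimum(ms, 1, q0 = -0.4)
  expect_equal(r2$q_min, 0.3, tolerance = 1e-7)
})

test_that("normal modes round-trip the constructed frequencies", {
  m1 <- make_harmonic_model(600, masses_amu = 3)
  nm1 <- normal_modes(m1, 1, q_min = 0)
  expect_equal(nm1$frequencies_cm, 600, tolerance = 1 / 600)

  m2 <- make_harmonic_model(c(600, 750), masses_amu = c(3, 5))
  nm2 <- normal_modes(m2, 1, q_min = c(0, 0))
  expect_equal(nm2$frequencies_cm, c(600, 750), tolerance = 1 / 600)
  # decoupled modes: axis-aligned eigenvectors
  expect_equal(abs(nm2$mode_vectors), diag(2), tolerance = 1e-8)
  expect_lt(nm2$hessian_asym, 1e-8)
  # orthonormal mode vectors
  expect_equal(crossprod(nm2$mode_vectors), diag(2), tolerance = 1e-8)
})

test_that("frequencies are invariant under halving the finite-difference step", {
  m <- make_harmonic_model(c(600, 750), masses_amu = c(3, 5))
  a <- normal_modes(m, 1, c(0, 0), fd_step = 2e-3)
  b <- normal_modes(m, 1, c(0, 0), fd_step = 1e-3)
  expect_lt(max(abs(a$frequencies_cm - b$frequencies_cm)), 0.1)
})

test_that("analysis off a stationary point is refused unless forced", {
  m <- make_harmonic_model(600, masses_amu = 3)
  expect_error(normal_modes(m, 1, q_min = 0.5), "stationary")
  expect_s3_class(normal_modes(m, 1, q_min = 0.5, force = TRUE), "normal_modes")
})

test_that("the bright-state surface keeps its configured tuning modes", {
  # barrier variant: the bright surface has a genuine minimum at the origin
  m <- make_pucker_model(barrier_ev = 0.15, include_dark = FALSE)
  r <- locate_minimum(m, state = 2, q0 = c(0.05, 0.1, -0.1, 0))
  nm <- normal_modes(m, 2, r$q_min, grad_tol = 1e-5)
  freqs <- nm$frequencies_cm
  expect_lt(min(abs(freqs - 600)), 10)
  expect_lt(min(abs(freqs - 750)), 10)
  # local optimality: 100 random nearby points lie higher
  e_min <- eval_adiabatic(m, r$q_min)$energies[2]
  set.seed(9)
  nearby <- vapply(1:100, function(i) {
    dq <- c(rnorm(3, sd = 0.02), 0)   # vibrational coordinates only; the
    eval_adiabatic(m, r$q_min + dq)$energies[2]  # solvent coordinate is driven
  }, numeric(1))
  expect_true(all(nearby >= e_min))
})

test_that("mode energies are zero at rest and conserved for coherent motion", {
  m <- make_harmonic_model(c(600, 750), masses_amu = c(3, 5))
  nm <- normal_modes(m, 1, c(0, 0))
  rest <- fake_trajectory(0:10, rep(0, 11), q = matrix(0, 11, 2))
  rest$p <- matrix(0, 11, 2)
  ep0 <- mode_energy_partition(rest, nm)
  expect_true(all(abs(ep0$total_ev) < 1e-14))

  # single-mode oscillation of amplitude A: constant energy 0.5 w^2 A^2 (mw)
  A <- 0.2
  tr <- run_trajectory(m, q0 = c(A, 0), p0 = c(0, 0), t_max_fs = 200,
                       dt_fs = 0.05, seed = 1)
  ep <- mode_energy_partition(tr, nm)
  w <- 600 / hopta_constants$cm_per_hartree
  e_expect <- 27.211386 * 0.5 * w^2 * (sqrt(3 * 1822.888) * A)^2
  expect_lt(diff(range(ep$total_ev)) / e_expect, 0.01)
  expect_equal(mean(ep$mode1_ev), e_expect, tolerance = 0.01)
  expect_lt(max(ep$mode2_ev), 1e-12)

  # sum of mode energies tracks the total nuclear energy on a harmonic run
  ke <- rowSums(sweep(tr$p^2, 2, 2 * m$masses_me, "/"))
  vtot <- tr$energies[, 1]
  expect_equal(ep$total_ev, 27.211386 * (ke + vtot), tolerance = 0.05)

  expect_error(mode_energy_partition(fake_trajectory(0:5, rep(0, 6)), nm),
               "mismatch")
})
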