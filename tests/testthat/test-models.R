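# Vibronic model construction and adiabatic evaluation

test_that("Tully benchmarks have the canonical structure", {
  m1 <- make_tully_model("simple_avoided_crossing")
  pt0 <- eval_adiabatic(m1, 0)
  # diabatic diagonal elements are equal at the crossing; gap = 2|V12(0)|
  expect_equal(pt0$V[1, 1], pt0$V[2, 2])
  expect_equal(diff(pt0$energies), 2 * abs(pt0$V[1, 2]), tolerance = 1e-12)

  # asymptotic decoupling: adiabatic = diabatic where the coupling vanishes
  for (id in c("simple_avoided_crossing", "dual_avoided_crossing")) {
    m <- make_tully_model(id)
    pt <- eval_adiabatic(m, 25)
    expect_lt(abs(pt$V[1, 2]), 1e-12)
    expect_lt(max(abs(sort(diag(pt$V)) - pt$energies)), 1e-12)
  }
  # the extended-coupling model decouples at x -> -infinity
  m3 <- make_tully_model("extended_coupling")
  pt <- eval_adiabatic(m3, -40)
  expect_lt(abs(pt$V[1, 2]), 1e-12)

  expect_error(make_tully_model("no_such_model"))
})

test_that("adiabatic energies ascend and NAC is antisymmetric", {
  m <- make_pucker_model()
  set.seed(7)
  for (i in 1:5) {
    q <- rnorm(4, sd = 0.4)
    pt <- eval_adiabatic(m, q)
    expect_true(all(diff(pt$energies) >= 0))
    for (mm in 1:4) {
      expect_equal(pt$nac[mm, , ], -t(pt$nac[mm, , ]), tolerance = 1e-12)
    }
    expect_true(all(pt$dipoles >= 0))
    expect_equal(pt$dipoles, t(pt$dipoles), tolerance = 1e-12)
  }
})

test_that("diagonalization round trip reconstructs V to 1e-12", {
  m <- make_pucker_model()
  q <- c(0.6, 0.1, -0.2, 0.3)
  pt <- eval_adiabatic(m, q)
  V_rec <- pt$U %*% diag(pt$energies) %*% t(pt$U)
  expect_lt(max(abs(V_rec - pt$V)), 1e-12)
})

test_that("analytic gradients match central differences to 1e-6", {
  m <- make_tully_model("simple_avoided_crossing")
  set.seed(11)
  xs <- runif(10, -4, 4)
  h <- 1e-6
  for (x in xs) {
    pt <- eval_adiabatic(m, x)
    for (s in 1:2) {
      gnum <- (eval_adiabatic(m, x + h)$energies[s] -
                 eval_adiabatic(m, x - h)$energies[s]) / (2 * h)
      expect_lt(abs(pt$gradients[1, s] - gnum), 1e-6)
    }
  }
})

test_that("NAC matches the finite-difference eigenvector overlap", {
  m <- make_tully_model("simple_avoided_crossing")
  h <- 1e-5
  for (x in c(-1.5, -0.5, 0.7, 1.8)) {
    pt <- eval_adiabatic(m, x)
    up <- eval_adiabatic(m, x + h, u_prev = pt$U)
    dn <- eval_adiabatic(m, x - h, u_prev = pt$U)
    d12_fd <- sum(pt$U[, 1] * (up$U[, 2] - dn$U[, 2])) / (2 * h)
    expect_lt(abs(pt$nac[1, 1, 2] - d12_fd), 1e-5)
  }
})

test_that("zero diabatic coupling gives zero NAC everywhere", {
  m <- electronic_model(
    2, 1, 1,
    diabatic = function(q) list(
      V = matrix(c(0.5 * q^2, 0, 0, 0.1 + 0.3 * q^2), 2, 2),
      dV = array(c(q, 0, 0, 0.6 * q), c(1, 2, 2))),
    dipole = matrix(0, 2, 2))
  for (x in c(-1, 0.3, 2)) {
    expect_equal(eval_adiabatic(m, x)$nac[1, 1, 2], 0)
  }
})

test_that("near-degenerate pairs are flagged and capped, not diverging", {
  m <- electronic_model(
    2, 1, 1,
    diabatic = function(q) list(
      V = matrix(c(0, 1e-7, 1e-7, 1e-9), 2, 2),
      dV = array(c(0.1, 0.2, 0.2, -0.1), c(1, 2, 2))),
    dipole = matrix(0, 2, 2))
  pt <- eval_adiabatic(m, 0)
  expect_true(pt$degenerate[1, 2])
  expect_true(is.finite(pt$nac[1, 1, 2]))
})

test_that("the scanned barrier reproduces the configured height", {
  m <- make_pucker_model(barrier_ev = 0.15, include_dark = FALSE)
  b <- surface_barrier(m)
  expect_equal(b$barrier_ev, 0.15, tolerance = 0.01 / 0.15)
})

test_that("the effective barrier is non-increasing in the relaxed solvent coordinate", {
  m <- make_pucker_model(barrier_ev = 0.05, solvent_coupling_ev = 0.12,
                         include_dark = FALSE)
  heights <- vapply(c(0, 0.4, 0.8, 1), function(qs) {
    surface_barrier(m, q_ref = c(0, 0, 0, qs))$barrier_ev
  }, numeric(1))
  expect_true(all(diff(heights) <= 1e-9))
})

test_that("pucker model rejects unphysical parameters", {
  expect_error(make_pucker_model(mass_pucker_amu = -1), "positive")
  expect_error(make_pucker_model(tuning_wavenumbers_cm = c(-600, 750)), "positive")
  expect_error(make_pucker_model(barrier_ev = 0.5), "range")
})

test_that("the dark state sits at the configured vertical offset", {
  m <- make_pucker_model(include_dark = TRUE, dark_offset_ev = 0.2,
                         dark_coupling_ev = 0)
  pt <- eval_adiabatic(m, rep(0, 4))
  gap_bright <- pt$energies_ev[2] - pt$energies_ev[1]
  gap_dark <- pt$energies_ev[3] - pt$energies_ev[1]
  expect_equal(gap_dark - gap_bright, 0.2, tolerance = 0.02)
  expect_identical(m$n_states, 3L)
  expect_identical(make_pucker_model(include_dark = FALSE)$n_states, 2L)
})

test_that("model config round trip rebuilds an identical model", {
  m <- make_pucker_model(barrier_ev = 0.12, mass_pucker_amu = 3,
                         include_dark = FALSE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  set.seed(3)
  for (i in 1:5) {
    q <- rnorm(4, sd = 0.5)
    expect_equal(m$diabatic(q)$V, m2$diabatic(q)$V, tolerance = 1e-12)
  }
  expect_equal(m$masses_amu, m2$masses_amu)
})

test_that("fast two-state path agrees with the generic matrix path", {
  m <- make_pucker_model(include_dark = FALSE)
  set.seed(5)
  for (i in 1:5) {
    q <- rnorm(4, sd = 0.6)
    f <- m$diabatic2(q)
    d <- m$diabatic(q)
    expect_equal(f$v11, d$V[1, 1], tolerance = 1e-14)
    expect_equal(f$v22, d$V[2, 2], tolerance = 1e-14)
    expect_equal(f$v12, d$V[1, 2], tolerance = 1e-14)
    expect_equal(f$d22, d$dV[, 2, 2], tolerance = 1e-14)
  }
})
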