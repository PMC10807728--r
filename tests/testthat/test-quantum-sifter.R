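test_that("two-spin SIFTER reproduces cos(omega (tau2 - tau1)) on a delay grid", {
  for (om in c(0.7, 1.9, 3.3, 5.1, 8.4)) {
    sys <- spin_system(2, data.frame(i = 1, j = 2, omega = om))
    tau1 <- seq(0.05, 1.4, length.out = 20)
    tau2 <- seq(0, 1.2, length.out = 20)
    err <- 0
    for (a in tau1) for (b in tau2) {
      v <- run_sequence(sys, sequence_preset("sifter", tau1 = a, tau2 = b),
                        detect = 1:2)
      err <- max(err, abs(v - cos(om * (b - a))))
    }
    expect_lt(err, 1e-10)
  }
})

test_that("propagation is unitary and trace-preserving through a sequence", {
  helper <- random_mono_system(4, seed = 3)
  sys <- helper$system
  n <- 4; dim2 <- 2^n
  rho <- matrix(0 + 0i, dim2, dim2)
  for (k in 1:n) rho <- rho - diag(siftr:::sz_diag(n, k))
  ev0 <- sort(Re(eigen(rho, only.values = TRUE)$values))
  dH <- secular_hamiltonian(sys)
  for (ev in sequence_preset("sifter", tau1 = 0.37, tau2 = 0.81)) {
    if (ev$type == "pulse") {
      U <- ideal_pulse(n, ev$flip, ev$phase)
      rho <- U %*% rho %*% Conj(t(U))
    } else {
      ph <- exp(-1i * ev$tau * dH)
      rho <- rho * (ph %o% Conj(ph))
    }
  }
  expect_lt(max(abs(rho - Conj(t(rho)))), 1e-12)         # Hermitian
  expect_lt(abs(sum(diag(rho)) - 0), 1e-12)              # trace preserved
  ev1 <- sort(Re(eigen(rho, only.values = TRUE)$values))
  expect_lt(max(abs(ev1 - ev0)), 1e-10)                  # spectrum preserved
})

test_that("SIFTER and SIDRE toggle separates the cos-cos and sin-sin pathways", {
  om <- 2.4; tau1 <- 0.7; tau2 <- 0.35
  sys <- spin_system(2, data.frame(i = 1, j = 2, omega = om))
  vs <- run_sequence(sys, sequence_preset("sifter", tau1 = tau1, tau2 = tau2),
                     detect = 1:2)
  vr <- run_sequence(sys, sequence_preset("sidre", tau1 = tau1, tau2 = tau2),
                     detect = 1:2)
  expect_equal((vs + vr) / 2, cos(om * tau1) * cos(om * tau2), tolerance = 1e-12)
  expect_equal((vs - vr) / 2, sin(om * tau1) * sin(om * tau2), tolerance = 1e-12)
  ## SIDRE on an uncoupled spin is flat at 1
  expect_equal(run_sequence(spin_system(1),
                            sequence_preset("sidre", tau1 = 0.3, tau2 = 0.9)),
               1, tolerance = 1e-12)
})

test_that("monoradical A channel equals the cosine product for 3-5 spins", {
  for (n in 3:5) {
    helper <- random_mono_system(n, seed = n)
    for (tau in list(c(0.4, 0.4), c(0.8, 0.3), c(0.25, 1.1))) {
      v <- run_sequence(helper$system,
                        sequence_preset("sifter", tau1 = tau[1], tau2 = tau[2]),
                        detect = 1, polarization = c(1, rep(0, n - 1)))
      expect_equal(v, oracle_mono_product(helper$omega_A, tau[1], tau[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("remote-spin transfer signal converges quadratically to the analytic limit", {
  omega0 <- 3.1; omega_t <- 1.9; tau1 <- 0.7; tau2 <- 0.35
  lim <- cos(omega0 * tau1) * cos(omega_t * tau2) * tau1 * tau2
  om1s <- c(0.08, 0.04, 0.02)
  errs <- vapply(om1s, function(om1) {
    sys <- spin_system(3, data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                     omega = c(omega0, om1, omega_t)))
    v <- run_sequence(sys, sequence_preset("sifter", tau1 = tau1, tau2 = tau2),
                      detect = 3, polarization = c(1, 0, 0))
    abs(v / om1^2 - lim)
  }, numeric(1))
  expect_lt(errs[3], 1e-4)
  ## quadratic convergence: halving omega1 divides the error by ~4
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.1)
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.1)
})

test_that("detected signals scale exactly linearly with initial polarization", {
  helper <- random_mono_system(4, seed = 11)
  spec <- sequence_preset("sifter", tau1 = 0.6, tau2 = 0.45)
  v1 <- run_sequence(helper$system, spec, detect = 1:4, polarization = 1)
  for (p in c(0.5, 0.17, 2)) {
    vp <- run_sequence(helper$system, spec, detect = 1:4, polarization = p)
    expect_equal(vp, p * v1, tolerance = 1e-12)
  }
})

test_that("exact SIFTER traces respect symmetry and grid validation", {
  om <- 2 * pi  # omega * tau0 = 2 pi at tau0 = 1
  sys <- spin_system(2, data.frame(i = 1, j = 2, omega = om))
  tg <- seq(-1, 1, 0.1)
  tr <- sifter_trace_exact(sys, tau0 = 1, t_grid = tg, detect = 1:2)
  expect_equal(tr$amplitude, cos(om * tg), tolerance = 1e-10)
  expect_equal(tr$amplitude[tg == 0], 1, tolerance = 1e-12)
  expect_equal(tr$amplitude, rev(tr$amplitude), tolerance = 1e-10)
  expect_error(sifter_trace_exact(sys, tau0 = 1, t_grid = c(-2, 0)),
               "outside")
})
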