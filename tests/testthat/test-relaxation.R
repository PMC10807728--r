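test_that("Bt is a normalised, monotone stretched-exponential mixture", {
  m <- relaxation_model(tau_d = c(2, 6), beta = c(1.4, 1), weights = c(0.4, 0.6),
                        xi = 2)
  expect_equal(evaluate_bt(m, 0), 1)
  taus <- seq(0, 5, 0.05)
  expect_true(all(diff(evaluate_bt(m, taus)) < 0))
  m1 <- relaxation_model(tau_d = 3, beta = 1.2)
  expect_equal(evaluate_bt(m1, 3 / 2), exp(-1), tolerance = 1e-12)
})

test_that("SIDRE surface obeys boundary equality, product reduction and decoupling", {
  ## boundary: BS(tau, 0) = Bt(tau), also for multi-component models
  m <- relaxation_model(tau_d = c(2, 6), beta = c(1.4, 1), weights = c(0.4, 0.6),
                        xi = 2)
  for (tau in c(0.3, 1.1, 2.7)) {
    expect_equal(evaluate_bs(m, tau, 0), evaluate_bt(m, tau), tolerance = 1e-14)
    expect_equal(evaluate_bs(m, 0, tau), evaluate_bt(m, tau), tolerance = 1e-14)
  }
  ## xi = beta: single-component surface is the product of Hahn decays
  mp <- relaxation_model(tau_d = 3, beta = 1.3, xi = 1.3)
  for (tau in list(c(0.4, 1.2), c(2, 0.7)))
    expect_equal(evaluate_bs(mp, tau[1], tau[2]),
                 evaluate_bt(mp, tau[1]) * evaluate_bt(mp, tau[2]),
                 tolerance = 1e-14)
  ## decoupling inequality BS(tau,tau) >= Bt(tau)^2 on a parameter sweep
  for (beta in c(0.7, 1, 1.6, 2.4)) for (xi in c(1, 1.5, 2.5, 4)) {
    if (xi < max(beta, 1)) next
    ms <- relaxation_model(tau_d = 4, beta = beta, xi = xi)
    for (tau in seq(0.2, 4, 0.4))
      expect_gte(evaluate_bs(ms, tau, tau), evaluate_bt(ms, tau)^2 - 1e-12)
  }
  ## maximum of the fixed-tau0 trace sits at t = 0 for xi > 1
  m2 <- relaxation_model(tau_d = 4, beta = 1.3, xi = 2.2)
  tg <- seq(-2, 2, 0.01)
  bs <- evaluate_bs(m2, (2 + tg) / 2, (2 - tg) / 2)
  expect_equal(tg[which.max(bs)], 0)
  expect_error(relaxation_model(tau_d = 1, beta = 2, xi = 1.5), "xi < beta")
})

test_that("division trace is 1 at the ends, minimal at t = 0, and flat when xi = beta", {
  m <- relaxation_model(tau_d = 4, beta = 1.3, xi = 2.2)
  tau0 <- 2.5
  tg <- seq(-tau0, tau0, 0.01)
  r <- ratio_surface(m, tau0, tg)
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_equal(r[length(r)], 1, tolerance = 1e-12)
  expect_true(all(r <= 1 + 1e-12))
  expect_equal(tg[which.min(r)], 0)
  ## non-decreasing in |t|
  pos <- r[tg >= 0]
  expect_true(all(diff(pos) >= -1e-12))
  mp <- relaxation_model(tau_d = 4, beta = 1.3, xi = 1.3)
  expect_equal(ratio_surface(mp, tau0, tg), rep(1, length(tg)),
               tolerance = 1e-12)
})

test_that("SSE fitting recovers generating parameters", {
  ## single stretched exponential, noise-free: near-exact recovery
  x <- seq(0.04, 8, 0.04)
  y <- exp(-(x / 2)^1.4)
  fit <- fit_decay(y, n_components = 1, x = x)
  cf <- coef(fit)
  expect_equal(unname(cf["tau_d1"]), 2, tolerance = 1e-6)
  expect_equal(unname(cf["beta1"]), 1.4, tolerance = 1e-6)
  expect_equal(unname(cf["amplitude"]), 1, tolerance = 1e-6)
  expect_false(fit$degenerate)
  ## two well-separated components at SNR 100: time constants within 5 %
  x2 <- seq(0.02, 10, 0.02)
  y2 <- 0.5 * exp(-(x2 / 0.6)^1) + 0.5 * exp(-(x2 / 6)^2)
  y2n <- y2 + siftr:::with_seed(8, rnorm(length(x2), 0, max(y2) / 100))
  y2n <- pmax(y2n, 1e-4)
  fit2 <- fit_decay(y2n, n_components = 2, x = x2)
  td <- sort(fit2$model$tau_d)
  expect_equal(unname(td[1]), 0.6, tolerance = 0.05)
  expect_equal(unname(td[2]), 6, tolerance = 0.05)
  ## constant trace flags the degenerate infinite-time limit
  fit3 <- fit_decay(rep(1, length(x)), n_components = 1, x = x)
  expect_true(fit3$degenerate)
  ## predict() reproduces the fitted curve on the echo-time axis
  expect_equal(predict(fit, x), fit$fitted, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("SIDRE xi fit recovers the decoupling exponent from a trace", {
  truth <- relaxation_model(tau_d = 3.5, beta = 1.3, xi = 2.2)
  tau0 <- 2.5
  tg <- seq(-tau0, tau0, 0.02)
  tr <- dipolar_trace(tg, evaluate_bs(truth, (tau0 + tg) / 2, (tau0 - tg) / 2),
                      tau0 = tau0, sequence = "sidre")
  bt_only <- relaxation_model(tau_d = 3.5, beta = 1.3, xi = 1.3)
  fit <- fit_sidre_xi(tr, bt_only)
  expect_equal(fit$xi, 2.2, tolerance = 1e-4)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
})
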