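test_that("configuration sampling honours Poisson counts, exclusion and determinism", {
  s <- mc_settings(50, n_realizations = 100, seed = 5, tau_max = 2)
  cfg <- sample_configuration(s)
  expect_identical(cfg, sample_configuration(s))   # same seed, same draw
  expect_true(all(sqrt(rowSums(cfg$positions^2)) >= s$r_min))
  ## mean count over draws ~ C * V within 3 standard errors
  counts <- vapply(1:300, function(k)
    nrow(sample_configuration(s, seed = 1000 + k)$positions), numeric(1))
  mu <- s$C * 4 / 3 * pi * s$box_radius^3
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 300) + 3 * sd(counts) / sqrt(300))
  ## a sampling sphere smaller than 5 mean nearest-neighbour distances is
  ## rejected (the background would be truncated)
  expect_error(mc_settings(1e-6, n_realizations = 100, seed = 1,
                           box_radius = 200, tau_max = 0.1),
               "nearest-neighbour")
  ## bi mode needs a distribution and adds the intramolecular partner
  sb <- mc_settings(50, n_realizations = 100, seed = 2, mode = "bi", tau_max = 2)
  expect_error(sample_configuration(sb), "distribution")
  cfgb <- sample_configuration(sb, dist = gaussian_distribution(3, 0.2))
  expect_length(cfgb$partner0, 3)
  expect_true(is.finite(cfgb$omega0))
})

test_that("Monte-Carlo B2p matches the analytic homogeneous exponential within 2 %", {
  s <- mc_settings(50, n_realizations = 10000, seed = 17, tau_max = 3)
  tau <- seq(0.3, 3, length.out = 8)
  b <- b2p_curve(s, tau)
  expect_equal(b$B2p[1], b$B2p[1])  # finite
  oracle <- oracle_b2p(tau, s$C, s$r_min, s$box_radius)
  expect_lt(max(abs(b$B2p - oracle) / oracle), 0.02)
  ## bounded and non-increasing envelope within MC error
  expect_true(all(abs(b$B2p) <= 1))
  expect_true(all(diff(b$B2p) < 3 * (b$se[-1] + b$se[-length(b$se)])))
  ## B2p(0) = 1 exactly
  b0 <- b2p_curve(mc_settings(50, n_realizations = 200, seed = 1, tau_max = 1),
                  c(0, 0.5))
  expect_equal(b0$B2p[1], 1)
})

test_that("halving the concentration halves the background exponent", {
  tau <- c(1, 2, 3)
  b1 <- b2p_curve(mc_settings(60, n_realizations = 8000, seed = 23, tau_max = 3),
                  tau)
  b2 <- b2p_curve(mc_settings(30, n_realizations = 8000, seed = 29, tau_max = 3),
                  tau)
  expect_equal(-log(b2$B2p), -log(b1$B2p) / 2, tolerance = 0.06)
})

test_that("the summed second moment matches the closed-form shell integral", {
  s <- mc_settings(50, n_realizations = 4000, seed = 31, tau_max = 2)
  sm <- second_moment(s)
  oracle <- oracle_second_moment(s$C, s$r_min, s$box_radius)
  expect_lt(abs(sm$D - oracle), 4 * sm$se + 0.02 * oracle)
  expect_identical(sm$r_min, s$r_min)
  ## doubling r_min reduces D (positive integrand)
  s2 <- mc_settings(50, r_min = 3, n_realizations = 4000, seed = 31, tau_max = 2)
  expect_lt(second_moment(s2)$D, sm$D)
})

test_that("MC standard errors shrink as 1/sqrt(n)", {
  tau <- c(1.5, 2.5)
  se1 <- b2p_curve(mc_settings(50, n_realizations = 1000, seed = 41,
                               tau_max = 3), tau)$se
  se2 <- b2p_curve(mc_settings(50, n_realizations = 4000, seed = 43,
                               tau_max = 3), tau)$se
  expect_equal(se1 / se2, rep(2, 2), tolerance = 0.35)
})

test_that("factorization check is exact at tau1 = 0 and unbiased for independent draws", {
  s <- mc_settings(50, n_realizations = 600, seed = 7, tau_max = 2.5)
  fc0 <- factorization_check(s, 0, 1.5)
  ## at tau1 = 0 the A-side product is identically 1, so joint equals the
  ## factorized average exactly
  expect_equal(fc0$joint, fc0$factorized, tolerance = 1e-12)
  expect_lt(abs(fc0$discrepancy), 1e-12)
  ## transfer-weighted check at 50 uM: discrepancy reported with errors
  fc <- factorization_check(s, 2, 2)
  expect_true(is.finite(fc$discrepancy))
  expect_true(is.finite(fc$discrepancy_se))
  expect_gt(fc$n_used, 0)
})

test_that("power-law fitter recovers injected scaling exponents", {
  C <- c(5, 10, 25, 50, 100)
  ## exact injected power laws (confint warns about the perfect fit)
  suppressWarnings({
    expect_equal(fit_power_law(C, 0.3 * C)$exponent, 1, tolerance = 1e-10)
    expect_equal(fit_power_law(C, 2e-4 * C^2)$exponent, 2, tolerance = 1e-10)
  })
  ## measured exponent of the cutoff-dominated summed second moment:
  ## linear in concentration, reported with its confidence interval
  s <- mc_settings(50, n_realizations = 800, seed = 13, tau_max = 1.5)
  scan <- artefact_scaling_scan(s, c(10, 25, 50, 100))
  expect_true(is.finite(scan$exponent))
  expect_lt(scan$ci[1], scan$exponent)
  expect_gt(scan$ci[2], scan$exponent)
  expect_equal(scan$exponent, 1, tolerance = 0.15)
})
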