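test_that("transfer factor is the down-curved parabola with the right anchors", {
  D <- 0.08; tau0 <- 2
  tg <- seq(-tau0, tau0, 0.05)
  tt <- siftr:::tau_split(tau0, tg)
  v <- transfer_factor(D, tt$tau1, tt$tau2)
  expect_equal(v, D / 4 * (tau0^2 - tg^2), tolerance = 1e-14)
  expect_equal(v[1], 0)                          # tau2 = 0 end
  expect_equal(v[length(v)], 0)                  # tau1 = 0 end
  expect_equal(max(v), D * tau0^2 / 4)
  expect_equal(tg[which.max(v)], 0)
  expect_equal(v, rev(v))                        # even in t
})

test_that("monoradical composition assembles BS + D tau1 tau2 BtBt", {
  m <- relaxation_model(tau_d = 3.5, beta = 1.3, xi = 2.2)
  tau0 <- 2.5; tg <- seq(-tau0, tau0, 0.02)
  tr <- compose_monoradical(m, 0.05, tau0, tg)
  bd <- tr$meta$breakdown
  expect_equal(tr$amplitude, bd$BS + bd$Dtau * bd$BtBt, tolerance = 1e-14)
  expect_equal(tr$amplitude, rev(tr$amplitude), tolerance = 1e-12)
  ## D = 0 reduces to the SIDRE surface
  tr0 <- compose_monoradical(m, 0, tau0, tg)
  tt <- siftr:::tau_split(tau0, tg)
  expect_equal(tr0$amplitude, evaluate_bs(m, tt$tau1, tt$tau2),
               tolerance = 1e-14)
  ## trace ends equal Bt(tau0): BS boundary equality + vanishing transfer
  expect_equal(tr$amplitude[1], evaluate_bt(m, tau0), tolerance = 1e-12)
  expect_equal(tr$amplitude[length(tg)], evaluate_bt(m, tau0), tolerance = 1e-12)
  ## divided form: 1 + D tau1 tau2 BtBt / BS
  s <- divide_by_sidre(tr, m)
  expect_equal(s$amplitude, 1 + bd$Dtau * bd$BtBt / bd$BS, tolerance = 1e-12)
  ## with xi = beta the divided monoradical trace is the pure parabola
  mp <- relaxation_model(tau_d = 3.5, beta = 1.3, xi = 1.3)
  sp <- divide_by_sidre(compose_monoradical(mp, 0.05, tau0, tg), mp)
  expect_equal(sp$amplitude, 1 + transfer_factor(0.05, tt$tau1, tt$tau2),
               tolerance = 1e-12)
})

test_that("artefact term vanishes at the ends and reduces to the transfer factor", {
  tau0 <- 2; tg <- seq(-tau0, tau0, 0.05)
  tt <- siftr:::tau_split(tau0, tg)
  d <- gaussian_distribution(3, 0.2)
  F1 <- powder_form_factor(d, tt$tau1)
  F2 <- powder_form_factor(d, tt$tau2)
  a <- artefact_term(F1, F2, 0.05, tt$tau1, tt$tau2)
  expect_equal(a[1], 0); expect_equal(a[length(a)], 0)
  expect_true(all(abs(a) <= 0.05 * tau0^2 / 4 + 1e-12))
  expect_equal(artefact_term(1, 1, 0.05, tt$tau1, tt$tau2),
               transfer_factor(0.05, tt$tau1, tt$tau2))
})

test_that("grouped and direct biradical assemblies agree on random parameter draws", {
  tau0 <- 2.2; tg <- seq(-tau0, tau0, 0.05)
  for (k in 1:20) {
    set.seed(k)
    d <- gaussian_distribution(runif(1, 2.8, 4.2), runif(1, 0.1, 0.3))
    beta <- runif(1, 0.7, 1.8)
    m <- relaxation_model(tau_d = runif(1, 2, 8), beta = beta,
                          xi = runif(1, max(beta, 1), 3))
    lambda <- runif(1, 0, 0.9)
    D <- runif(1, 0, 0.2)
    g <- compose_biradical(d, m, lambda, D, tau0, tg, form = "grouped")
    x <- compose_biradical(d, m, lambda, D, tau0, tg, form = "direct")
    expect_lt(max(abs(g$amplitude - x$amplitude)), 1e-10)
    expect_equal(g$amplitude, rev(g$amplitude), tolerance = 1e-10)
  }
})

test_that("biradical composition has the right limiting cases", {
  d <- gaussian_distribution(3, 0.2)
  m <- relaxation_model(tau_d = 3.5, beta = 1.3, xi = 2.2)
  tau0 <- 2.5; tg <- seq(-tau0, tau0, 0.02)
  ## lambda = 0: exactly the monoradical signal
  expect_equal(compose_biradical(d, m, 0, 0.05, tau0, tg)$amplitude,
               compose_monoradical(m, 0.05, tau0, tg)$amplitude,
               tolerance = 1e-14)
  ## lambda = 1, D = 0, relaxation off: the bare form factor (K-terms cancel)
  expect_equal(compose_biradical(d, NULL, 1, 0, tau0, tg)$amplitude,
               powder_form_factor(d, tg), tolerance = 1e-14)
  ## modulated/unmodulated separability from the breakdown
  v <- compose_biradical(d, m, 0.3, 0.05, tau0, tg)
  bd <- v$meta$breakdown
  rec <- (v$amplitude - bd$V_nm_scaled) / (0.3 * 0.5 * (bd$BS + bd$BtBt))
  tt <- siftr:::tau_split(tau0, tg)
  expect_equal(rec, bd$F + bd$artefact * bd$BtBt / (0.5 * (bd$BS + bd$BtBt)),
               tolerance = 1e-12)
})

test_that("powder-averaged composition matches exact propagation for a pair", {
  ## relaxation off, lambda = 1, delta distance: the composed biradical
  ## trace equals the quantum propagator's two-spin SIFTER trace
  r <- 3.2; tau0 <- 1.2
  tg <- seq(-tau0, tau0, length.out = 41)
  comp <- compose_biradical(delta_distribution(r), NULL, 1, 0, tau0, tg,
                            n_theta = 400)
  ## exact propagation per orientation node, averaged with the same weights
  ang <- siftr:::orientation_nodes(400L)
  acc <- numeric(length(tg))
  for (i in seq_along(ang$u)) {
    om <- dipolar_frequency_u(r, ang$u[i])
    acc <- acc + ang$w[i] * cos(om * tg)   # isolated-pair cosine oracle per node
  }
  expect_equal(comp$amplitude, acc / sum(ang$w), tolerance = 1e-10)
  ## spot-check one orientation against the full density-matrix propagator
  om1 <- dipolar_frequency_u(r, ang$u[17])
  sys <- spin_system(2, data.frame(i = 1, j = 2, omega = om1))
  tr <- sifter_trace_exact(sys, tau0, tg[c(5, 21, 33)], detect = 1:2)
  expect_equal(tr$amplitude, cos(om1 * tg[c(5, 21, 33)]), tolerance = 1e-10)
})

test_that("SIDRE division masks sub-floor points and reports them", {
  tau0 <- 2; tg <- seq(-tau0, tau0, 0.1)
  tr <- dipolar_trace(tg, rep(1, length(tg)), tau0 = tau0)
  bs <- rep(1, length(tg)); bs[c(3, 7)] <- 1e-9
  expect_warning(out <- divide_by_sidre(tr, bs), "masked")
  expect_identical(out$meta$n_masked, 2L)
  expect_true(all(is.na(out$amplitude[c(3, 7)])))
  expect_equal(out$amplitude[-c(3, 7)], rep(1, length(tg) - 2))
})

test_that("main-term background interpolates between BtBt and BS", {
  m <- relaxation_model(tau_d = 3.5, beta = 1.3, xi = 2.2)
  tau0 <- 2.5; tg <- seq(-tau0, tau0, 0.02)
  tt <- siftr:::tau_split(tau0, tg)
  main <- main_term_background(m, tau0, tg)
  bs <- evaluate_bs(m, tt$tau1, tt$tau2)
  btbt <- evaluate_bt(m, tt$tau1) * evaluate_bt(m, tt$tau2)
  expect_true(all(main > 0))
  expect_true(all(main >= pmin(bs, btbt) - 1e-14))
  expect_true(all(main <= pmax(bs, btbt) + 1e-14))
  expect_equal(main[1], evaluate_bt(m, tau0), tolerance = 1e-12)
  mp <- relaxation_model(tau_d = 3.5, beta = 1.3, xi = 1.3)
  expect_equal(main_term_background(mp, tau0, tg),
               evaluate_bs(mp, tt$tau1, tt$tau2), tolerance = 1e-14)
})
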