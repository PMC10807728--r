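## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: brute-force quadrature, closed-form integrals
## and direct product-operator algebra.

## Analytic two-pulse intermolecular background for a grand-canonical
## uniform ensemble in a sphere:
##   B2p(tau) = exp(-C * int_{r_min}^{R} 4 pi r^2 <1 - cos(w(r,u) tau)>_u dr)
## evaluated by dense trapezoidal quadrature (independent of the MC code).
oracle_b2p <- function(tau, C_nm3, r_min, R, n_u = 2001L, n_r = 4001L) {
  u <- seq(0, 1, length.out = n_u)
  r <- seq(r_min, R, length.out = n_r)
  pref <- 2 * pi * 52.04 # rad/us nm^3, 2*pi*Cdd with Cdd ~ mu0 g^2 muB^2/(4 pi h)
  vapply(tau, function(tt) {
    inner <- vapply(r, function(rr)
      mean(1 - cos(pref / rr^3 * (1 - 3 * u^2) * tt)), numeric(1))
    exp(-C_nm3 * pracma::trapz(r, 4 * pi * r^2 * inner))
  }, numeric(1))
}

## Closed-form shell integral for the summed second moment
##   D = C * int_{r_min}^{R} <w^2>_theta 4 pi r^2 dr,
## with the angular average <(1-3u^2)^2> = 4/5.
oracle_second_moment <- function(C_nm3, r_min, R) {
  pref <- 2 * pi * 52.04
  C_nm3 * pref^2 * (4 / 5) * 4 * pi * (1 / (3 * r_min^3) - 1 / (3 * R^3))
}

## Brute-force powder form factor by dense Riemann sums in cos(theta)
## (midpoint rule, 1e5 nodes) -- independent of the Gauss-Legendre path.
oracle_form_factor <- function(r, t, n_u = 1e5L) {
  u <- (seq_len(n_u) - 0.5) / n_u
  pref <- 2 * pi * 52.04 / r^3
  vapply(t, function(tt) mean(cos(pref * (1 - 3 * u^2) * tt)), numeric(1))
}

## Direct product-operator prediction for the monoradical A channel.
oracle_mono_product <- function(om, tau1, tau2) {
  prod(cos(om * tau1)) * prod(cos(om * tau2))
}

## Random small spin system: star topology around the A spin plus random
## B-B couplings.
random_mono_system <- function(n, seed) {
  set.seed(seed)
  om <- stats::runif(n - 1, 0.3, 6)
  cpl <- data.frame(i = 1, j = 2:n, omega = om)
  if (n > 2) {
    bb <- t(utils::combn(2:n, 2))
    cpl <- rbind(cpl, data.frame(i = bb[, 1], j = bb[, 2],
                                 omega = stats::runif(nrow(bb), 0.2, 3)))
  }
  list(system = spin_system(n, cpl), omega_A = om)
}

## Random distance distribution within the working envelope of the study
## generator (spin-label pairs with r ~ 3-4 nm, narrow Gaussian widths).
random_distribution <- function(seed) {
  set.seed(seed)
  gaussian_distribution(stats::runif(1, 3.0, 4.2), stats::runif(1, 0.1, 0.2))
}
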