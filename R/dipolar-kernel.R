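#' Secular dipolar frequency of a spin pair
#'
#' Computes the orientation-dependent secular dipolar coupling
#' \eqn{\omega_{dd}(r,\theta) = 2\pi C_{dd} / r^3 (1 - 3\cos^2\theta)}
#' in rad/µs, where \eqn{\theta} is the angle between the inter-spin vector
#' and the static field and \eqn{C_{dd}} is [dipolar_constant()] in
#' MHz nm^3.  The frequency vanishes at the magic angle
#' \eqn{\theta = \arccos(1/\sqrt3)} and scales as \eqn{1/r^3}.
#'
#' @param r distance in nm (> 0), vectorised.
#' @param theta angle in rad, vectorised.
#' @param Cdd coupling constant in MHz nm^3.
#' @return angular frequency in rad/µs.
#' @export
#' @examples
#' dipolar_frequency(2, pi / 2) / (2 * pi)   # ~ -6.5 MHz (perpendicular)
#' dipolar_frequency(3, acos(1 / sqrt(3)))   # 0 at the magic angle
dipolar_frequency <- function(r, theta, Cdd = dipolar_constant()) {
  if (any(r <= 0)) stop("distance must be positive")
  2 * pi * Cdd / r^3 * (1 - 3 * cos(theta)^2)
}

## Same, parameterised by u = cos(theta) (uniform for an isotropic powder).
dipolar_frequency_u <- function(r, u, Cdd = dipolar_constant()) {
  2 * pi * Cdd / r^3 * (1 - 3 * u^2)
}

## Gauss-Legendre nodes/weights on u = cos(theta) in [0, 1] (the integrand
## is even in u).  Deterministic; cached per node count.
.gl_cache <- new.env(parent = emptyenv())
orientation_nodes <- function(n_theta = 201L) {
  key <- as.character(n_theta)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n_theta, 0, 1)
    .gl_cache[[key]] <- list(u = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

## Shared quadrature over (r, u) for a distance distribution.  Returns the
## vector of dipolar frequencies omega (rad/µs) and matching weights that
## sum to one -- the "powder" measure used by all kernel averages below.
powder_quadrature <- function(dist, n_theta = 201L, n_r = 101L,
                              Cdd = dipolar_constant()) {
  ang <- orientation_nodes(n_theta)
  rad <- dd_nodes(dist, n_r)
  omega <- outer(2 * pi * Cdd / rad$r^3, 1 - 3 * ang$u^2)
  w <- outer(rad$w, ang$w)
  list(omega = as.vector(omega), w = as.vector(w) / sum(w))
}

#' Powder-averaged dipolar form factor F(t)
#'
#' The intramolecular form factor is the time-domain Pake signal
#' \eqn{F(t) = \langle \cos(\omega_{dd}(r,\theta) t) \rangle}, averaged
#' over orientations uniform in \eqn{\cos\theta} and over distances drawn
#' from `dist`.  F(0) = 1 and F is even in t.  The orientation average uses
#' Gauss-Legendre quadrature (deterministic) and the distance average a
#' trapezoidal rule.
#'
#' @param dist a [distance_distribution][gaussian_distribution].
#' @param t time grid in µs.
#' @param n_theta,n_r quadrature resolution (orientation / distance nodes).
#' @param Cdd coupling constant in MHz nm^3.
#' @return numeric vector F(t) on `t`.
#' @export
#' @examples
#' tt <- seq(0, 3, 0.01)
#' F <- powder_form_factor(delta_distribution(3), tt)
#' F[1]   # exactly 1
powder_form_factor <- function(dist, t, n_theta = 201L, n_r = 101L,
                               Cdd = dipolar_constant()) {
  if (length(t) == 0L) stop("empty time grid")
  q <- powder_quadrature(dist, n_theta, n_r, Cdd)
  ## cos(omega t) weighted sum; vectorised as a matrix product
  as.vector(crossprod(q$w, cos(outer(q$omega, t))))
}

#' Sine-product artefact kernel Fs(tau1, tau2)
#'
#' The coherence-transfer pathway of the SIFTER signal carries the kernel
#' \eqn{F_s(\tau_1,\tau_2) = \langle \sin(\omega_{dd}\tau_1)
#' \sin(\omega_{dd}\tau_2)\rangle}.  By the product-to-sum identity it
#' equals \eqn{\tfrac12 F(\tau_2-\tau_1) - \tfrac12 \langle\cos
#' \omega_{dd}(\tau_1+\tau_2)\rangle}; the second term is constant along a
#' SIFTER trace of fixed total length (see [fixed_sum_cosine()]).
#'
#' @inheritParams powder_form_factor
#' @param tau1,tau2 delays in µs (vectorised, equal length).
#' @export
sine_product_term <- function(dist, tau1, tau2, n_theta = 201L, n_r = 101L,
                              Cdd = dipolar_constant()) {
  stopifnot(all(tau1 >= 0), all(tau2 >= 0))
  q <- powder_quadrature(dist, n_theta, n_r, Cdd)
  s1 <- sin(outer(q$omega, tau1))
  s2 <- sin(outer(q$omega, tau2))
  as.vector(crossprod(q$w, s1 * s2))
}

#' Fixed-sum cosine constant K(tau0)
#'
#' \eqn{K(\tau_0) = \langle \cos(\omega_{dd} \tau_0) \rangle} evaluated on
#' the same powder quadrature as [powder_form_factor()]; because
#' \eqn{\tau_1 + \tau_2 = \tau_0} is held fixed in SIFTER, this term is
#' constant at every point of a trace.  Identical to the form factor
#' evaluated at \eqn{t = \tau_0}.
#'
#' @inheritParams powder_form_factor
#' @param tau0 half the total transverse evolution time, µs.
#' @export
fixed_sum_cosine <- function(dist, tau0, n_theta = 201L, n_r = 101L,
                             Cdd = dipolar_constant()) {
  stopifnot(tau0 >= 0)
  powder_form_factor(dist, tau0, n_theta, n_r, Cdd)
}
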