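## Single spin-1/2 operator matrices (hbar = 1).
.half_ops <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2, 2),
  y = matrix(c(0 + 0i, 0 + 0.5i, 0 - 0.5i, 0 + 0i), 2, 2),
  z = matrix(c(0.5, 0, 0, -0.5), 2, 2),
  i = diag(2)
)

#' Build a product spin operator on an n-spin Hilbert space
#'
#' Constructs the Kronecker product of single spin-1/2 operators
#' (\eqn{S_x, S_y, S_z}, entries \eqn{\pm 1/2, \pm i/2}) and identities.
#' Spin 1 is the slowest-varying tensor factor.  No factors of two are
#' applied: `build_spin_operator(2, c("z","z"))` is \eqn{S_zI_z} with
#' diagonal (1/4, -1/4, -1/4, 1/4).
#'
#' @param n_spins number of spins.
#' @param axes named or positional specification of single-spin axes: a
#'   character vector of length `n_spins` with entries in
#'   `c("x","y","z","i")` (`"i"` = identity), or a named list/vector
#'   mapping spin indices to axes (unmentioned spins get identity).
#' @return complex matrix of dimension 2^n.
#' @export
#' @examples
#' build_spin_operator(1, "z")            # diag(1/2, -1/2)
#' build_spin_operator(3, list(`2` = "x"))
build_spin_operator <- function(n_spins, axes) {
  stopifnot(n_spins >= 1, n_spins <= 10)
  ax <- rep("i", n_spins)
  if (!is.null(names(axes)) && any(nzchar(names(axes)))) {
    idx <- as.integer(names(axes))
    if (any(is.na(idx) | idx < 1 | idx > n_spins))
      stop("spin index out of range")
    ax[idx] <- unlist(axes)
  } else {
    axes <- unlist(axes)
    if (length(axes) != n_spins)
      stop("axes must name spins or have length n_spins")
    ax <- axes
  }
  if (!all(ax %in% names(.half_ops))) stop("unknown axis; use x, y, z or i")
  out <- .half_ops[[ax[1]]]
  for (k in seq_len(n_spins - 1L)) out <- kronecker(out, .half_ops[[ax[k + 1L]]])
  out + 0i
}

## Diagonal of Sz for spin k in the 2^n product basis: +1/2 where the k-th
## spin is alpha, -1/2 where beta.  Spin 1 varies slowest.
sz_diag <- function(n_spins, k) {
  block <- 2^(n_spins - k)
  rep(rep(c(0.5, -0.5), each = block), length.out = 2^n_spins)
}

#' Secular dipolar Hamiltonian of a spin system
#'
#' \eqn{H = \sum_{i<j} \omega_{ij} S_z^{(i)} S_z^{(j)}} in rad/µs.  Only
#' the secular part of the dipolar coupling is kept (valid when dipolar
#' frequencies are small against the spectral width), and the electron
#' Zeeman terms are omitted because they refocus at the echo positions.
#' H is diagonal in the product basis, so all coupling terms commute and
#' free evolution can be applied exactly by phase factors.
#'
#' @param system a [spin_system()].
#' @param diagonal if `TRUE` (default) return the diagonal as a numeric
#'   vector, else the full matrix.
#' @export
secular_hamiltonian <- function(system, diagonal = TRUE) {
  stopifnot(inherits(system, "spin_system"))
  n <- system$n_spins
  d <- numeric(2^n)
  cpl <- system$couplings
  for (row in seq_len(nrow(cpl)))
    d <- d + cpl$omega[row] * sz_diag(n, cpl$i[row]) * sz_diag(n, cpl$j[row])
  if (diagonal) d else diag(d) + 0i
}

#' Ideal (infinitely short, infinite bandwidth) global pulse
#'
#' Returns the unitary \eqn{U = \exp(-i\,\phi \sum_k S_a^{(k)})} rotating
#' every spin by flip angle `flip` about the given phase axis.  Because
#' single-spin rotations commute across spins, U is the n-fold Kronecker
#' power of the one-spin rotation
#' \eqn{\cos(\phi/2) - 2 i \sin(\phi/2) S_a}.
#'
#' @param n_spins number of spins.
#' @param flip flip angle in rad, in (0, 2*pi].
#' @param phase one of `"x"`, `"y"`, `"-x"`, `"-y"`.
#' @return complex unitary matrix of dimension 2^n.
#' @export
ideal_pulse <- function(n_spins, flip, phase = "x") {
  stopifnot(flip > 0, flip <= 2 * pi)
  sgn <- 1
  ax <- phase
  if (phase %in% c("-x", "-y")) { sgn <- -1; ax <- substring(phase, 2) }
  if (!ax %in% c("x", "y")) stop("unsupported phase axis: ", phase)
  s <- .half_ops[[ax]] * sgn
  u1 <- cos(flip / 2) * diag(2) - 2i * sin(flip / 2) * s
  out <- u1
  for (k in seq_len(n_spins - 1L)) out <- kronecker(out, u1)
  out
}
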