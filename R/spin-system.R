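#' Define a network of coupled spin-1/2 centres
#'
#' A `spin_system` holds the number of electron spins and the list of
#' secular dipolar couplings between them.  Spin 1 is by convention the
#' detected A spin and occupies the slowest-varying tensor factor of the
#' product basis.  Angular frequencies are in rad/µs throughout.
#'
#' @param n_spins number of spin-1/2 centres (1 to 10; dense matrices of
#'   dimension 2^n are refused above that).
#' @param couplings data frame or matrix with columns `i`, `j`, `omega`
#'   giving the coupling \eqn{\omega_{ij}} (rad/µs) between spins `i < j`
#'   (1-based indices).  May be `NULL` for an uncoupled system.
#' @return an object of class `spin_system`.
#' @export
#' @examples
#' spin_system(2, data.frame(i = 1, j = 2, omega = 2 * pi * 5))
spin_system <- function(n_spins, couplings = NULL) {
  stopifnot(length(n_spins) == 1L, n_spins == round(n_spins), n_spins >= 1)
  if (n_spins > 10)
    stop("refusing n_spins > 10 (density matrix dimension 2^n)")
  if (is.null(couplings)) {
    couplings <- data.frame(i = integer(), j = integer(), omega = numeric())
  } else {
    couplings <- as.data.frame(couplings)
    names(couplings) <- c("i", "j", "omega")
    with(couplings, {
      if (any(i < 1 | i > n_spins | j < 1 | j > n_spins))
        stop("coupling index out of range")
      if (any(i >= j)) stop("couplings must have i < j")
      if (!all(is.finite(omega))) stop("coupling frequencies must be finite")
    })
    if (anyDuplicated(couplings[c("i", "j")]))
      stop("duplicate coupling pair")
  }
  structure(list(n_spins = as.integer(n_spins), couplings = couplings),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("spin_system: %d spin(s), %d coupling(s)\n",
              x$n_spins, nrow(x$couplings)))
  if (nrow(x$couplings)) {
    cpl <- x$couplings
    cpl$MHz <- cpl$omega / (2 * pi)
    print(cpl, row.names = FALSE)
  }
  invisible(x)
}
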