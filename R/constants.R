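## Physical constants (CODATA 2018) used to derive the dipolar coupling
## constant.  Units are chosen so that distances are in nm, times in µs,
## angular frequencies in rad/µs and linear frequencies in MHz.

.mu0     <- 1.25663706212e-6   # vacuum permeability, N A^-2
.muB     <- 9.2740100783e-24   # Bohr magneton, J T^-1
.planck  <- 6.62607015e-34     # Planck constant, J s
.g_free  <- 2.0023             # electron g value used for both spins

#' Electron-electron dipolar coupling constant
#'
#' Returns the point-dipole coupling constant
#' \eqn{C_{dd} = \mu_0 g^2 \mu_B^2 / (4 \pi h)} expressed in MHz nm^3, so
#' that the perpendicular-orientation dipolar frequency of a spin pair at
#' distance \eqn{r} (nm) is \eqn{\nu_\perp = C_{dd}/r^3} MHz.  For free
#' electron g values this evaluates to about 52.04 MHz nm^3.
#'
#' @param g electron g value applied to both spins.
#' @return coupling constant in MHz nm^3.
#' @export
#' @examples
#' dipolar_constant()          # ~52.04
#' dipolar_constant() / 2^3    # ~6.5 MHz at r = 2 nm
dipolar_constant <- function(g = .g_free) {
  (.mu0 / (4 * pi)) * (g * .muB)^2 / .planck * 1e27 * 1e-6
}

## Spins per nm^3 for a 1 micromolar solution.
.uM_to_nm3 <- 6.02214076e-7

#' Convert a concentration in micromolar to spins per cubic nanometre
#'
#' 1 µM corresponds to 6.022e-7 spins/nm^3.
#'
#' @param uM concentration in µM.
#' @return number density in spins/nm^3.
#' @export
concentration_uM_to_nm3 <- function(uM) {
  stopifnot(is.numeric(uM), all(uM >= 0))
  uM * .uM_to_nm3
}

## Run an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.  All stochastic code in the
## package funnels through this helper so that seeds behave as a pure
## function argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}
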