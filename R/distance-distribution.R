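#' Distance distributions for spin pairs
#'
#' A `distance_distribution` describes the intramolecular spin-spin distance
#' density P(r) (in 1/nm, r in nm) over which dipolar signals are averaged.
#' Two representations are supported: a parametric Gaussian (`mean`, `sd`)
#' truncated at r > 0, and a tabulated density on an r grid, interpolated
#' linearly and integrated by the trapezoidal rule.
#'
#' @param mean mean distance in nm (Gaussian form).
#' @param sd standard deviation in nm (Gaussian form).
#' @param r grid of distances in nm (tabulated form), strictly increasing.
#' @param density non-negative density values on `r`; renormalised to
#'   integrate to 1.
#' @return an object of class `distance_distribution`.
#' @export
#' @examples
#' gaussian_distribution(3, 0.2)
#' tabulated_distribution(seq(2, 4, 0.01), dnorm(seq(2, 4, 0.01), 3, 0.2))
gaussian_distribution <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, mean > 0,
            is.numeric(sd), length(sd) == 1L, sd > 0)
  structure(list(type = "gaussian", mean = mean, sd = sd),
            class = "distance_distribution")
}

#' @rdname gaussian_distribution
#' @export
tabulated_distribution <- function(r, density) {
  stopifnot(is.numeric(r), is.numeric(density), length(r) == length(density),
            length(r) >= 2L, all(is.finite(r)), all(is.finite(density)))
  if (any(diff(r) <= 0)) stop("distance grid must be strictly increasing")
  if (any(density < 0)) stop("density must be non-negative")
  if (r[1] <= 0) stop("distance support must be positive")
  z <- pracma::trapz(r, density)
  if (z <= 0) stop("density integrates to zero")
  structure(list(type = "tabulated", r = r, density = density / z),
            class = "distance_distribution")
}

#' Single-distance (delta) distribution
#'
#' Convenience constructor for a spin pair at one fixed distance.
#'
#' @param r distance in nm.
#' @export
delta_distribution <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0)
  structure(list(type = "delta", r = r), class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  switch(x$type,
    gaussian = cat(sprintf(
      "Gaussian distance distribution: mean %.3f nm, sd %.3f nm\n",
      x$mean, x$sd)),
    delta = cat(sprintf("Delta distance distribution at %.3f nm\n", x$r)),
    tabulated = cat(sprintf(
      "Tabulated distance distribution on [%.3f, %.3f] nm (%d points)\n",
      min(x$r), max(x$r), length(x$r))))
  invisible(x)
}

#' Read a tabulated distance distribution from a two-column ASCII file
#'
#' The file holds distance (nm) and density (1/nm) columns; lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @export
read_distance_distribution <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("r", "density"))
  tabulated_distribution(tab$r, tab$density)
}

## Quadrature nodes and normalised weights in r for any distribution.
## Gaussian distributions are discretised on mean +- 5 sd (truncated at
## r > 0); tabulated ones use their own grid with trapezoidal weights.
dd_nodes <- function(dist, n_r = 101L) {
  switch(dist$type,
    delta = list(r = dist$r, w = 1),
    gaussian = {
      lo <- max(dist$mean - 5 * dist$sd, 1e-3)
      hi <- dist$mean + 5 * dist$sd
      r <- seq(lo, hi, length.out = n_r)
      w <- stats::dnorm(r, dist$mean, dist$sd)
      ## trapezoid end-point halving
      tw <- c(diff(r)[1] / 2, (r[-1:-2] - r[1:(n_r - 2)]) / 2, diff(r)[n_r - 1] / 2)
      w <- w * tw
      list(r = r, w = w / sum(w))
    },
    tabulated = {
      r <- dist$r
      n <- length(r)
      tw <- c(diff(r)[1] / 2, (r[-1:-2] - r[1:(n - 2)]) / 2, diff(r)[n - 1] / 2)
      w <- dist$density * tw
      list(r = r, w = w / sum(w))
    })
}

## Draw m distances from the distribution (used when placing biradical
## partner spins in the Monte Carlo ensemble).
dd_sample <- function(dist, m) {
  switch(dist$type,
    delta = rep(dist$r, m),
    gaussian = {
      x <- stats::rnorm(m, dist$mean, dist$sd)
      while (any(bad <- x <= 0))
        x[bad] <- stats::rnorm(sum(bad), dist$mean, dist$sd)
      x
    },
    tabulated = {
      nodes <- dd_nodes(dist)
      sample(nodes$r, m, replace = TRUE, prob = nodes$w)
    })
}
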