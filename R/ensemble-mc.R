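#' Settings for the Monte-Carlo radical ensemble
#'
#' Configures grand-canonical sampling of a uniform random distribution of
#' mono- or biradicals around a central A spin.  Spin counts are
#' Poisson-drawn with mean `concentration x volume`; positions are uniform
#' in a sphere centred on the A spin with an excluded contact distance
#' `r_min`.  The sphere radius defaults to the larger of (i) the radius at
#' which truncating more distant spins changes the two-pulse background by
#' less than 0.1 % at `tau_max` and (ii) five mean nearest-neighbour
#' distances.
#'
#' @param concentration_uM spin concentration in µM.
#' @param r_min excluded contact distance in nm (> 0); the summed second
#'   moment diverges as r_min -> 0, and the weak-transfer linearisation
#'   fails for close pairs, so 1.5 nm (a physical contact distance for
#'   nitroxide/trityl radicals) is the default.
#' @param n_realizations number of Monte-Carlo realizations (>= 100).
#' @param seed integer master seed.
#' @param mode `"mono"` or `"bi"`.
#' @param box_radius sphere radius in nm, `NULL` for automatic.
#' @param tau_max largest delay (µs) the settings must support; enters the
#'   automatic radius rule.
#' @return an object of class `mc_settings`.
#' @export
mc_settings <- function(concentration_uM, r_min = 1.5,
                        n_realizations = 1000L, seed = 1L,
                        mode = c("mono", "bi"), box_radius = NULL,
                        tau_max = 5) {
  mode <- match.arg(mode)
  stopifnot(concentration_uM > 0, r_min > 0, n_realizations >= 100,
            tau_max > 0)
  C <- concentration_uM_to_nm3(concentration_uM)
  nn <- 0.554 / C^(1 / 3)          # mean nearest-neighbour distance, Poisson
  r_trunc <- (C * (2 * pi * dipolar_constant())^2 * (8 * pi / 15) *
                tau_max^2 / 1e-3)^(1 / 3)
  auto <- max(5 * nn, r_trunc)
  if (is.null(box_radius)) box_radius <- auto
  if (box_radius < 5 * nn)
    stop(sprintf("box radius %.1f nm below 5 mean nearest-neighbour distances (%.1f nm)",
                 box_radius, 5 * nn))
  structure(list(concentration_uM = concentration_uM, C = C,
                 r_min = r_min, n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed), mode = mode,
                 box_radius = box_radius, tau_max = tau_max),
            class = "mc_settings")
}

#' @export
print.mc_settings <- function(x, ...) {
  cat(sprintf(paste0("mc_settings: %.4g µM (%s), r_min %.2f nm, ",
                     "R %.1f nm, %d realizations, seed %d\n"),
              x$concentration_uM, x$mode, x$r_min, x$box_radius,
              x$n_realizations, x$seed))
  invisible(x)
}

## Uniform points in a sphere of radius R, excluding r < r_min from the
## origin; violating points are resampled (capped).
.sample_sphere <- function(n, R, r_min, max_retry = 1000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  draw <- function(m) {
    r <- R * stats::runif(m)^(1 / 3)
    u <- stats::runif(m, -1, 1)
    phi <- stats::runif(m, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    cbind(r * s * cos(phi), r * s * sin(phi), r * u)
  }
  pts <- draw(n)
  for (k in seq_len(max_retry)) {
    bad <- sqrt(rowSums(pts^2)) < r_min
    if (!any(bad)) return(pts)
    pts[bad, ] <- draw(sum(bad))
  }
  stop("could not satisfy r_min exclusion after capped retries")
}

#' Sample one radical configuration
#'
#' Places the A spin at the origin and Poisson-many surrounding B spins
#' uniformly in the sampling sphere.  In `"bi"` mode the surrounding spins
#' are grouped into biradical molecules whose partner offsets are drawn
#' from `dist` with isotropic orientation, and the A spin gets its own
#' intramolecular partner.  All A-B dipolar frequencies \eqn{\omega_l} are
#' computed from the actual geometry (field along z).
#'
#' @param settings an [mc_settings()].
#' @param dist partner [distance_distribution][gaussian_distribution]
#'   (required in `"bi"` mode).
#' @param seed seed for this draw; defaults to `settings$seed`.  Pass
#'   `NULL` to draw from the current RNG stream (used internally when a
#'   caller manages the stream itself).
#' @return list with `positions` (n x 3 matrix of B-spin positions, nm),
#'   `omega_l` (A to each B, rad/µs), `molecule` (molecule index per B
#'   spin), and in bi mode `partner0` (A's partner position) and `omega0`.
#' @export
sample_configuration <- function(settings, dist = NULL, seed = settings$seed) {
  stopifnot(inherits(settings, "mc_settings"))
  if (settings$mode == "bi" && is.null(dist))
    stop("bi mode requires a partner distance distribution")
  with_seed(seed, {
    R <- settings$box_radius
    V <- 4 / 3 * pi * R^3
    if (settings$mode == "mono") {
      n <- stats::rpois(1, settings$C * V)
      pos <- .sample_sphere(n, R, settings$r_min)
      mol <- seq_len(n)
      partner0 <- NULL; omega0 <- NA_real_
    } else {
      n_mol <- stats::rpois(1, settings$C * V / 2)
      first <- .sample_sphere(n_mol, R, settings$r_min)
      rpart <- dd_sample(dist, n_mol)
      u <- stats::runif(n_mol, -1, 1)
      phi <- stats::runif(n_mol, 0, 2 * pi)
      s <- sqrt(1 - u^2)
      off <- cbind(rpart * s * cos(phi), rpart * s * sin(phi), rpart * u)
      pos <- rbind(first, first + off)
      mol <- rep(seq_len(n_mol), 2)
      ## enforce contact exclusion from A for partner spins too
      d <- sqrt(rowSums(pos^2))
      keep <- d >= settings$r_min
      pos <- pos[keep, , drop = FALSE]; mol <- mol[keep]
      ## A's own partner
      r0 <- dd_sample(dist, 1)
      u0 <- stats::runif(1, -1, 1); p0 <- stats::runif(1, 0, 2 * pi)
      partner0 <- r0 * c(sqrt(1 - u0^2) * cos(p0), sqrt(1 - u0^2) * sin(p0), u0)
      omega0 <- dipolar_frequency_u(r0, u0)
    }
    d <- sqrt(rowSums(pos^2))
    omega_l <- if (nrow(pos)) dipolar_frequency_u(d, pos[, 3] / d) else numeric(0)
    list(positions = pos, omega_l = omega_l, molecule = mol,
         partner0 = partner0, omega0 = omega0)
  })
}

## Pairwise dipolar frequencies from spin `from` (row of positions or the
## origin) to a set of positions.
.freqs_from <- function(origin, pos) {
  if (nrow(pos) == 0L) return(numeric(0))
  dv <- sweep(pos, 2, origin)
  d <- sqrt(rowSums(dv^2))
  dipolar_frequency_u(d, dv[, 3] / d)
}

#' Monte-Carlo two-pulse intermolecular background B2p
#'
#' Estimates \eqn{B_{2p}(\tau) = \langle \prod_l \cos(\omega_l \tau)
#' \rangle} over Poisson realizations of the surrounding spin ensemble.
#' For a homogeneous spatial distribution this converges to the
#' mono-exponential DEER-type background.
#'
#' @param settings an [mc_settings()] (mono mode).
#' @param tau_grid delays in µs (>= 2 points).
#' @return data frame with `tau`, `B2p` and the standard error `se`.
#' @export
b2p_curve <- function(settings, tau_grid) {
  stopifnot(length(tau_grid) >= 2)
  n <- settings$n_realizations
  acc <- matrix(NA_real_, n, length(tau_grid))
  with_seed(settings$seed, {
    R <- settings$box_radius
    V <- 4 / 3 * pi * R^3
    for (k in seq_len(n)) {
      m <- stats::rpois(1, settings$C * V)
      pos <- .sample_sphere(m, R, settings$r_min)
      d <- sqrt(rowSums(pos^2))
      om <- if (m) dipolar_frequency_u(d, pos[, 3] / d) else numeric(0)
      acc[k, ] <- if (m) apply(cos(outer(om, tau_grid)), 2, prod) else 1
    }
  })
  data.frame(tau = tau_grid,
             B2p = colMeans(acc),
             se = apply(acc, 2, stats::sd) / sqrt(n))
}

#' Monte-Carlo summed second moment of intermolecular dipolar frequencies
#'
#' Estimates \eqn{D = \langle \sum_l \omega_l^2 \rangle}, the summed
#' squared intermolecular dipolar frequency per A spin, which sets the
#' amplitude of the coherence-transfer parabola \eqn{D\tau_1\tau_2}.  The
#' integral diverges as `r_min -> 0`, so the estimate is only meaningful
#' together with its contact cutoff, which is echoed in the output.
#'
#' @param settings an [mc_settings()].
#' @return list with `D` (rad^2/µs^2), `se`, `r_min`,
#'   `definition = "sum-over-B-spins"`.
#' @export
second_moment <- function(settings) {
  if (settings$r_min <= 0) stop("second moment diverges for r_min = 0")
  n <- settings$n_realizations
  vals <- numeric(n)
  with_seed(settings$seed, {
    R <- settings$box_radius
    V <- 4 / 3 * pi * R^3
    for (k in seq_len(n)) {
      m <- stats::rpois(1, settings$C * V)
      pos <- .sample_sphere(m, R, settings$r_min)
      d <- sqrt(rowSums(pos^2))
      vals[k] <- if (m) sum(dipolar_frequency_u(d, pos[, 3] / d)^2) else 0
    }
  })
  list(D = mean(vals), se = stats::sd(vals) / sqrt(n),
       r_min = settings$r_min, definition = "sum-over-B-spins")
}

#' Monte-Carlo test of the background factorization assumption
#'
#' The signal theory assumes that the cosine product over the A spin's
#' surroundings at \eqn{\tau_1} and the product over the transfer
#' partner's surroundings at \eqn{\tau_2} average independently.  This
#' routine measures both sides: per realization a transfer partner B_n is
#' drawn with probability proportional to \eqn{\omega_n^2} (the transfer
#' weight), its surrounding frequencies \eqn{\tilde\omega_{n,m}} (to all
#' other B spins and to A) are computed from the geometry, and the joint
#' and factorized averages are accumulated.
#'
#' @param settings an [mc_settings()].
#' @param tau1,tau2 delays in µs.
#' @param dist partner distribution for bi mode.
#' @return list with `joint`, `factorized`, their standard errors,
#'   `discrepancy` (joint - factorized), `rel_discrepancy` and
#'   `discrepancy_se`.
#' @export
factorization_check <- function(settings, tau1, tau2, dist = NULL) {
  n <- settings$n_realizations
  joint <- m1 <- m2 <- rep(NA_real_, n)
  with_seed(settings$seed, {
    for (k in seq_len(n)) {
      cfg <- sample_configuration(settings, dist = dist, seed = NULL)
      om <- cfg$omega_l
      if (length(om) < 2) { joint[k] <- m1[k] <- m2[k] <- NA; next }
      wk <- om^2
      nsel <- sample.int(length(om), 1, prob = wk)
      ## surroundings of the selected B spin: all other B spins plus A
      others <- cfg$positions[-nsel, , drop = FALSE]
      om_t <- c(.freqs_from(cfg$positions[nsel, ], others),
                cfg$omega_l[nsel])          # coupling back to A at origin
      p1 <- prod(cos(om * tau1))
      p2 <- prod(cos(om_t * tau2))
      joint[k] <- p1 * p2
      m1[k] <- p1
      m2[k] <- p2
    }
  })
  ok <- is.finite(joint)
  joint <- joint[ok]; m1 <- m1[ok]; m2 <- m2[ok]
  jm <- mean(joint); f1 <- mean(m1); f2 <- mean(m2)
  fact <- f1 * f2
  ## delta-method error for the factorized product + direct error for joint
  se_j <- stats::sd(joint) / sqrt(length(joint))
  se_f <- sqrt((f2 * stats::sd(m1) / sqrt(length(m1)))^2 +
               (f1 * stats::sd(m2) / sqrt(length(m2)))^2)
  disc <- jm - fact
  list(joint = jm, factorized = fact,
       joint_se = se_j, factorized_se = se_f,
       discrepancy = disc,
       discrepancy_se = sqrt(se_j^2 + se_f^2),
       rel_discrepancy = disc / max(abs(fact), 1e-12),
       n_used = length(joint))
}

#' Power-law exponent of the second moment versus concentration
#'
#' Runs [second_moment()] at each concentration and fits a log-log power
#' law \eqn{D \propto C^p}.  The exponent is reported with a confidence
#' interval and not asserted against any expectation: with a fixed contact
#' cutoff the summed second moment is cutoff-dominated and scales linearly
#' in concentration, while the artefact-versus-concentration argument in
#' the signal theory anticipates quadratic scaling of the artefact term
#' (one factor of C from D, one from the transfer-partner density).
#'
#' @param settings an [mc_settings()]; its concentration is replaced by
#'   each element of `concentrations_uM`.
#' @param concentrations_uM at least 4 concentrations spanning a decade.
#' @return list with `exponent`, `ci` (95 %), `fit` (the lm object) and
#'   the per-concentration table.
#' @export
artefact_scaling_scan <- function(settings, concentrations_uM) {
  stopifnot(length(concentrations_uM) >= 4)
  if (max(concentrations_uM) / min(concentrations_uM) < 10)
    stop("concentrations must span at least one decade")
  tab <- do.call(rbind, lapply(seq_along(concentrations_uM), function(i) {
    s <- mc_settings(concentrations_uM[i], r_min = settings$r_min,
                     n_realizations = settings$n_realizations,
                     seed = settings$seed + i, mode = settings$mode,
                     tau_max = settings$tau_max)
    sm <- second_moment(s)
    data.frame(concentration_uM = concentrations_uM[i], D = sm$D, se = sm$se)
  }))
  fit <- stats::lm(log(D) ~ log(concentration_uM), data = tab)
  ci <- stats::confint(fit)["log(concentration_uM)", ]
  list(exponent = unname(stats::coef(fit)[2]), ci = unname(ci),
       fit = fit, table = tab)
}

#' Fit a power-law exponent to (x, y) pairs
#'
#' Utility used by [artefact_scaling_scan()] and its self-tests: ordinary
#' least squares of log y on log x.
#'
#' @param x,y positive numeric vectors.
#' @return list with `exponent` and 95 % `ci`.
#' @export
fit_power_law <- function(x, y) {
  stopifnot(all(x > 0), all(y > 0))
  fit <- stats::lm(log(y) ~ log(x))
  list(exponent = unname(stats::coef(fit)[2]),
       ci = unname(stats::confint(fit)[2, ]))
}
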