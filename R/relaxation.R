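#' Phenomenological relaxation model for SIFTER background work
#'
#' Collects the parameters of the two decay factors that enter the SIFTER
#' signal composition:
#'
#' * the two-pulse (Hahn) decay
#'   \eqn{B_t(\tau) = \sum_i w_i \exp(-(2\tau/\tau_{d,i})^{\beta_i})},
#'   a sum of stretched exponentials (SSE) in the echo time \eqn{2\tau};
#' * the SIDRE surface
#'   \eqn{B_S(\tau_1,\tau_2) = \sum_i w_i \exp\{-[(2\tau_1)^{\xi} +
#'   (2\tau_2)^{\xi}]^{\beta_i/\xi} / \tau_{d,i}^{\beta_i}\}},
#'   a generalized-power-mean stretched exponential whose single extra
#'   exponent \eqn{\xi \ge \max(\beta, 1)} controls the strength of
#'   dynamical decoupling.  By construction it equals \eqn{B_t} on the
#'   boundary (\eqn{\tau_1 = 0} or \eqn{\tau_2 = 0}), reduces to the
#'   product \eqn{B_t(\tau_1)B_t(\tau_2)} component-wise when
#'   \eqn{\xi = \beta}, and attains its maximum along a fixed-\eqn{\tau_0}
#'   trace at \eqn{\tau_1 = \tau_2} for \eqn{\xi > 1}.
#'
#' @param tau_d component time constants in µs (> 0).
#' @param beta stretch exponents in (0, 4].
#' @param weights non-negative component weights, normalised to sum to 1.
#' @param xi decoupling shape exponent, `xi >= max(beta, 1)`; `xi = beta`
#'   switches decoupling off.
#' @return an object of class `relaxation_model`.
#' @export
#' @examples
#' m <- relaxation_model(tau_d = 4, beta = 1.3, xi = 2)
#' evaluate_bt(m, 1)
#' evaluate_bs(m, 1, 1) >= evaluate_bt(m, 1)^2   # dynamical decoupling
relaxation_model <- function(tau_d, beta, weights = NULL, xi = max(beta, 1)) {
  k <- length(tau_d)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(beta) == k, length(weights) == k,
            all(tau_d > 0), all(beta > 0), all(beta <= 4),
            all(weights >= 0), sum(weights) > 0,
            length(xi) == 1L)
  if (xi < max(beta))
    stop("xi < beta would violate the decoupling inequality BS >= Bt*Bt")
  if (xi < 1)
    stop("xi must be >= 1 so the SIDRE surface peaks at tau1 = tau2")
  structure(list(weights = weights / sum(weights), tau_d = tau_d,
                 beta = beta, xi = xi),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat(sprintf("relaxation_model: %d SSE component(s), xi = %.3f\n",
              length(x$tau_d), x$xi))
  print(data.frame(weight = x$weights, tau_d_us = x$tau_d, beta = x$beta),
        row.names = FALSE)
  invisible(x)
}

#' Two-pulse (Hahn) echo decay Bt
#'
#' @param model a [relaxation_model()].
#' @param tau inter-pulse delay in µs (echo time is 2*tau), vectorised.
#' @return values in (0, 1]; Bt(0) = 1.
#' @export
evaluate_bt <- function(model, tau) {
  stopifnot(all(tau >= 0))
  out <- 0
  for (i in seq_along(model$tau_d))
    out <- out + model$weights[i] *
      exp(-(2 * tau / model$tau_d[i])^model$beta[i])
  out
}

#' SIDRE surface BS(tau1, tau2)
#'
#' @inheritParams evaluate_bt
#' @param tau1,tau2 delays in µs, vectorised (recycled to a common length).
#' @export
evaluate_bs <- function(model, tau1, tau2) {
  stopifnot(all(tau1 >= 0), all(tau2 >= 0))
  xi <- model$xi
  g <- ((2 * tau1)^xi + (2 * tau2)^xi)
  out <- 0
  for (i in seq_along(model$tau_d))
    out <- out + model$weights[i] *
      exp(-g^(model$beta[i] / xi) / model$tau_d[i]^model$beta[i])
  out
}

#' Division trace Bt(tau1) Bt(tau2) / BS(tau1, tau2)
#'
#' The shape comparison used to diagnose transverse-evolution filtering: 1
#' at the trace ends (t = +-tau0) where one delay vanishes, minimal at
#' t = 0 where dynamical decoupling makes BS exceed the Hahn product.
#'
#' @inheritParams evaluate_bt
#' @param tau0 half total evolution time, µs.
#' @param t_grid SIFTER time grid in µs, |t| <= tau0.
#' @export
ratio_surface <- function(model, tau0, t_grid) {
  if (any(abs(t_grid) > tau0 + 1e-12)) stop("t grid outside [-tau0, tau0]")
  tau1 <- (tau0 + t_grid) / 2
  tau2 <- (tau0 - t_grid) / 2
  evaluate_bt(model, tau1) * evaluate_bt(model, tau2) /
    evaluate_bs(model, tau1, tau2)
}

## Build the nls model expression for an n-component SSE in echo time x.
.sse_formula <- function(n) {
  terms <- vapply(seq_len(n), function(i)
    sprintf("a%d * exp(-(x / td%d)^b%d)", i, i, i), character(1))
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Fit a sum of stretched exponentials to an echo decay
#'
#' Fits \eqn{y(x) = \sum_i a_i \exp(-(x/\tau_{d,i})^{\beta_i})} to a
#' two-pulse decay trace recorded against echo time x = 2*tau, by
#' Levenberg-Marquardt least squares with a fixed, deterministic grid of
#' starting values (SSE fits are multimodal).  Component amplitudes are
#' constrained non-negative; the result is reported as normalised weights
#' plus an overall amplitude, directly usable in [relaxation_model()].
#'
#' @param trace a [dipolar_trace()] with the echo-time axis in µs, or a
#'   numeric vector of amplitudes (then `x` must be given).
#' @param n_components number of SSE components, 1 to 3.
#' @param x echo-time axis when `trace` is a bare vector.
#' @param xi decoupling exponent attached to the returned model (not
#'   fitted; the Hahn decay carries no information on it).
#' @return object of class `decay_fit` with elements `model`
#'   ([relaxation_model()]), `amplitude`, `fitted`, `residuals`, `rss`,
#'   `converged`, `degenerate` and the parameter covariance `cov`.
#' @export
fit_decay <- function(trace, n_components = 1L, x = NULL, xi = NULL) {
  if (inherits(trace, "dipolar_trace")) {
    y <- trace$amplitude
    x <- trace$t
  } else y <- as.numeric(trace)
  stopifnot(!is.null(x), length(x) == length(y),
            n_components %in% 1:3)
  if (any(y <= 0)) stop("decay amplitudes must be positive")
  keep <- is.finite(x) & is.finite(y) & x >= 0
  x <- x[keep]; y <- y[keep]
  xmax <- max(x[x > 0])
  n <- as.integer(n_components)

  ## deterministic multi-start grid in the dominant time constant / stretch;
  ## the far start lets non-decaying traces reach the degenerate flat fit
  td_starts <- xmax * c(0.25, 0.6, 1.2, 3, 500)
  b_starts <- c(0.8, 1.2, 2)
  frm <- .sse_formula(n)

  best <- NULL
  for (td0 in td_starts) for (b0 in b_starts) {
    start <- list()
    for (i in seq_len(n)) {
      start[[paste0("a", i)]] <- max(y) / n
      start[[paste0("td", i)]] <- td0 * 2^(i - 1)
      start[[paste0("b", i)]] <- b0
    }
    lower <- unlist(lapply(seq_len(n), function(i)
      stats::setNames(c(0, xmax * 1e-3, 0.2), paste0(c("a", "td", "b"), i))))
    upper <- unlist(lapply(seq_len(n), function(i)
      stats::setNames(c(Inf, xmax * 1e3, 4), paste0(c("a", "td", "b"), i))))
    fit <- tryCatch(
      minpack.lm::nlsLM(frm, data = data.frame(x = x, y = y),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-14 * sum(y^2))
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("SSE fit failed from every start")

  cf <- stats::coef(best$fit)
  a <- cf[paste0("a", seq_len(n))]
  td <- cf[paste0("td", seq_len(n))]
  b <- cf[paste0("b", seq_len(n))]
  ord <- order(td)
  a <- a[ord]; td <- td[ord]; b <- b[ord]
  amp <- sum(a)
  fitted_vals <- stats::fitted(best$fit)
  ## degenerate: effectively no decay on the measured window (tau_d beyond
  ## the data, or a flat fitted curve)
  degenerate <- any(td > 100 * xmax) || amp <= 0 ||
    (max(fitted_vals) - min(fitted_vals)) < 1e-3 * max(abs(fitted_vals))
  ## drop zero-weight components defensively
  w <- if (amp > 0) a / amp else rep(1 / n, n)
  ## Bt is parameterised in tau with echo time 2*tau in the exponent, so
  ## the echo-time constants map over unchanged.
  model <- relaxation_model(tau_d = pmax(td, 1e-12), beta = pmin(pmax(b, 1e-6), 4),
                            weights = w,
                            xi = if (is.null(xi)) max(b, 1) else xi)
  covm <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  structure(list(model = model, amplitude = amp,
                 fitted = stats::fitted(best$fit),
                 residuals = stats::resid(best$fit),
                 rss = best$rss, x = x, y = y,
                 converged = best$fit$convInfo$isConv %||% TRUE,
                 degenerate = degenerate, cov = covm,
                 n_components = n),
            class = "decay_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("SSE decay fit: %d component(s), amplitude %.4g, RSS %.3g%s\n",
              x$n_components, x$amplitude, x$rss,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$model)
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  m <- object$model
  c(amplitude = object$amplitude,
    stats::setNames(m$weights, paste0("w", seq_along(m$weights))),
    stats::setNames(m$tau_d, paste0("tau_d", seq_along(m$tau_d))),
    stats::setNames(m$beta, paste0("beta", seq_along(m$beta))))
}

#' @export
predict.decay_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) x <- object$x
  object$amplitude * evaluate_bt(object$model, x / 2)
}

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.5,
                 xlab = "echo time 2τ (µs)", ylab = "amplitude", ...)
  graphics::lines(x$x, x$fitted, col = "red3", lwd = 2)
  invisible(x)
}

#' Fit the decoupling exponent xi to a SIDRE trace
#'
#' Given Hahn-decay SSE parameters, fits the single SIDRE shape exponent
#' xi (and an amplitude) to a measured SIDRE trace at fixed tau0 by
#' Levenberg-Marquardt least squares.
#'
#' @param sidre a [dipolar_trace()] from a SIDRE measurement.
#' @param bt_model [relaxation_model()] (or [decay_fit()]) holding the SSE
#'   parameters of the Hahn decay.
#' @return list with `xi`, `amplitude`, `model` (the completed
#'   [relaxation_model()]), `rss`.
#' @export
fit_sidre_xi <- function(sidre, bt_model) {
  if (inherits(bt_model, "decay_fit")) bt_model <- bt_model$model
  stopifnot(inherits(sidre, "dipolar_trace"))
  tau0 <- sidre$tau0
  tau1 <- (tau0 + sidre$t) / 2
  tau2 <- (tau0 - sidre$t) / 2
  y <- sidre$amplitude
  bs_xi <- function(xi, A) {
    m <- bt_model; m$xi <- xi
    A * evaluate_bs(m, tau1, tau2)
  }
  xi_lo <- max(max(bt_model$beta), 1)
  fit <- minpack.lm::nlsLM(y ~ bs_xi(xi, A),
                           start = list(xi = xi_lo + 0.5, A = max(y)),
                           lower = c(xi = xi_lo, A = 0),
                           upper = c(xi = 8, A = Inf))
  cf <- stats::coef(fit)
  m <- bt_model; m$xi <- unname(cf["xi"])
  list(xi = unname(cf["xi"]), amplitude = unname(cf["A"]),
       model = m, rss = sum(stats::resid(fit)^2))
}
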