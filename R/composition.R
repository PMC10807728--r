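#' Dipolar time trace container
#'
#' Holds a signal sampled against the SIFTER time \eqn{t = \tau_1 - \tau_2}
#' (or the echo time for Hahn decays) plus the metadata needed to re-run
#' any analysis step: `tau0`, the sequence name, seeds and model
#' provenance.  Per-term breakdowns from the composition functions are kept
#' in `meta$breakdown` for introspection.
#'
#' @param t time grid in µs, strictly increasing.
#' @param amplitude signal values (finite).
#' @param tau0 half total transverse evolution time, µs (may be `NA` for
#'   Hahn decays).
#' @param sequence sequence name, e.g. `"sifter"`, `"sidre"`, `"hahn"`.
#' @param meta named list of additional metadata.
#' @export
dipolar_trace <- function(t, amplitude, tau0 = NA_real_,
                          sequence = "sifter", meta = list()) {
  stopifnot(is.numeric(t), is.numeric(amplitude),
            length(t) == length(amplitude), length(t) >= 1L)
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  if (!all(is.finite(amplitude) | is.na(amplitude)))
    stop("amplitudes must be finite (or NA for masked points)")
  if (is.finite(tau0) && any(abs(t) > tau0 + 1e-9) &&
      sequence %in% c("sifter", "sidre"))
    stop("|t| exceeds tau0")
  structure(list(t = t, amplitude = amplitude, tau0 = tau0,
                 sequence = sequence, meta = meta),
            class = "dipolar_trace")
}

#' @export
print.dipolar_trace <- function(x, ...) {
  cat(sprintf("dipolar_trace [%s]: %d points, t in [%.4g, %.4g] µs%s\n",
              x$sequence, length(x$t), min(x$t), max(x$t),
              if (is.finite(x$tau0)) sprintf(", tau0 = %.4g µs", x$tau0) else ""))
  keys <- setdiff(names(x$meta), "breakdown")
  if (length(keys))
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dipolar_trace <- function(x, ...) {
  graphics::plot(x$t, x$amplitude, type = "l",
                 xlab = "t (µs)", ylab = "signal",
                 main = x$sequence, ...)
  invisible(x)
}

## tau1/tau2 from the symmetric SIFTER time convention.
tau_split <- function(tau0, t_grid) {
  if (any(abs(t_grid) > tau0 + 1e-12)) stop("t grid outside [-tau0, tau0]")
  list(tau1 = (tau0 + t_grid) / 2, tau2 = (tau0 - t_grid) / 2)
}

#' Intermolecular coherence-transfer factor D tau1 tau2
#'
#' \eqn{D\tau_1\tau_2 = \tfrac{D}{4}(\tau_0^2 - t^2)}: an inverted
#' parabola, zero at the trace ends (\eqn{\tau_1 = 0} or \eqn{\tau_2 = 0})
#' and maximal (\eqn{D\tau_0^2/4}) at t = 0.  D is the ensemble-averaged
#' sum of squared intermolecular dipolar frequencies, rad^2/µs^2.
#'
#' @param D second moment in rad^2/µs^2.
#' @param tau1,tau2 delays in µs (vectorised).
#' @export
transfer_factor <- function(D, tau1, tau2) {
  stopifnot(D >= 0, all(tau1 >= 0), all(tau2 >= 0))
  D * tau1 * tau2
}

#' Intermolecular coherence-transfer artefact term
#'
#' \eqn{A(\tau_1,\tau_2) = F(\tau_1) F(\tau_2) D \tau_1 \tau_2}: the
#' product of two single-delay form factors with the transfer factor.  It
#' vanishes at the trace ends exactly where F would peak, which is why the
#' artefact stays weak in practically useful measurements.
#'
#' @param F1,F2 form-factor values at `tau1` and `tau2`.
#' @inheritParams transfer_factor
#' @export
artefact_term <- function(F1, F2, D, tau1, tau2) {
  F1 * F2 * transfer_factor(D, tau1, tau2)
}

#' Compose the monoradical SIFTER signal
#'
#' \eqn{V^{mono}(\tau_1,\tau_2) = B_S(\tau_1,\tau_2) +
#' D\tau_1\tau_2\, B_t(\tau_1) B_t(\tau_2)}: the no-transfer pathway
#' relaxes with the SIDRE surface, the intermolecular transfer pathway
#' with the product of Hahn decays.
#'
#' @param model a [relaxation_model()]; `NULL` disables relaxation
#'   (Bt = BS = 1).
#' @param D second moment in rad^2/µs^2.
#' @param tau0 half total evolution time, µs.
#' @param t_grid SIFTER time grid in µs.
#' @return a [dipolar_trace()]; `meta$breakdown` holds the BS and
#'   Bt-product components.
#' @export
compose_monoradical <- function(model, D, tau0, t_grid) {
  tt <- tau_split(tau0, t_grid)
  if (is.null(model)) {
    bs <- rep(1, length(t_grid)); btbt <- bs
  } else {
    bs <- evaluate_bs(model, tt$tau1, tt$tau2)
    btbt <- evaluate_bt(model, tt$tau1) * evaluate_bt(model, tt$tau2)
  }
  dterm <- transfer_factor(D, tt$tau1, tt$tau2)
  dipolar_trace(t_grid, bs + dterm * btbt, tau0 = tau0, sequence = "sifter",
                meta = list(kind = "mono", D = D,
                            breakdown = list(BS = bs, BtBt = btbt,
                                             Dtau = dterm)))
}

#' Intermolecular background of the main dipolar term
#'
#' \eqn{\tfrac12 [B_S(\tau_1,\tau_2) + B_t(\tau_1)B_t(\tau_2)]}: the
#' background that multiplies the intramolecular modulation F(t) in the
#' biradical SIFTER signal, lying pointwise between the Hahn product and
#' the SIDRE surface.  This -- not the SIDRE trace itself -- is the correct
#' divisor for the modulated signal part.
#'
#' @inheritParams compose_monoradical
#' @export
main_term_background <- function(model, tau0, t_grid) {
  tt <- tau_split(tau0, t_grid)
  if (is.null(model)) return(rep(1, length(t_grid)))
  0.5 * (evaluate_bs(model, tt$tau1, tt$tau2) +
         evaluate_bt(model, tt$tau1) * evaluate_bt(model, tt$tau2))
}

#' Compose the full biradical SIFTER signal
#'
#' Assembles the modulation-depth-weighted signal
#' \eqn{V = (1-\lambda) V^{n.m.} + \lambda V^{mod.}} with
#' \deqn{V^{mod.} = F(\tau_2-\tau_1)\tfrac12[B_S + B_tB_t] +
#'   F(\tau_1)F(\tau_2) D\tau_1\tau_2 B_tB_t,}
#' \deqn{(1-\lambda) V^{n.m.} = (1-\lambda)[B_S + D\tau_1\tau_2 B_tB_t] +
#'   \tfrac{\lambda}{2} K (B_S - B_tB_t),}
#' where \eqn{K = \langle\cos\omega_{dd}(\tau_1+\tau_2)\rangle} is the
#' fixed-sum cosine constant.  This grouping is algebraically identical to
#' the ungrouped form \eqn{\lambda[F B_S + F_s(B_tB_t - B_S) + A B_tB_t] +
#' (1-\lambda)[B_S + D\tau_1\tau_2 B_tB_t]} (`form = "direct"`), which is
#' evaluated through the sine-product kernel [sine_product_term()] and
#' retained as an internal consistency check.
#'
#' At \eqn{\lambda = 0} the output equals [compose_monoradical()]; at
#' \eqn{\lambda = 1} with relaxation and transfer off it reduces to the
#' bare form factor.
#'
#' @param dist a [distance_distribution][gaussian_distribution] for the
#'   intramolecular spin pair.
#' @param model a [relaxation_model()], or `NULL` for no relaxation.
#' @param lambda modulation depth in `[0, 1]`.
#' @param D second moment in rad^2/µs^2.
#' @param tau0 half total evolution time, µs.
#' @param t_grid SIFTER time grid in µs.
#' @param form `"grouped"` (default) or `"direct"`; both give identical
#'   values to numerical precision.
#' @param n_theta,n_r powder quadrature resolution.
#' @return a [dipolar_trace()] whose `meta$breakdown` contains every term
#'   (F, F1, F2, Fs, K, BS, BtBt, V_nm, V_mod).
#' @export
compose_biradical <- function(dist, model, lambda, D, tau0, t_grid,
                              form = c("grouped", "direct"),
                              n_theta = 201L, n_r = 101L) {
  form <- match.arg(form)
  if (lambda < 0 || lambda > 1) stop("modulation depth lambda must be in [0, 1]")
  tt <- tau_split(tau0, t_grid)
  if (is.null(model)) {
    bs <- rep(1, length(t_grid)); bt1 <- bs; bt2 <- bs
  } else {
    bs <- evaluate_bs(model, tt$tau1, tt$tau2)
    bt1 <- evaluate_bt(model, tt$tau1)
    bt2 <- evaluate_bt(model, tt$tau2)
  }
  btbt <- bt1 * bt2
  Fmod <- powder_form_factor(dist, t_grid, n_theta, n_r)
  F1 <- powder_form_factor(dist, tt$tau1, n_theta, n_r)
  F2 <- powder_form_factor(dist, tt$tau2, n_theta, n_r)
  K <- fixed_sum_cosine(dist, tau0, n_theta, n_r)
  dterm <- transfer_factor(D, tt$tau1, tt$tau2)
  art <- F1 * F2 * dterm

  v_mod <- Fmod * 0.5 * (bs + btbt) + art * btbt
  v_nm_scaled <- (1 - lambda) * (bs + dterm * btbt) +
    (lambda / 2) * K * (bs - btbt)

  if (form == "grouped") {
    v <- v_nm_scaled + lambda * v_mod
  } else {
    fs <- sine_product_term(dist, tt$tau1, tt$tau2, n_theta, n_r)
    v_bi <- Fmod * bs + fs * (btbt - bs) + art * btbt
    v <- (1 - lambda) * (bs + dterm * btbt) + lambda * v_bi
  }

  dipolar_trace(t_grid, v, tau0 = tau0, sequence = "sifter",
                meta = list(kind = "bi", lambda = lambda, D = D, K = K,
                            form = form,
                            breakdown = list(F = Fmod, F1 = F1, F2 = F2,
                                             K = K, BS = bs, BtBt = btbt,
                                             Dtau = dterm, artefact = art,
                                             V_mod = v_mod,
                                             V_nm_scaled = v_nm_scaled)))
}

#' Divide a SIFTER trace by the SIDRE surface
#'
#' Pointwise quotient of a trace by \eqn{B_S(\tau_1,\tau_2)}; for
#' monoradical input this yields \eqn{1 + D\tau_1\tau_2\,
#' B_tB_t/B_S}.  Points where the divisor falls below `floor` are masked
#' (`NA`) with a warning rather than interpolated; the count is recorded
#' in `meta$n_masked`.
#'
#' @param trace a [dipolar_trace()].
#' @param bs either a [relaxation_model()] (the surface is evaluated on
#'   the trace grid) or a numeric vector of divisor values.
#' @param floor divisor floor below which points are masked.
#' @export
divide_by_sidre <- function(trace, bs, floor = 1e-6) {
  stopifnot(inherits(trace, "dipolar_trace"))
  if (inherits(bs, "relaxation_model")) {
    tt <- tau_split(trace$tau0, trace$t)
    bs <- evaluate_bs(bs, tt$tau1, tt$tau2)
  }
  stopifnot(length(bs) == length(trace$t))
  bad <- !is.finite(bs) | bs < floor
  if (any(bad))
    warning(sum(bad), " point(s) masked: SIDRE divisor below floor")
  out <- trace$amplitude / ifelse(bad, NA_real_, bs)
  meta <- trace$meta
  meta$n_masked <- sum(bad)
  meta$divided_by <- "sidre"
  dipolar_trace(trace$t, out, tau0 = trace$tau0,
                sequence = trace$sequence, meta = meta)
}
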