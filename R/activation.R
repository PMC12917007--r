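#' Expected distractor activation at time t
#'
#' The distractor-based (automatic) route contributes a pulse of activation
#' shaped as a rescaled gamma density,
#' \deqn{E[X_A(t)] = A \, e^{-t/\tau}
#'   \left(\frac{t e}{(\alpha - 1)\tau}\right)^{\alpha - 1},}
#' which is 0 at \eqn{t = 0}, rises to its maximum, exactly \eqn{A}, at
#' \eqn{t_{peak} = (\alpha - 1)\tau}, and decays back toward zero.
#'
#' @param t Time(s) since stimulus onset, ms (vectorized; must be >= 0).
#' @param p A [dmc_params()] object.
#' @return Expected activation in evidence units, same length as `t`.
#' @seealso [automatic_drift()] for its time derivative.
#' @export
automatic_activation <- function(t, p) {
  stopifnot(inherits(p, "dmc_params"))
  if (any(!is.finite(t))) stop("t must be finite")
  if (any(t < 0)) stop("t must be >= 0")
  a <- p$aa_shape
  out <- p$amp * exp(-t / p$tau) * (t * exp(1) / ((a - 1) * p$tau))^(a - 1)
  out[t == 0] <- 0
  out
}

#' Time-varying distractor drift rate
#'
#' The drift contributed by the distractor route is the time derivative of
#' [automatic_activation()]:
#' \deqn{\mu_D(t) = E[X_A(t)] \left(\frac{\alpha - 1}{t} -
#'   \frac{1}{\tau}\right).}
#' It is positive before the pulse peak, zero exactly at
#' \eqn{t_{peak} = (\alpha - 1)\tau}, and negative afterwards.  At
#' \eqn{t = 0} the value is defined by continuity (for \eqn{\alpha = 2} this
#' limit is \eqn{A e / \tau}).
#'
#' @inheritParams automatic_activation
#' @return Drift in evidence units per ms, same length as `t`.
#' @export
automatic_drift <- function(t, p) {
  stopifnot(inherits(p, "dmc_params"))
  if (any(!is.finite(t))) stop("t must be finite")
  if (any(t < 0)) stop("t must be >= 0")
  a <- p$aa_shape
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- automatic_activation(tp, p) * ((a - 1) / tp - 1 / p$tau)
  if (any(!pos)) {
    out[!pos] <- if (a == 2) p$amp * exp(1) / p$tau else if (a > 2) 0 else Inf
  }
  out
}

#' Superimposed drift rate of the combined process
#'
#' The drift of the single diffusion process is the sum of the constant
#' target drift `mu_t` and the time-varying distractor drift, the latter
#' entering positively on congruent and negatively on incongruent trials
#' (evidence toward the correct response is positive).  In the
#' delayed-target-onset variant the target term is suppressed for
#' `t < onset_delay` while the distractor pulse clock runs from stimulus
#' onset.
#'
#' @inheritParams automatic_activation
#' @param congruency `"congruent"` or `"incongruent"`.
#' @return Drift in evidence units per ms, same length as `t`.
#' @export
superimposed_drift <- function(t, p, congruency = c("congruent", "incongruent")) {
  congruency <- match.arg(congruency)
  sgn <- if (congruency == "congruent") 1 else -1
  target <- ifelse(t >= p$onset_delay, p$mu_t, 0)
  sgn * automatic_drift(t, p) + target
}

#' Draw diffusion starting points
#'
#' Starting points vary from trial to trial: a symmetric
#' beta(`sp_shape`, `sp_shape`) variate rescaled from (0, 1) to
#' `(-bound, bound)`, hence symmetric around zero.  `sp_shape = 1` gives a
#' uniform start; larger shapes concentrate starts near zero.
#'
#' @param p A [dmc_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of starting points in `(-bound, bound)`.  Uses R's
#'   RNG stream (see `set.seed`).
#' @export
draw_start_point <- function(p, n = 1) {
  stopifnot(inherits(p, "dmc_params"), n >= 1)
  (2 * stats::rbeta(n, p$sp_shape, p$sp_shape) - 1) * p$bound
}
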