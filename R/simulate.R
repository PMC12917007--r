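#' Simulate DMC trials of one congruency
#'
#' Runs the Euler-Maruyama scheme
#' \deqn{X(t + dt) = X(t) + \mu(t)\,dt + \sigma \sqrt{dt}\, N(0, 1)}
#' from a random starting point until absorption at `+bound` (correct) or
#' `-bound` (error), where \eqn{\mu(t)} is [superimposed_drift()].  Decision
#' time is the first-crossing step times `dt`; reaction time adds a residual
#' time draw `N(res_mean, res_sd)` truncated at zero.  Trials that reach no
#' boundary by `t_max` are flagged `responded = FALSE` with missing RT —
#' a valid outcome, mirroring response-deadline misses.
#'
#' @param p A [dmc_params()] object.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param n Number of trials (>= 1).
#' @param seed Integer seed for the simulator's own RNG stream; the same
#'   seed reproduces identical trials.  If `NULL`, a seed is drawn from R's
#'   RNG.
#' @param antithetic If `TRUE`, odd-numbered trials mirror the noise of the
#'   preceding trial (antithetic variates).  Marginal distributions are
#'   unchanged but summary statistics have lower Monte-Carlo variance;
#'   trials are then pairwise dependent, so leave this off (the default)
#'   when emulating real independent-trial data.  The fitting objective
#'   turns it on.
#' @return A data.frame with columns `congruency`, `decision_time` (ms),
#'   `rt` (ms), `correct`, `responded`, and attribute `seed`.
#' @examples
#' p <- demo_params(tau = 25)
#' trials <- simulate_condition(p, "incongruent", n = 1000, seed = 1)
#' mean(trials$rt[trials$correct], na.rm = TRUE)
#' @export
simulate_condition <- function(p, congruency = c("congruent", "incongruent"),
                               n, seed = NULL, antithetic = FALSE) {
  stopifnot(inherits(p, "dmc_params"))
  congruency <- match.arg(congruency)
  if (length(n) != 1L || n < 1) stop("n must be a single count >= 1")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  sgn <- if (congruency == "congruent") 1L else -1L
  res <- .sim_trials_cpp(p$amp, p$tau, p$aa_shape, p$mu_t, p$sigma, p$bound,
                         p$res_mean, p$res_sd, p$sp_shape, p$onset_delay,
                         p$dt, p$t_max, sgn, as.integer(n), as.double(seed),
                         isTRUE(antithetic))
  out <- data.frame(congruency = rep(congruency, n),
                    decision_time = res$decision_time, rt = res$rt,
                    correct = res$correct, responded = res$responded,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_condition()] with `n = 1`.
#'
#' @inheritParams simulate_condition
#' @return A one-row data.frame (see [simulate_condition()]).
#' @export
simulate_trial <- function(p, congruency = c("congruent", "incongruent"),
                           seed = NULL) {
  simulate_condition(p, congruency, n = 1L, seed = seed)
}

#' Simulate both congruencies of one condition cell
#'
#' @inheritParams simulate_condition
#' @param n Trials per congruency.
#' @param seed Base seed; congruent trials use `seed` and incongruent
#'   `seed + 1`.
#' @return A data.frame stacking both congruencies.
#' @export
simulate_both <- function(p, n, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  rbind(simulate_condition(p, "congruent", n, seed = seed),
        simulate_condition(p, "incongruent", n, seed = seed + 1))
}
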