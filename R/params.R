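#' DMC model parameters
#'
#' Construct a validated parameter set for the diffusion model for conflict
#' tasks (DMC).  The model superimposes a constant target-based drift rate
#' `mu_t` with the time-varying drift of a distractor-based activation pulse
#' shaped as a rescaled gamma density: the expected distractor activation is
#' \deqn{E[X_A(t)] = A \, e^{-t/\tau} \left(\frac{t e}{(\alpha-1)\tau}\right)^{\alpha-1},}
#' which rises from 0 to its peak amplitude `amp` at
#' \eqn{t_{peak} = (\alpha - 1)\tau} and decays back to zero.  A single
#' diffusion process with diffusion constant `sigma` accumulates the summed
#' drift between absorbing boundaries at `+bound` (correct) and `-bound`
#' (error); reaction time is decision time plus a normally distributed
#' residual (non-decision) time.
#'
#' `onset_delay` implements the delayed-target-onset variant: target
#' accumulation only begins `onset_delay` ms after stimulus onset while the
#' distractor pulse clock starts at 0, so distractor activation has already
#' started to decay when target evidence begins to accrue.  The standard
#' model has `onset_delay = 0`.
#'
#' @param amp Distractor pulse peak amplitude \eqn{A} (evidence units).
#' @param tau Distractor pulse scale \eqn{\tau} (ms).  With the conventional
#'   shape \eqn{\alpha = 2} the pulse peaks exactly at `tau` ms.
#' @param mu_t Target drift rate \eqn{\mu_T} (evidence units per ms).
#' @param bound Decision boundary \eqn{b} (evidence units).
#' @param res_mean,res_sd Mean \eqn{\mu_R} and standard deviation
#'   \eqn{\sigma_R} of the residual time (ms).  Draws are truncated at zero.
#' @param sp_shape Shape \eqn{\alpha_s} of the symmetric beta distribution of
#'   starting points on `(-bound, bound)`.
#' @param aa_shape Distractor pulse shape \eqn{\alpha} (> 1); fixed at 2 in
#'   all standard fits.
#' @param sigma Diffusion constant \eqn{\sigma}
#'   (evidence units per \eqn{\sqrt{ms}}); fixed at 4.
#' @param onset_delay Target-accumulation onset delay \eqn{\delta} (ms).
#' @param dt Integration step (ms).
#' @param t_max Maximum decision time (ms); trials that reach no boundary by
#'   `t_max` are recorded as non-responses.
#'
#' @return An object of class `dmc_params` (a named list).
#' @examples
#' p <- dmc_params(amp = 30, tau = 25, mu_t = 0.7, bound = 70,
#'                 res_mean = 300, res_sd = 30, sp_shape = 3)
#' pulse_peak_time(p)  # 25 ms
#' @export
dmc_params <- function(amp, tau, mu_t, bound, res_mean, res_sd, sp_shape,
                       aa_shape = 2, sigma = 4, onset_delay = 0,
                       dt = 1, t_max = 2000) {
  p <- list(amp = amp, tau = tau, aa_shape = aa_shape, mu_t = mu_t,
            sigma = sigma, bound = bound, res_mean = res_mean,
            res_sd = res_sd, sp_shape = sp_shape, onset_delay = onset_delay,
            dt = dt, t_max = t_max)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  stopifnot(p$amp >= 0, p$tau > 0, p$aa_shape > 1, p$sigma > 0,
            p$bound > 0, p$res_sd >= 0, p$sp_shape > 0,
            p$onset_delay >= 0, p$dt > 0, p$t_max > p$dt)
  structure(p, class = "dmc_params")
}

#' @export
print.dmc_params <- function(x, ...) {
  cat("DMC parameters\n")
  cat(sprintf("  distractor pulse: amp = %g, tau = %g ms, shape = %g (peak at %g ms)\n",
              x$amp, x$tau, x$aa_shape, pulse_peak_time(x)))
  cat(sprintf("  target drift mu_t = %g%s\n", x$mu_t,
              if (x$onset_delay > 0)
                sprintf(" (onset delayed by %g ms)", x$onset_delay) else ""))
  cat(sprintf("  boundary = %g, sigma = %g, start-point shape = %g\n",
              x$bound, x$sigma, x$sp_shape))
  cat(sprintf("  residual time: mean = %g ms, sd = %g ms\n",
              x$res_mean, x$res_sd))
  cat(sprintf("  integration: dt = %g ms, t_max = %g ms\n", x$dt, x$t_max))
  invisible(x)
}

#' Time at which the distractor pulse peaks
#'
#' @param p A [dmc_params()] object.
#' @return `(aa_shape - 1) * tau`, in ms.
#' @export
pulse_peak_time <- function(p) {
  (p$aa_shape - 1) * p$tau
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named parameters replaced, re-validated.
#'
#' @param p A [dmc_params()] object.
#' @param ... Named scalar replacements, e.g. `amp = 0`.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  stopifnot(all(names(repl) %in% names(p)))
  q <- unclass(p)
  q[names(repl)] <- repl
  do.call(dmc_params, q[c("amp", "tau", "mu_t", "bound", "res_mean",
                          "res_sd", "sp_shape", "aa_shape", "sigma",
                          "onset_delay", "dt", "t_max")])
}

#' Published condition-average parameter sets
#'
#' Mean best-fitting DMC parameters for the two eccentricity conditions of
#' the two Simon-task experiments (within-block and between-block
#' eccentricity manipulation), as reported with their standard errors across
#' 96 participants.  These serve as generating values for synthetic
#' populations and as recovery-study ground truth.
#'
#' @param experiment 1 (eccentricity varied within blocks) or 2 (between
#'   blocks, alternating).
#' @param eccentricity `"near"` or `"far"`.
#' @param se If `TRUE`, return the named vector of standard errors of the
#'   condition means instead of a parameter object.
#' @return A [dmc_params()] object (or a named numeric vector of SEs).
#' @export
reference_params <- function(experiment = 1,
                             eccentricity = c("near", "far"),
                             se = FALSE) {
  eccentricity <- match.arg(eccentricity)
  experiment <- match.arg(as.character(experiment), c("1", "2"))
  key <- paste0("e", experiment, "_", eccentricity)
  means <- list(
    e1_near = c(mu_t = 0.58, bound = 77, res_mean = 332, res_sd = 29,
                sp_shape = 3.54, amp = 12.9, tau = 103),
    e1_far  = c(mu_t = 0.54, bound = 75, res_mean = 332, res_sd = 31,
                sp_shape = 3.48, amp = 16.6, tau = 98),
    e2_near = c(mu_t = 0.61, bound = 75, res_mean = 348, res_sd = 30,
                sp_shape = 3.5,  amp = 14.5, tau = 85),
    e2_far  = c(mu_t = 0.56, bound = 77, res_mean = 349, res_sd = 32,
                sp_shape = 3.5,  amp = 14.8, tau = 79))
  ses <- list(
    e1_near = c(mu_t = 0.02, bound = 2, res_mean = 4, res_sd = 2,
                sp_shape = 0.05, amp = 0.6, tau = 8),
    e1_far  = c(mu_t = 0.02, bound = 2, res_mean = 4, res_sd = 2,
                sp_shape = 0.06, amp = 0.7, tau = 7),
    e2_near = c(mu_t = 0.02, bound = 2, res_mean = 5, res_sd = 2,
                sp_shape = 0.06, amp = 0.7, tau = 7),
    e2_far  = c(mu_t = 0.02, bound = 2, res_mean = 6, res_sd = 2,
                sp_shape = 0.05, amp = 0.8, tau = 7))
  if (se) return(ses[[key]])
  m <- means[[key]]
  dmc_params(amp = m[["amp"]], tau = m[["tau"]], mu_t = m[["mu_t"]],
             bound = m[["bound"]], res_mean = m[["res_mean"]],
             res_sd = m[["res_sd"]], sp_shape = m[["sp_shape"]])
}

#' Illustrative parameter set with an early- or late-peaking distractor
#'
#' The canonical demonstration parameters for the model's delta-plot
#' signatures: \eqn{\sigma = 4}, \eqn{\mu_T = 0.7}, \eqn{\mu_R = 300},
#' \eqn{\sigma_R = 30}, \eqn{b = 70}, \eqn{A = 30}, \eqn{\alpha = 2}.  With
#' `tau = 25` the distractor peaks early and the Simon effect decreases
#' monotonically across the RT distribution; with `tau = 40` it peaks later
#' and the effect first rises then falls.
#'
#' @param tau Distractor scale in ms (25 or 40 for the two demonstration
#'   cells; any positive value is accepted).
#' @param sp_shape Starting-point shape (the demonstration leaves it
#'   unstated; 3 is the conventional default).
#' @return A [dmc_params()] object.
#' @export
demo_params <- function(tau = 25, sp_shape = 3) {
  dmc_params(amp = 30, tau = tau, mu_t = 0.7, bound = 70,
             res_mean = 300, res_sd = 30, sp_shape = sp_shape)
}

#' Read and write parameter sets as flat key-value text
#'
#' One `key = value` pair per line; keys are the [dmc_params()] argument
#' names.  Round-trips exactly at full double precision.
#'
#' @param p A [dmc_params()] object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   [dmc_params()] object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "dmc_params"))
  lines <- sprintf("%s = %s", names(p),
                   vapply(unclass(p), format, "", digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed parameter file at line ", bad[1], ": ", lines[bad[1]])
  vals <- as.numeric(vapply(kv, function(x) trimws(x[2]), ""))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  do.call(dmc_params, as.list(vals))
}
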