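#' Fitting specification
#'
#' Settings for fitting the DMC to one participant x one condition: which
#' parameters are free and their box bounds, the fixed constants, the
#' Monte-Carlo budget per cost evaluation, and the differential-evolution
#' (DE) settings.
#'
#' Defaults: the seven free parameters are `amp`, `tau`, `mu_t`, `bound`,
#' `res_mean`, `res_sd`, `sp_shape`, with generous bounds around typical
#' Simon-task estimates; `sigma = 4`, `aa_shape = 2`, `dt = 1` ms,
#' `t_max = 2000` ms are fixed.  The objective is the weighted RMSE of
#' [cost_rmse()]; `caf_weight` (default 300) converts accuracy-proportion
#' residuals to the millisecond scale of the CDF residuals so that both
#' blocks contribute comparably: a 0.01 accuracy miss counts like a 3 ms
#' quantile miss, which also matches the sampling noise of the two blocks
#' at a few hundred observed trials (CAF bin accuracies have binomial SE
#' around 0.02-0.03, CDF deciles around 6-9 ms).  DE uses binomial crossover (0.9)
#' with population `10 x` the number of free parameters, differential
#' weight drawn uniformly in \[0.5, 1\] per generation (dither),
#' reflection at the bounds, and at most `max_gen` generations with early
#' stop after `stall_gen` generations without relative improvement
#' `> rel_tol`.  The default mutation strategy is local-to-best/1 — each
#' candidate moves toward the current best plus a scaled random difference
#' — matching the default of the optimizer package used for the reference
#' fits; plain rand/1 is available via `strategy`.
#' Common random numbers (`crn = TRUE`) reuse one simulation seed across all
#' candidate evaluations, which removes Monte-Carlo jitter from the
#' comparison between candidates.
#'
#' @param free Character vector of free parameter names.
#' @param lower,upper Named bounds for the free parameters.
#' @param fixed Named list of fixed parameter values.
#' @param n_sim_trials Simulated trials per congruency per cost evaluation.
#' @param cdf_probs CDF probability grid.
#' @param n_caf_bins CAF bin count.
#' @param caf_weight Scale factor applied to CAF residuals (ms per unit
#'   proportion).
#' @param pop_size DE population size (default `10 * length(free)`).
#' @param max_gen Maximum DE generations.
#' @param cr DE crossover probability.
#' @param rel_tol,stall_gen Early-stopping rule: stop when the best
#'   objective has improved by a relative factor below `rel_tol` over the
#'   last `stall_gen` generations.
#' @param strategy DE mutation strategy: `"local-to-best"` (default; the
#'   default of the optimizer package used for the reference fits) or
#'   `"rand/1"`.
#' @param crn Use common random numbers across cost evaluations.
#' @param antithetic Use antithetic variates inside cost-evaluation
#'   simulations (variance reduction; see [simulate_condition()]).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free = c("amp", "tau", "mu_t", "bound", "res_mean",
                              "res_sd", "sp_shape"),
                     lower = c(amp = 0, tau = 5, mu_t = 0.1, bound = 20,
                               res_mean = 200, res_sd = 5, sp_shape = 2),
                     upper = c(amp = 40, tau = 300, mu_t = 1.0, bound = 150,
                               res_mean = 800, res_sd = 100, sp_shape = 4),
                     fixed = list(sigma = 4, aa_shape = 2, dt = 1,
                                  t_max = 2000, onset_delay = 0),
                     n_sim_trials = 2500,
                     cdf_probs = seq(0.1, 0.9, by = 0.1),
                     n_caf_bins = 5,
                     caf_weight = 300,
                     pop_size = NULL,
                     max_gen = 110,
                     cr = 0.9,
                     rel_tol = 1e-4,
                     stall_gen = 25,
                     strategy = c("local-to-best", "rand/1"),
                     crn = TRUE,
                     antithetic = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(length(free) >= 1, all(free %in% names(lower)),
            all(free %in% names(upper)))
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper")
  if (is.null(pop_size)) pop_size <- 10L * length(free)
  structure(list(free = free, lower = lower, upper = upper, fixed = fixed,
                 n_sim_trials = n_sim_trials, cdf_probs = cdf_probs,
                 n_caf_bins = n_caf_bins, caf_weight = caf_weight,
                 pop_size = as.integer(pop_size), max_gen = as.integer(max_gen),
                 cr = cr, rel_tol = rel_tol, stall_gen = as.integer(stall_gen),
                 strategy = strategy, crn = crn, antithetic = antithetic),
            class = "fit_spec")
}

#' @export
print.fit_spec <- function(x, ...) {
  cat("DMC fit specification\n")
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  cat(sprintf("  %d sim trials/congruency/evaluation; caf_weight = %g\n",
              x$n_sim_trials, x$caf_weight))
  cat(sprintf("  DE (%s): pop %d, <= %d generations, CR %.2f, CRN %s\n",
              x$strategy, x$pop_size, x$max_gen, x$cr, x$crn))
  invisible(x)
}

.params_from_vector <- function(theta, spec) {
  args <- c(as.list(theta), spec$fixed)
  do.call(dmc_params, args[c("amp", "tau", "mu_t", "bound", "res_mean",
                             "res_sd", "sp_shape", "aa_shape", "sigma",
                             "onset_delay", "dt", "t_max")])
}

#' Weighted RMSE between observed and predicted condition summaries
#'
#' Pools, over both congruencies, the CDF-quantile residuals (ms) and the
#' CAF-accuracy residuals multiplied by `caf_weight`, and returns the root
#' mean square of the pooled residual vector.  This is the objective
#' minimized during fitting: the model is fitted simultaneously to the RT
#' distributions and the error patterns of both congruencies.
#'
#' @param observed,predicted Lists with elements `congruent` and
#'   `incongruent`, each a [summarize_condition()] object on matching grids.
#' @param caf_weight Scale factor for accuracy residuals (ms per unit
#'   proportion).
#' @return A single non-negative number.
#' @export
cost_rmse <- function(observed, predicted, caf_weight = 300) {
  resid <- c()
  for (cond in c("congruent", "incongruent")) {
    o <- observed[[cond]]; pr <- predicted[[cond]]
    if (is.null(o) || is.null(pr)) stop("missing congruency '", cond, "'")
    if (length(o$cdf_probs) != length(pr$cdf_probs) ||
        any(o$cdf_probs != pr$cdf_probs))
      stop("CDF probability grids do not match")
    if (nrow(o$caf) != nrow(pr$caf))
      stop("CAF bin counts do not match")
    resid <- c(resid, o$cdf_quantiles - pr$cdf_quantiles,
               caf_weight * (o$caf$accuracy - pr$caf$accuracy))
  }
  sqrt(mean(resid^2))
}

#' Model-predicted condition summaries
#'
#' Simulates `spec$n_sim_trials` trials per congruency at the given
#' parameters and summarizes them on the spec's grids.  With a fixed
#' `seed` the prediction is deterministic, which is how common random
#' numbers are realized during fitting.
#'
#' @param p A [dmc_params()] object.
#' @param spec A [fit_spec()].
#' @param seed Integer seed for the simulation stream.
#' @return A list with `congruent` and `incongruent`
#'   [summarize_condition()] objects.
#' @export
predict_summaries <- function(p, spec, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  sims <- list(
    congruent = simulate_condition(p, "congruent", spec$n_sim_trials,
                                   seed = seed,
                                   antithetic = spec$antithetic),
    incongruent = simulate_condition(p, "incongruent", spec$n_sim_trials,
                                     seed = seed + 1,
                                     antithetic = spec$antithetic))
  lapply(sims, summarize_condition, cdf_probs = spec$cdf_probs,
         n_caf_bins = spec$n_caf_bins)
}

# Bound-constrained differential evolution with binomial crossover,
# dither, and reflection at the bounds.  Two mutation strategies:
# "local-to-best/1" (the default of the optimizer package the reference
# fits used: each candidate moves toward the current best plus a random
# difference vector) and plain "rand/1".  Deterministic given R's RNG
# state.
.de_optimize <- function(fn, lower, upper, pop_size, max_gen, cr,
                         rel_tol, stall_gen, strategy = "local-to-best") {
  d <- length(lower)
  pop <- matrix(stats::runif(pop_size * d, lower, upper),
                nrow = pop_size, ncol = d, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  n_eval <- pop_size
  best_hist <- min(cost)
  for (gen in seq_len(max_gen)) {
    f <- stats::runif(1, 0.5, 1)
    b <- which.min(cost)
    for (i in seq_len(pop_size)) {
      idx <- sample.int(pop_size, 3)
      while (any(idx == i)) idx <- sample.int(pop_size, 3)
      mutant <- if (strategy == "local-to-best")
        pop[i, ] + f * (pop[b, ] - pop[i, ]) + f * (pop[idx[1], ] - pop[idx[2], ])
      else
        pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      # reflect out-of-bounds components back into the box
      low <- mutant < lower
      mutant[low] <- pmin(2 * lower[low] - mutant[low], upper[low])
      high <- mutant > upper
      mutant[high] <- pmax(2 * upper[high] - mutant[high], lower[high])
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tc <- fn(trial)
      n_eval <- n_eval + 1
      if (is.finite(tc) && tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    best_hist <- c(best_hist, min(cost))
    if (gen > stall_gen) {
      prev <- best_hist[gen + 1 - stall_gen]
      if ((prev - best_hist[gen + 1]) <= rel_tol * prev) break
    }
  }
  if (!any(is.finite(cost)))
    stop("differential evolution failed: no finite objective value")
  b <- which.min(cost)
  list(par = pop[b, ], value = cost[b], n_eval = n_eval,
       generations = length(best_hist) - 1L,
       converged = length(best_hist) - 1L < max_gen,
       trace = best_hist)
}

#' Fit the DMC to one participant x one condition
#'
#' Summarizes the observed trials of both congruencies and minimizes
#' [cost_rmse()] over the free parameters by differential evolution.  The
#' fitting unit is all trials of one participant in one eccentricity
#' condition, both congruencies jointly.
#'
#' @param trials A data.frame of observed trials with columns `congruency`
#'   (`"congruent"`/`"incongruent"`), `rt` (ms, `NA` for no response) and
#'   `correct`.  Fewer than 100 responded trials per congruency triggers a
#'   warning (summaries become unstable).
#' @param spec A [fit_spec()].
#' @param seed Integer seed governing the whole fit (DE moves and the
#'   common-random-number simulation stream); the fit is deterministic
#'   given `seed`.
#' @param condition Optional label stored in the result.
#' @return An object of class `fit_result`: `params` (a [dmc_params()]),
#'   `rmse`, `n_evaluations`, `generations`, `converged`, `seed`,
#'   `condition`, `spec`.
#' @export
fit_condition <- function(trials, spec = fit_spec(), seed = NULL,
                          condition = NA_character_) {
  stopifnot(is.data.frame(trials),
            all(c("congruency", "rt", "correct") %in% names(trials)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  observed <- list()
  for (cond in c("congruent", "incongruent")) {
    sub <- trials[trials$congruency == cond, , drop = FALSE]
    n_resp <- sum(!is.na(sub$rt))
    if (n_resp == 0) stop("no responded '", cond, "' trials")
    if (n_resp < 100)
      warning("only ", n_resp, " responded '", cond,
              "' trials; summaries may be unstable")
    observed[[cond]] <- summarize_condition(sub, spec$cdf_probs,
                                            spec$n_caf_bins)
  }
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  oc <- observed$congruent; oi <- observed$incongruent
  fn <- function(theta) {
    names(theta) <- spec$free
    p <- .params_from_vector(theta, spec)
    s <- if (spec$crn) sim_seed else sample.int(.Machine$integer.max - 1L, 1L)
    .dmc_cost_cpp(p$amp, p$tau, p$aa_shape, p$mu_t, p$sigma, p$bound,
                  p$res_mean, p$res_sd, p$sp_shape, p$onset_delay, p$dt,
                  p$t_max, spec$cdf_probs, spec$n_caf_bins, spec$caf_weight,
                  oc$cdf_quantiles, oi$cdf_quantiles,
                  oc$caf$accuracy, oi$caf$accuracy,
                  as.integer(spec$n_sim_trials), as.double(s),
                  isTRUE(spec$antithetic))
  }
  de <- .de_optimize(fn, spec$lower, spec$upper, spec$pop_size, spec$max_gen,
                     spec$cr, spec$rel_tol, spec$stall_gen,
                     strategy = spec$strategy)
  theta <- de$par
  names(theta) <- spec$free
  structure(list(params = .params_from_vector(theta, spec), rmse = de$value,
                 n_evaluations = de$n_eval, generations = de$generations,
                 converged = de$converged, seed = seed,
                 condition = condition, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("DMC fit%s: RMSE %.2f after %d evaluations (%d generations%s)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$rmse, x$n_evaluations, x$generations,
              if (x$converged) ", early stop" else ""))
  est <- unlist(x$params[x$spec$free])
  cat("  ", paste(sprintf("%s = %.3g", names(est), est), collapse = ", "),
      "\n")
  invisible(x)
}

#' Paired comparison of a fitted parameter between two conditions
#'
#' Paired t-test across participants of one best-fitting parameter between
#' two condition fits (e.g. near vs. far eccentricity), with Cohen's d for
#' paired data (mean difference over the SD of the differences).
#'
#' @param fits_a,fits_b Lists of [fit_condition()] results, same
#'   participants in the same order.
#' @param parameter Parameter name, e.g. `"mu_t"`.
#' @return A data.frame row: `parameter`, `mean_a`, `mean_b`,
#'   `mean_diff` (a minus b), `t`, `df`, `p_value`, `cohens_d`.
#' @export
compare_fitted_params <- function(fits_a, fits_b, parameter) {
  stopifnot(length(fits_a) == length(fits_b))
  if (length(fits_a) < 2) stop("need at least 2 participants")
  va <- vapply(fits_a, function(f) f$params[[parameter]], 0)
  vb <- vapply(fits_b, function(f) f$params[[parameter]], 0)
  d <- va - vb
  if (stats::sd(d) == 0) {
    # degenerate: all paired differences equal; t is 0 (no difference) or
    # unbounded (a constant nonzero shift)
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(data.frame(parameter = parameter, mean_a = mean(va),
                      mean_b = mean(vb), mean_diff = mean(d), t = t_stat,
                      df = length(d) - 1,
                      p_value = if (mean(d) == 0) 1 else 0,
                      cohens_d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf))
  }
  tt <- stats::t.test(va, vb, paired = TRUE)
  data.frame(parameter = parameter, mean_a = mean(va), mean_b = mean(vb),
             mean_diff = mean(d), t = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             cohens_d = mean(d) / stats::sd(d))
}

#' Export fit results as a delimited table
#'
#' One row per fit with all parameter estimates, the objective value, the
#' seed and optimizer metadata; plus, via `aggregate = TRUE`, a
#' condition-level aggregation (mean and SE per parameter).
#'
#' @param fits A list of [fit_condition()] results.
#' @param path Output path (tab-separated).
#' @param aggregate Also write `<path>.summary` with mean and SE per
#'   parameter.
#' @return The per-fit table, invisibly.
#' @export
write_fit_table <- function(fits, path = NULL, aggregate = FALSE) {
  rows <- lapply(fits, function(f) {
    est <- as.list(unlist(f$params[f$spec$free]))
    cbind(data.frame(condition = f$condition), est,
          data.frame(rmse = f$rmse, seed = f$seed,
                     n_evaluations = f$n_evaluations,
                     generations = f$generations, converged = f$converged))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    if (aggregate) {
      free <- fits[[1]]$spec$free
      agg <- data.frame(
        parameter = c(free, "rmse"),
        mean = vapply(c(free, "rmse"), function(nm) mean(tab[[nm]]), 0),
        se = vapply(c(free, "rmse"),
                    function(nm) stats::sd(tab[[nm]]) / sqrt(nrow(tab)), 0))
      utils::write.table(agg, paste0(path, ".summary"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  invisible(tab)
}
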