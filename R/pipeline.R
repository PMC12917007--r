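#' Simulation suite: mean RTs and delta plots across parameter cells
#'
#' Simulates a list of parameter cells and returns, per cell, mean
#' congruent/incongruent RT, error rates, the mean Simon effect and the
#' nine-percentile delta plot — the model's distributional signature.  Two
#' ready-made cell lists are provided: [demo_cells()] for the early- vs.
#' late-peaking distractor demonstration (tau = 25 vs. 40), and
#' [drift_grid_cells()] for grids over the target drift rate (and
#' optionally the distractor amplitude) that show how the same drift
#' manipulation can raise, lower or leave unchanged the mean Simon effect
#' depending on distractor timing, while the delta plot ordering stays
#' consistent.
#'
#' @param cells A named list of [dmc_params()] objects.
#' @param n Simulated trials per congruency per cell.
#' @param seed Integer seed.
#' @param probs Delta-plot percentile grid.
#' @return A list with `summary` (one row per cell: mean RTs, error
#'   rates, Simon effect in ms) and `delta_plots` (named list of
#'   [delta_plot()]s), plus `activation` traces (mean distractor
#'   activation over 0-500 ms) per cell.
#' @export
run_figure_simulations <- function(cells = demo_cells(), n = 50000,
                                   seed = NULL,
                                   probs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(is.list(cells), length(cells) >= 1, !is.null(names(cells)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  tgrid <- 0:500
  summary_rows <- list(); dps <- list(); act <- list()
  for (nm in names(cells)) {
    p <- cells[[nm]]
    sim <- simulate_both(p, n, seed = sample.int(.Machine$integer.max - 1L,
                                                 1L))
    cong <- sim[sim$congruency == "congruent" & !is.na(sim$rt), ]
    incg <- sim[sim$congruency == "incongruent" & !is.na(sim$rt), ]
    dps[[nm]] <- delta_plot(cong$rt[cong$correct], incg$rt[incg$correct],
                            probs)
    act[[nm]] <- data.frame(t = tgrid,
                            activation = automatic_activation(tgrid, p))
    summary_rows[[nm]] <- data.frame(
      cell = nm,
      mean_rt_congruent = mean(cong$rt[cong$correct]),
      mean_rt_incongruent = mean(incg$rt[incg$correct]),
      simon_rt = mean(incg$rt[incg$correct]) - mean(cong$rt[cong$correct]),
      error_rate_congruent = 1 - mean(cong$correct),
      error_rate_incongruent = 1 - mean(incg$correct),
      n_per_congruency = n)
  }
  list(summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
       delta_plots = dps, activation = act, seed = seed)
}

#' @rdname run_figure_simulations
#' @param taus Distractor scales for the two demonstration cells.
#' @export
demo_cells <- function(taus = c(25, 40)) {
  cells <- lapply(taus, demo_params)
  names(cells) <- paste0("tau", taus)
  cells
}

#' @rdname run_figure_simulations
#' @param mu_ts Target drift rates of the grid.
#' @param amps Distractor amplitudes, recycled against `mu_ts` (a single
#'   value fixes the amplitude across the drift grid).
#' @param tau Distractor scale of the grid.
#' @param base Base parameter set supplying the remaining values.
#' @export
drift_grid_cells <- function(mu_ts = c(0.5, 0.6, 0.7), amps = 40, tau = 25,
                             base = demo_params()) {
  amps <- rep(amps, length.out = length(mu_ts))
  cells <- Map(function(m, a) update_params(base, mu_t = m, amp = a,
                                            tau = tau),
               mu_ts, amps)
  names(cells) <- sprintf("mu%.2f_A%g_tau%g", mu_ts, amps, tau)
  cells
}

#' Delayed-target-onset simulation suite
#'
#' Simulates the standard model (`onset_delay = 0`) against delayed
#' variants in which target accumulation starts only after a delay while
#' the distractor pulse already decays.  Delays prolong RT and shrink the
#' mean Simon effect (less distractor activation remains when target
#' evidence starts), and they shift the delta plot of the delayed
#' (far-analog) cell *below* the undelayed (near-analog) cell — the
#' opposite offset direction from a strength-based eccentricity effect.
#'
#' @param delays Onset delays in ms; must include 0 for the reference cell.
#' @param base Base parameter set.
#' @param n Trials per congruency per cell.
#' @param seed Integer seed (each cell is simulated with the same
#'   per-cell stream offsets, so `delays = 0` reproduces the standard
#'   model exactly).
#' @return A list: `summary` (per delay: mean RTs, Simon effect),
#'   `delta_plots` (named by delay), `seed`.
#' @export
run_appendix_delay <- function(delays = c(0, 40, 80), base = demo_params(),
                               n = 50000, seed = NULL) {
  stopifnot(all(delays >= 0))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 2L, 1L)
  rows <- list(); dps <- list()
  for (d in delays) {
    p <- update_params(base, onset_delay = d)
    cong <- simulate_condition(p, "congruent", n, seed = seed)
    incg <- simulate_condition(p, "incongruent", n, seed = seed + 1)
    crt <- cong$rt[cong$correct & !is.na(cong$rt)]
    irt <- incg$rt[incg$correct & !is.na(incg$rt)]
    nm <- paste0("delay", d)
    dps[[nm]] <- delta_plot(crt, irt)
    rows[[nm]] <- data.frame(delay = d, mean_rt_congruent = mean(crt),
                             mean_rt_incongruent = mean(irt),
                             simon_rt = mean(irt) - mean(crt))
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       delta_plots = dps, seed = seed)
}

#' Full synthetic-experiment pipeline
#'
#' Runs the whole analysis chain on a synthetic population (or a
#' user-supplied trial table): generate trials, apply the standard
#' exclusions, compute cell means and Simon effects, run the 2 x 2
#' repeated-measures ANOVAs on mean RT and percentage error, build group
#' delta plots and the near/far shift test, and (optionally) fit the DMC
#' per participant x eccentricity and compare the fitted parameters.
#'
#' @param pop A [population_spec()], or `NULL` if `trials` is given.
#' @param trials A tidy trial table (alternative to `pop`).
#' @param seed Integer seed for generation and fitting.
#' @param fit If `TRUE`, fit every participant x eccentricity and run
#'   paired parameter comparisons (slow; scales with participants).
#' @param spec [fit_spec()] used when fitting.
#' @param output_dir If non-`NULL`, write all tables (trials, cell means,
#'   ANOVAs, delta plots, fits) plus a `manifest.txt` recording the seed,
#'   the configuration and an md5 digest of each written file.  Refuses to
#'   overwrite an existing manifest unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a directory with an existing
#'   manifest.
#' @return A list: `prepared` (exclusion output), `cells`, `simon`,
#'   `anova_rt`, `anova_pe`, `delta_near`, `delta_far` (group
#'   [delta_plot()]s), `shift_test`, and when `fit = TRUE` also
#'   `fits_near`, `fits_far`, `param_tests`.
#' @export
run_full_pipeline <- function(pop = NULL, trials = NULL, seed = NULL,
                              fit = FALSE, spec = fit_spec(),
                              output_dir = NULL, overwrite = FALSE) {
  if (is.null(pop) == is.null(trials))
    stop("supply exactly one of 'pop' or 'trials'")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (is.null(trials)) trials <- simulate_experiment(pop, seed = seed)
  prepared <- apply_exclusions(trials)
  cells <- cell_means(prepared)
  simon <- simon_effects(cells)
  anova_rt <- anova_2x2_rm(cells, "mean_rt")
  anova_pe <- anova_2x2_rm(cells, "pe")
  dps <- participant_delta_plots(prepared$rt_set)
  out <- list(prepared = prepared, cells = cells, simon = simon,
              anova_rt = anova_rt, anova_pe = anova_pe,
              delta_near = group_delta_plot(dps$near),
              delta_far = group_delta_plot(dps$far),
              shift_test = delta_shift_test(dps$near, dps$far),
              seed = seed)
  if (fit) {
    set.seed(seed + 1)
    ids <- sort(unique(prepared$accuracy_set$participant))
    fit_one <- function(id, ecc) {
      sub <- prepared$accuracy_set[
        prepared$accuracy_set$participant == id &
          prepared$accuracy_set$eccentricity == ecc, ]
      fit_condition(sub, spec,
                    seed = sample.int(.Machine$integer.max, 1L),
                    condition = paste0(id, "_", ecc))
    }
    out$fits_near <- lapply(ids, fit_one, ecc = "near")
    out$fits_far <- lapply(ids, fit_one, ecc = "far")
    out$param_tests <- do.call(rbind, lapply(
      spec$free, function(nm)
        compare_fitted_params(out$fits_near, out$fits_far, nm)))
  }
  if (!is.null(output_dir)) .write_pipeline_bundle(out, trials, output_dir,
                                                  overwrite)
  out
}

.write_pipeline_bundle <- function(out, trials, dir, overwrite) {
  manifest_path <- file.path(dir, "manifest.txt")
  if (file.exists(manifest_path) && !overwrite)
    stop("output directory already holds a manifest; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE,
                       na = "NA")
    paths <<- c(paths, p)
  }
  wt(trials, "trials.tsv")
  wt(out$cells, "cell_means.tsv")
  wt(out$simon, "simon_effects.tsv")
  wt(out$anova_rt, "anova_rt.tsv")
  wt(out$anova_pe, "anova_pe.tsv")
  wt(as.data.frame(out$delta_near), "delta_near.tsv")
  wt(as.data.frame(out$delta_far), "delta_far.tsv")
  wt(out$shift_test$per_percentile, "shift_test.tsv")
  if (!is.null(out$fits_near)) {
    wt(write_fit_table(out$fits_near), "fits_near.tsv")
    wt(write_fit_table(out$fits_far), "fits_far.tsv")
    wt(out$param_tests, "param_tests.tsv")
  }
  digests <- tools::md5sum(paths)
  writeLines(c(sprintf("seed: %d", out$seed),
               sprintf("package: simondmc %s",
                       as.character(utils::packageVersion("simondmc"))),
               sprintf("%s  %s", digests, basename(names(digests)))),
             manifest_path)
  invisible(manifest_path)
}

#' Parameter-recovery study
#'
#' Simulates participants at a known generating parameter set (zero
#' between-participant variability), applies the standard exclusions, fits
#' each participant's post-exclusion trials, and reports per-parameter
#' recovered means against the generating values.  This is the package's
#' validity standard: the fitting machinery must return the parameters
#' that produced the data.
#'
#' Each synthetic participant runs the full 12-block design with both
#' eccentricity cells generated from the same parameter set, so after
#' dropping the two practice blocks 560 trials (280 per congruency) enter
#' the fit.
#'
#' @param generating A [dmc_params()] generating set.
#' @param n_participants Number of synthetic participants (>= 1).
#' @param spec A [fit_spec()].
#' @param seed Integer seed for the whole study.
#' @return A list: `fits` (per participant), `estimates` (data.frame of
#'   per-participant estimates), `summary` (per parameter: generating
#'   value, mean recovered, relative error).
#' @export
recover_parameters <- function(generating, n_participants = 10,
                               spec = fit_spec(), seed = NULL) {
  stopifnot(inherits(generating, "dmc_params"), n_participants >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  fits <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    des <- generate_design(1, participant = i)
    tab <- simulate_participant(des, generating, generating,
                                seed = sample.int(
                                  .Machine$integer.max - 8L, 1L))
    prepared <- apply_exclusions(tab, accuracy_cutoff = 0)
    fits[[i]] <- fit_condition(prepared$accuracy_set, spec,
                               seed = sample.int(.Machine$integer.max, 1L),
                               condition = paste0("recovery_", i))
  }
  est <- do.call(rbind, lapply(fits, function(f)
    as.data.frame(as.list(unlist(f$params[spec$free])))))
  gen <- unlist(generating[spec$free])
  summary <- data.frame(parameter = spec$free, generating = unname(gen),
                        mean_recovered = unname(colMeans(est)),
                        rel_error = unname((colMeans(est) - gen) / gen))
  list(fits = fits, estimates = est, summary = summary, seed = seed)
}
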