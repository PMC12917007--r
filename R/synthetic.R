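#' Fixed constants of the two experimental designs
#'
#' Both experiments use 12 blocks of 56 trials, eight stimulus displays
#' (2 colors x 2 sides x 2 eccentricities), a 2 s response deadline, and
#' target-center distances of 1.6 cm (near) and 7.4 cm (far) from fixation
#' under the screen calibration assumed by the task.  Experiment 1 mixes
#' eccentricities randomly within blocks; Experiment 2 holds eccentricity
#' constant within a block and alternates it across blocks, with the
#' starting eccentricity counterbalanced across participants.
#'
#' @return A named list of design constants.
#' @export
design_constants <- function() {
  list(n_blocks = 12L, trials_per_block = 56L,
       colors = c("red", "blue"), sides = c("left", "right"),
       eccentricities = c("near", "far"),
       deadline_ms = 2000, near_cm = 1.6, far_cm = 7.4)
}

#' Trial-by-trial design for one synthetic participant
#'
#' Builds the trial stubs (no behavior yet) for one participant.
#' Experiment 1: every block holds exactly `trials_per_block / 8`
#' repetitions of each of the eight displays, in random order.
#' Experiment 2: eccentricity is constant within a block and alternates
#' across blocks; odd-numbered participants start near, even-numbered far;
#' each block holds `trials_per_block / 4` repetitions of each of its four
#' displays.
#'
#' Congruency is derived from the color-to-response mapping: a trial is
#' congruent when the response side mapped to the stimulus color equals the
#' stimulus side.  The mapping itself is irrelevant in aggregate (each
#' congruency gets the same design cells either way); `counterbalance`
#' assigns the reversed mapping to even-numbered participants.
#'
#' @param experiment 1 or 2.
#' @param participant Participant id (integer; drives Experiment 2
#'   counterbalancing and, with `counterbalance`, the color mapping).
#' @param n_blocks,trials_per_block Design size; defaults 12 x 56.
#' @param counterbalance Reverse the color mapping for even participants.
#' @return A data.frame of trial stubs: `participant`, `block`, `trial`,
#'   `eccentricity`, `side`, `color`, `congruency`.
#' @export
generate_design <- function(experiment = 1, participant = 1L,
                            n_blocks = 12L, trials_per_block = 56L,
                            counterbalance = FALSE) {
  experiment <- match.arg(as.character(experiment), c("1", "2"))
  dc <- design_constants()
  mapping <- c(red = "left", blue = "right")
  if (counterbalance && participant %% 2 == 0)
    mapping <- c(red = "right", blue = "left")
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    if (experiment == "1") {
      cells <- expand.grid(color = dc$colors, side = dc$sides,
                           eccentricity = dc$eccentricities,
                           stringsAsFactors = FALSE)
      if (trials_per_block %% nrow(cells) != 0)
        stop("trials_per_block (", trials_per_block,
             ") not divisible by the ", nrow(cells), " display types")
      reps <- trials_per_block / nrow(cells)
    } else {
      start_near <- participant %% 2 == 1
      ecc <- if (xor(b %% 2 == 0, start_near)) "near" else "far"
      cells <- expand.grid(color = dc$colors, side = dc$sides,
                           eccentricity = ecc, stringsAsFactors = FALSE)
      if (trials_per_block %% nrow(cells) != 0)
        stop("trials_per_block (", trials_per_block,
             ") not divisible by the ", nrow(cells), " display types")
      reps <- trials_per_block / nrow(cells)
    }
    blk <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
    blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
    blk$block <- b
    blk$trial <- seq_len(nrow(blk))
    blocks[[b]] <- blk
  }
  out <- do.call(rbind, blocks)
  out$participant <- as.integer(participant)
  out$congruency <- ifelse(mapping[out$color] == out$side,
                           "congruent", "incongruent")
  rownames(out) <- NULL
  out[, c("participant", "block", "trial", "eccentricity", "side", "color",
          "congruency")]
}

#' Simulate the behavior of one participant
#'
#' Fills a design (from [generate_design()]) with DMC-simulated behavior:
#' each trial is simulated from the parameter set matching its eccentricity
#' and its congruency.  Trials in which the diffusion reaches no boundary
#' by `t_max` become `response = "none"` with missing RT (deadline
#' misses).  The response side is reconstructed from the color mapping
#' implied by the design's congruency labels.
#'
#' @param design A design data.frame from [generate_design()].
#' @param params_near,params_far [dmc_params()] for the two eccentricities.
#' @param seed Integer seed; the output table is byte-identical given the
#'   seed.
#' @return The design with added columns `rt` (ms, `NA` for none),
#'   `response` (`"left"`, `"right"`, `"none"`), `correct`.
#' @export
simulate_participant <- function(design, params_near, params_far,
                                 seed = NULL) {
  stopifnot(is.data.frame(design),
            all(c("eccentricity", "congruency", "side") %in% names(design)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 8L, 1L)
  params <- list(near = params_near, far = params_far)
  design$rt <- NA_real_
  design$correct <- FALSE
  design$responded <- FALSE
  k <- 0L
  for (ecc in c("near", "far")) {
    for (cong in c("congruent", "incongruent")) {
      sel <- which(design$eccentricity == ecc & design$congruency == cong)
      k <- k + 1L
      if (!length(sel)) next
      sim <- simulate_condition(params[[ecc]], cong, n = length(sel),
                                seed = seed + k)
      design$rt[sel] <- sim$rt
      design$correct[sel] <- sim$correct
      design$responded[sel] <- sim$responded
    }
  }
  # correct response side: the side demanded by the color mapping, which on
  # congruent trials equals the stimulus side and on incongruent the other
  other <- c(left = "right", right = "left")
  correct_side <- ifelse(design$congruency == "congruent", design$side,
                         other[design$side])
  design$response <- ifelse(!design$responded, "none",
                            ifelse(design$correct, correct_side,
                                   other[correct_side]))
  design$responded <- NULL
  design
}

#' Population specification for synthetic experiments
#'
#' Describes a synthetic sample: how many participants, the population
#' mean parameters for the near and far conditions, and the
#' between-participant SDs.  Individual parameters are drawn from normals
#' truncated to the fitting bounds; near and far draws of the same
#' parameter share a participant-level deviate with correlation
#' `cor_near_far` (the same people tend to be slow, cautious, etc. in both
#' conditions).
#'
#' The default SDs scale the reported condition-mean standard errors up to
#' person-level SDs (`SE * sqrt(96)` for the 96-participant samples); pass
#' `sd_near = 0, sd_far = 0` (recycled over parameters) for a homogeneous
#' population.
#'
#' @param n_participants Number of participants.
#' @param mean_near,mean_far [dmc_params()] population means.
#' @param sd_near,sd_far Named numeric vectors of SDs over the free
#'   parameters (missing names default to `SE * sqrt(96)`; a single 0
#'   recycles).
#' @param experiment 1 or 2 (design structure).
#' @param cor_near_far Correlation of near/far person deviates.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_participants,
                            mean_near = reference_params(1, "near"),
                            mean_far = reference_params(1, "far"),
                            sd_near = NULL, sd_far = NULL,
                            experiment = 1, cor_near_far = 0.8) {
  free <- c("amp", "tau", "mu_t", "bound", "res_mean", "res_sd", "sp_shape")
  expand_sd <- function(sd, ecc) {
    base <- reference_params(if (experiment == 1) 1 else 2, ecc, se = TRUE)
    base <- base[free] * sqrt(96)
    if (is.null(sd)) return(base)
    if (length(sd) == 1 && is.null(names(sd)))
      return(stats::setNames(rep(sd, length(free)), free))
    stopifnot(all(names(sd) %in% free))
    base[names(sd)] <- sd
    base
  }
  sdn <- expand_sd(sd_near, "near"); sdf <- expand_sd(sd_far, "far")
  if (any(sdn < 0) || any(sdf < 0)) stop("SDs must be >= 0")
  structure(list(n_participants = as.integer(n_participants),
                 mean_near = mean_near, mean_far = mean_far,
                 sd_near = sdn, sd_far = sdf,
                 experiment = as.integer(experiment),
                 cor_near_far = cor_near_far, free = free),
            class = "population_spec")
}

#' Draw per-participant parameter sets from a population
#'
#' @param pop A [population_spec()].
#' @param bounds_lower,bounds_upper Truncation bounds per parameter
#'   (defaults: the [fit_spec()] fitting bounds).
#' @return A list of length `n_participants`; each element has
#'   `params_near` and `params_far`.
#' @export
sample_population <- function(pop,
                              bounds_lower = fit_spec()$lower,
                              bounds_upper = fit_spec()$upper) {
  stopifnot(inherits(pop, "population_spec"))
  if (any(bounds_lower >= bounds_upper)) stop("degenerate truncation bounds")
  r <- pop$cor_near_far
  draw_one <- function() {
    # one shared person-level deviate per parameter induces the near/far
    # correlation; truncation by redrawing the condition-specific part
    z_shared <- stats::setNames(stats::rnorm(length(pop$free)), pop$free)
    out <- list()
    for (ecc in c("near", "far")) {
      m <- pop[[paste0("mean_", ecc)]]
      s <- pop[[paste0("sd_", ecc)]]
      vals <- numeric(length(pop$free)); names(vals) <- pop$free
      for (nm in pop$free) {
        for (attempt in 1:1000) {
          z2 <- stats::rnorm(1)
          v <- m[[nm]] + s[[nm]] * (r * z_shared[[nm]] + sqrt(1 - r^2) * z2)
          if (v >= bounds_lower[[nm]] && v <= bounds_upper[[nm]]) break
          if (s[[nm]] == 0) { v <- min(max(v, bounds_lower[[nm]]),
                                       bounds_upper[[nm]]); break }
        }
        vals[[nm]] <- v
      }
      out[[paste0("params_", ecc)]] <-
        do.call(dmc_params, as.list(vals))
    }
    out
  }
  lapply(seq_len(pop$n_participants), function(i) draw_one())
}

#' Generate a full synthetic experiment
#'
#' Samples a population, builds each participant's design, and simulates
#' all trials.  The result is a tidy trial table with the same structure as
#' the deposited raw data (participant, block, trial, eccentricity, side,
#' color, congruency, rt, response, correct).
#'
#' @param pop A [population_spec()].
#' @param seed Integer seed; the full table is reproducible given the seed.
#' @param counterbalance Passed to [generate_design()].
#' @return A data.frame of trials; the drawn parameter sets are attached as
#'   attribute `"population"`.
#' @export
simulate_experiment <- function(pop, seed = NULL, counterbalance = FALSE) {
  stopifnot(inherits(pop, "population_spec"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  draws <- sample_population(pop)
  tabs <- vector("list", pop$n_participants)
  for (i in seq_len(pop$n_participants)) {
    des <- generate_design(pop$experiment, participant = i,
                           counterbalance = counterbalance)
    tabs[[i]] <- simulate_participant(des, draws[[i]]$params_near,
                                      draws[[i]]$params_far,
                                      seed = sample.int(
                                        .Machine$integer.max - 8L, 1L))
  }
  out <- do.call(rbind, tabs)
  attr(out, "population") <- draws
  attr(out, "seed") <- seed
  out
}

#' Apply the standard data-preparation exclusions
#'
#' In order: (1) participants with overall accuracy below 80% are removed
#' (no-response trials count as incorrect); (2) the first two blocks are
#' dropped (practice); (3) trials without any response are dropped.  The
#' accuracy-analysis set keeps error trials; the RT-analysis set
#' additionally drops them.
#'
#' @param trials A tidy trial table (see [simulate_experiment()] /
#'   [read_trials()]).
#' @param accuracy_cutoff Participant-level accuracy threshold (default
#'   0.8).
#' @param practice_blocks Number of initial blocks to drop (default 2).
#' @return A list: `accuracy_set` (errors kept), `rt_set` (errors
#'   dropped), and `report`, a data.frame counting trials removed per
#'   exclusion category.
#' @export
apply_exclusions <- function(trials, accuracy_cutoff = 0.8,
                             practice_blocks = 2) {
  validate_trials(trials)
  n0 <- nrow(trials)
  acc <- tapply(trials$correct, trials$participant, mean)
  bad <- names(acc)[acc < accuracy_cutoff]
  keep <- !(as.character(trials$participant) %in% bad)
  t1 <- trials[keep, , drop = FALSE]
  n_excl_participant <- n0 - nrow(t1)
  t2 <- t1[t1$block > practice_blocks, , drop = FALSE]
  n_excl_practice <- nrow(t1) - nrow(t2)
  t3 <- t2[t2$response != "none", , drop = FALSE]
  n_excl_noresponse <- nrow(t2) - nrow(t3)
  if (nrow(t3) == 0) stop("no trials survive the exclusions")
  rt_set <- t3[t3$correct, , drop = FALSE]
  report <- data.frame(
    category = c("low_accuracy_participant", "practice_block",
                 "no_response", "error_trial_rt_only"),
    n_trials = c(n_excl_participant, n_excl_practice, n_excl_noresponse,
                 nrow(t3) - nrow(rt_set)),
    n_participants = c(length(bad), 0L, 0L, 0L))
  list(accuracy_set = t3, rt_set = rt_set, report = report)
}

#' Read, write and validate tidy trial tables
#'
#' Tab-separated text with a header; columns `participant`, `block`,
#' `trial`, `eccentricity`, `side`, `color`, `congruency`, `rt`,
#' `response`, `correct`.  `validate_trials()` raises an error naming the
#' offending rows for malformed values (unknown levels, negative RTs,
#' responses without RTs, and vice versa).
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `read_trials` the table; `write_trials` the path invisibly;
#'   `validate_trials` the table invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_trials(tab)
  tab
}

#' @rdname write_trials
#' @export
validate_trials <- function(trials) {
  req <- c("participant", "block", "trial", "eccentricity", "side", "color",
           "congruency", "rt", "response", "correct")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad_row <- function(ok, what) {
    if (!all(ok))
      stop("invalid trial table: ", what, " at row(s) ",
           paste(utils::head(which(!ok), 5), collapse = ", "),
           if (sum(!ok) > 5) " ..." else "")
  }
  bad_row(trials$eccentricity %in% c("near", "far"),
          "eccentricity not near/far")
  bad_row(trials$side %in% c("left", "right"), "side not left/right")
  bad_row(trials$color %in% c("red", "blue"), "color not red/blue")
  bad_row(trials$congruency %in% c("congruent", "incongruent"),
          "congruency not congruent/incongruent")
  bad_row(trials$response %in% c("left", "right", "none"),
          "response not left/right/none")
  bad_row(is.na(trials$rt) | trials$rt >= 0, "negative RT")
  bad_row(!(trials$response == "none" & !is.na(trials$rt)),
          "response 'none' with an RT")
  bad_row(!(trials$response != "none" & is.na(trials$rt)),
          "response without an RT")
  bad_row(!(trials$response == "none" & trials$correct),
          "response 'none' marked correct")
  invisible(trials)
}
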