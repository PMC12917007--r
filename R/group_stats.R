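#' Per-participant cell means
#'
#' Collapses a prepared trial table into the 2 x 2 (congruency x
#' eccentricity) cell means per participant: mean RT (ms) from the
#' RT-analysis set and percentage error from the accuracy-analysis set.
#'
#' @param prepared The list returned by [apply_exclusions()].
#' @return A data.frame with one row per participant x congruency x
#'   eccentricity: columns `participant`, `congruency`, `eccentricity`,
#'   `mean_rt`, `pe` (percentage error, 0-100).
#' @export
cell_means <- function(prepared) {
  stopifnot(is.list(prepared),
            all(c("accuracy_set", "rt_set") %in% names(prepared)))
  acc <- stats::aggregate(correct ~ participant + congruency + eccentricity,
                          data = prepared$accuracy_set, FUN = mean)
  rt <- stats::aggregate(rt ~ participant + congruency + eccentricity,
                         data = prepared$rt_set, FUN = mean)
  out <- merge(rt, acc, by = c("participant", "congruency", "eccentricity"))
  out$pe <- 100 * (1 - out$correct)
  out$correct <- NULL
  names(out)[names(out) == "rt"] <- "mean_rt"
  out[order(out$participant, out$eccentricity, out$congruency), ]
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-subjects ANOVA with two two-level factors (congruency,
#' eccentricity).  Each effect has df (1, n - 1); partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.  At 2 x 2 the interaction F equals
#' the squared paired t on the difference of congruency differences
#' between eccentricities.  When an effect's sum of squares is (numerically)
#' zero its F is reported as 0.
#'
#' @param cells A data.frame with columns `participant`, `congruency`,
#'   `eccentricity` and the measure named by `value`; one row per
#'   participant x cell, complete.
#' @param value Column to analyze (e.g. `"mean_rt"` or `"pe"`).
#' @return A data.frame with one row per effect (`congruency`,
#'   `eccentricity`, `congruency:eccentricity`): `F`, `df1`, `df2`,
#'   `p_value`, `pes` (partial eta squared).
#' @export
anova_2x2_rm <- function(cells, value = "mean_rt") {
  stopifnot(all(c("participant", "congruency", "eccentricity", value)
                %in% names(cells)))
  d <- cells
  d$participant <- factor(d$participant)
  d$congruency <- factor(d$congruency)
  d$eccentricity <- factor(d$eccentricity)
  n <- nlevels(d$participant)
  if (n < 2) stop("need at least 2 participants")
  counts <- table(d$participant, d$congruency, d$eccentricity)
  if (any(counts != 1)) stop("cells must be complete: one row per participant per cell")
  d$y <- d[[value]]
  fit <- stats::aov(y ~ congruency * eccentricity +
                      Error(participant / (congruency * eccentricity)),
                    data = d)
  sm <- summary(fit)
  effects <- c("congruency", "eccentricity", "congruency:eccentricity")
  rows <- lapply(effects, function(eff) {
    stratum <- sm[[paste0("Error: participant:", eff)]]
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    i <- match(eff, rn)
    ss_eff <- tab[i, "Sum Sq"]
    ss_err <- tab[rn == "Residuals", "Sum Sq"]
    f <- if (ss_eff <= .Machine$double.eps * max(1, ss_err)) 0
         else tab[i, "F value"]
    p <- if (f == 0) 1 else tab[i, "Pr(>F)"]
    data.frame(effect = eff, F = f, df1 = tab[i, "Df"],
               df2 = tab[rn == "Residuals", "Df"], p_value = p,
               pes = if (ss_eff + ss_err == 0) 0
                     else ss_eff / (ss_eff + ss_err))
  })
  do.call(rbind, rows)
}

#' Mean Simon effects per eccentricity
#'
#' The Simon effect is the incongruent minus congruent difference; this
#' returns its mean over participants separately for each eccentricity,
#' for mean RT (ms) and percentage error.
#'
#' @param cells Output of [cell_means()] (or any data.frame with
#'   `participant`, `congruency`, `eccentricity`, `mean_rt`, `pe`).
#' @return A data.frame: `eccentricity`, `simon_rt` (ms), `simon_pe`
#'   (percentage points).
#' @export
simon_effects <- function(cells) {
  wide <- merge(
    cells[cells$congruency == "incongruent",
          c("participant", "eccentricity", "mean_rt", "pe")],
    cells[cells$congruency == "congruent",
          c("participant", "eccentricity", "mean_rt", "pe")],
    by = c("participant", "eccentricity"), suffixes = c("_i", "_c"))
  agg <- stats::aggregate(cbind(simon_rt = mean_rt_i - mean_rt_c,
                                simon_pe = pe_i - pe_c) ~ eccentricity,
                          data = wide, FUN = mean)
  agg[order(agg$eccentricity, decreasing = TRUE), ]  # near before far
}

#' Delta-plot shift test between two conditions
#'
#' Tests whether one condition's delta plot sits above the other's across
#' the RT distribution: a paired t-test per percentile on
#' `delta_far - delta_near` (Holm-corrected over the percentile family)
#' plus an overall mean-offset paired t-test on each participant's average
#' difference across percentiles.  Swapping the condition arguments flips
#' every sign (antisymmetry).
#'
#' @param dps_near,dps_far Lists of per-participant [delta_plot()]s on a
#'   common percentile grid, same participants in the same order.
#' @return A list: `per_percentile` (data.frame with `p`, `mean_diff`,
#'   `t`, `df`, `p_value`, `p_holm`) and `overall` (one-row data.frame
#'   with `mean_offset`, `t`, `df`, `p_value`).
#' @export
delta_shift_test <- function(dps_near, dps_far) {
  stopifnot(length(dps_near) == length(dps_far), length(dps_near) >= 2)
  probs <- dps_near[[1]]$p
  get_mat <- function(dps) {
    for (d in dps)
      if (!isTRUE(all.equal(d$p, probs))) stop("percentile grids differ")
    t(vapply(dps, function(d) d$delta, numeric(length(probs))))
  }
  mn <- get_mat(dps_near)  # participants x percentiles
  mf <- get_mat(dps_far)
  diff <- mf - mn
  one_sample_t <- function(x) {
    # constant samples make t.test error; the limit is t = 0 (all zero)
    # or +/- Inf (constant nonzero shift)
    if (stats::sd(x) == 0) {
      t_stat <- if (mean(x) == 0) 0 else sign(mean(x)) * Inf
      return(data.frame(t = t_stat, df = length(x) - 1,
                        p_value = if (mean(x) == 0) 1 else 0))
    }
    tt <- stats::t.test(x)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  }
  per <- lapply(seq_along(probs), function(j) {
    cbind(data.frame(p = probs[j], mean_diff = mean(diff[, j])),
          one_sample_t(diff[, j]))
  })
  per <- do.call(rbind, per)
  per$p_holm <- stats::p.adjust(per$p_value, method = "holm")
  offsets <- rowMeans(diff)
  list(per_percentile = per,
       overall = cbind(data.frame(mean_offset = mean(offsets)),
                       one_sample_t(offsets)))
}

#' Per-participant delta plots from a prepared trial table
#'
#' Computes one [delta_plot()] per participant per eccentricity from the
#' RT-analysis set (correct trials only).
#'
#' @param rt_set The `rt_set` element of [apply_exclusions()].
#' @param probs Percentile grid.
#' @return A list with elements `near` and `far`, each a named list of
#'   `delta_plot`s keyed by participant id (same order in both).
#' @export
participant_delta_plots <- function(rt_set, probs = seq(0.1, 0.9, by = 0.1)) {
  ids <- sort(unique(rt_set$participant))
  out <- list(near = list(), far = list())
  for (ecc in c("near", "far")) {
    for (id in ids) {
      sub <- rt_set[rt_set$participant == id & rt_set$eccentricity == ecc, ]
      out[[ecc]][[as.character(id)]] <-
        delta_plot(sub$rt[sub$congruency == "congruent"],
                   sub$rt[sub$congruency == "incongruent"], probs)
    }
  }
  out
}
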