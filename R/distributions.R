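#' Empirical RT quantiles
#'
#' Quantiles of an RT sample by linear interpolation of order statistics
#' with plotting positions \eqn{p_k = (k - 0.5)/n} (`stats::quantile`
#' type 5).  This is the rule used for all CDF and delta-plot quantiles in
#' the package; it is documented here because the distributional analyses
#' are mildly sensitive to the interpolation rule at small trial counts.
#'
#' @param rts Numeric vector of RTs (ms); must be non-empty and finite.
#' @param probs Strictly increasing probabilities in (0, 1); default the
#'   nine deciles 0.1, 0.2, ..., 0.9.
#' @return Named numeric vector of quantiles.  If the sample is too small
#'   for stable estimates at the requested grid (fewer than
#'   `length(probs) + 1` observations) the result carries attribute
#'   `unstable = TRUE`.
#' @export
rt_quantiles <- function(rts, probs = seq(0.1, 0.9, by = 0.1)) {
  if (length(rts) == 0L) stop("empty RT sample")
  if (any(!is.finite(rts))) stop("RTs must be finite (drop missing first)")
  if (any(probs <= 0) || any(probs >= 1) || is.unsorted(probs, strictly = TRUE))
    stop("probs must be strictly increasing within (0, 1)")
  q <- stats::quantile(rts, probs = probs, type = 5, names = TRUE)
  if (length(rts) < length(probs) + 1L) attr(q, "unstable") <- TRUE
  q
}

#' Delta plot of the congruency effect across the RT distribution
#'
#' For each probability on the grid, the congruency effect is the
#' incongruent minus congruent quantile difference of correct RTs, plotted
#' against the average of the two quantiles.  Early-peaking distractor
#' activation yields effects that shrink (even reverse) at the slow end;
#' later peaks yield a rise-then-fall shape.
#'
#' @param cong_rts,incong_rts Correct-trial RTs (ms) for the congruent and
#'   incongruent condition.
#' @param probs Probability grid, as in [rt_quantiles()].
#' @return An object of class `delta_plot`: a data.frame with columns
#'   `p` (probability), `delta` (ms), `mean_rt` (ms).
#' @export
delta_plot <- function(cong_rts, incong_rts, probs = seq(0.1, 0.9, by = 0.1)) {
  qc <- rt_quantiles(cong_rts, probs)
  qi <- rt_quantiles(incong_rts, probs)
  out <- data.frame(p = probs, delta = unname(qi - qc),
                    mean_rt = unname((qi + qc) / 2))
  class(out) <- c("delta_plot", "data.frame")
  out
}

#' @export
print.delta_plot <- function(x, ...) {
  cat(sprintf("Delta plot (%d percentiles): mean effect %.1f ms, range %.1f to %.1f ms\n",
              nrow(x), mean(x$delta), min(x$delta), max(x$delta)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Conditional accuracy function
#'
#' Ranks responded trials by RT (stable order for ties), splits them into
#' `n_bins` bins of (as near as possible) equal counts — any remainder
#' spread over the earliest bins — and returns mean RT and proportion
#' correct per bin.  Fast errors show up as depressed accuracy in the first
#' bins, the signature of strong early distractor activation on incongruent
#' trials.
#'
#' @param trials A data.frame with columns `rt` and `correct` (e.g. from
#'   [simulate_condition()]); only rows with non-missing `rt` are used.
#' @param n_bins Number of RT bins (>= 2); default 5.
#' @return A data.frame with columns `bin`, `n`, `mean_rt`, `accuracy`.
#' @export
caf <- function(trials, n_bins = 5) {
  stopifnot(is.data.frame(trials), all(c("rt", "correct") %in% names(trials)),
            n_bins >= 2)
  keep <- !is.na(trials$rt)
  rt <- trials$rt[keep]
  correct <- trials$correct[keep]
  n <- length(rt)
  if (n < n_bins) stop("fewer trials (", n, ") than bins (", n_bins, ")")
  ord <- order(rt)  # stable: ties keep input order
  base <- n %/% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, n %% n_bins),
                                 rep(0L, n_bins - n %% n_bins))
  idx <- rep(seq_len(n_bins), times = sizes)
  data.frame(bin = seq_len(n_bins), n = sizes,
             mean_rt = as.numeric(tapply(rt[ord], idx, mean)),
             accuracy = as.numeric(tapply(correct[ord], idx, mean)))
}

#' Distributional fingerprint of one condition
#'
#' Bundles the summaries the model is fitted to: CDF quantiles of correct
#' RTs and the conditional accuracy function over all responded trials,
#' with trial counts.
#'
#' @param trials A data.frame with columns `rt`, `correct`, `responded`
#'   (rows with `responded = FALSE` or missing RT are counted but excluded
#'   from the summaries).
#' @param cdf_probs Probability grid for the correct-RT quantiles.
#' @param n_caf_bins Number of CAF bins.
#' @return An object of class `condition_summary` with fields
#'   `cdf_probs`, `cdf_quantiles`, `caf` (data.frame), `n_trials`
#'   (responded), `n_correct`.
#' @export
summarize_condition <- function(trials, cdf_probs = seq(0.1, 0.9, by = 0.1),
                                n_caf_bins = 5) {
  stopifnot(is.data.frame(trials), all(c("rt", "correct") %in% names(trials)))
  responded <- !is.na(trials$rt)
  trials <- trials[responded, , drop = FALSE]
  if (!any(trials$correct)) stop("no correct trials to summarize")
  structure(list(
    cdf_probs = cdf_probs,
    cdf_quantiles = unname(rt_quantiles(trials$rt[trials$correct], cdf_probs)),
    caf = caf(trials, n_caf_bins),
    n_trials = nrow(trials),
    n_correct = sum(trials$correct)), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition summary: %d responded trials, %d correct (%.1f%%)\n",
              x$n_trials, x$n_correct, 100 * x$n_correct / x$n_trials))
  cat("  CDF quantiles (ms):",
      paste(sprintf("%.0f", x$cdf_quantiles), collapse = " "), "\n")
  cat("  CAF accuracy:",
      paste(sprintf("%.3f", x$caf$accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Group-average delta plot
#'
#' Averages per-participant delta plots percentile-wise: the group delta at
#' each probability is the mean of the participants' deltas, and likewise
#' for the abscissa (quantile-average RT).  Location shifts shared by all
#' participants therefore survive averaging exactly.
#'
#' @param dps A list of [delta_plot()] objects on a common probability grid.
#' @return A `delta_plot` data.frame with an `n_participants` attribute.
#' @export
group_delta_plot <- function(dps) {
  stopifnot(length(dps) >= 1)
  probs <- dps[[1]]$p
  for (d in dps)
    if (!isTRUE(all.equal(d$p, probs)))
      stop("delta plots are not on a common probability grid")
  out <- data.frame(
    p = probs,
    delta = rowMeans(vapply(dps, function(d) d$delta, numeric(length(probs)))),
    mean_rt = rowMeans(vapply(dps, function(d) d$mean_rt,
                              numeric(length(probs)))))
  class(out) <- c("delta_plot", "data.frame")
  attr(out, "n_participants") <- length(dps)
  out
}

#' Write a condition summary or delta plot as a delimited table
#'
#' One row per percentile or bin, tab-separated, for plotting and
#' regression tests.
#'
#' @param x A `condition_summary` or `delta_plot` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  if (inherits(x, "condition_summary")) {
    tab <- data.frame(p = x$cdf_probs, cdf_quantile = x$cdf_quantiles)
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(x$caf, paste0(path, ".caf"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "delta_plot")) {
    utils::write.table(as.data.frame(x), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
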