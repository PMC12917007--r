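# Independent oracles: deliberately simple, self-contained implementations
# used to cross-check the package.  They share no code with R/ or src/.

# gamma-pulse drift for shape 2, from the closed form
# (A/tau) * exp(1 - t/tau) * (1 - t/tau)
oracle_drift_a2 <- function(t, amp, tau) {
  (amp / tau) * exp(1 - t / tau) * (1 - t / tau)
}

# straight-loop diffusion simulator using R's RNG; matrix cumsum over a
# fixed step grid, first boundary crossing per row
oracle_simulate <- function(p, congruency, n) {
  sgn <- if (congruency == "congruent") 1 else -1
  n_steps <- ceiling(p$t_max / p$dt)
  tgrid <- (seq_len(n_steps) - 1) * p$dt
  act <- p$amp * exp(-tgrid / p$tau) *
    (tgrid * exp(1) / ((p$aa_shape - 1) * p$tau))^(p$aa_shape - 1)
  dr <- ifelse(tgrid > 0,
               act * ((p$aa_shape - 1) / pmax(tgrid, 1e-12) - 1 / p$tau),
               if (p$aa_shape == 2) p$amp * exp(1) / p$tau else 0)
  drift <- sgn * dr + ifelse(tgrid >= p$onset_delay, p$mu_t, 0)
  start <- (2 * rbeta(n, p$sp_shape, p$sp_shape) - 1) * p$bound
  inc <- matrix(rnorm(n * n_steps, mean = rep(drift * p$dt, each = n),
                      sd = p$sigma * sqrt(p$dt)), n, n_steps)
  paths <- start + t(apply(inc, 1, cumsum))
  res <- data.frame(decision_time = rep(NA_real_, n), rt = NA_real_,
                    correct = FALSE, responded = FALSE)
  for (i in seq_len(n)) {
    hit <- which(paths[i, ] >= p$bound | paths[i, ] <= -p$bound)
    if (length(hit)) {
      k <- hit[1]
      res$responded[i] <- TRUE
      res$correct[i] <- paths[i, k] >= p$bound
      res$decision_time[i] <- k * p$dt
      res$rt[i] <- k * p$dt + max(0, rnorm(1, p$res_mean, p$res_sd))
    }
  }
  res
}

# type-5 quantiles written out longhand: linear interpolation of order
# statistics with plotting positions (k - 0.5)/n
oracle_quantile <- function(x, probs) {
  x <- sort(x)
  n <- length(x)
  vapply(probs, function(p) {
    h <- n * p + 0.5
    if (h <= 1) return(x[1])
    if (h >= n) return(x[n])
    lo <- floor(h)
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }, 0)
}

# brute-force CAF: stable RT order, equal-count bins, remainder to the
# earliest bins
oracle_caf <- function(rt, correct, n_bins) {
  ord <- order(rt)
  n <- length(rt)
  sizes <- rep(n %/% n_bins, n_bins)
  if (n %% n_bins > 0) sizes[seq_len(n %% n_bins)] <- sizes[seq_len(n %% n_bins)] + 1
  res <- data.frame(mean_rt = numeric(n_bins), accuracy = numeric(n_bins))
  pos <- 0
  for (b in seq_len(n_bins)) {
    idx <- ord[(pos + 1):(pos + sizes[b])]
    res$mean_rt[b] <- mean(rt[idx])
    res$accuracy[b] <- mean(correct[idx])
    pos <- pos + sizes[b]
  }
  res
}

# textbook sums-of-squares for a 2x2 within-subjects ANOVA; y indexed by
# [participant, a, b]
oracle_anova_2x2 <- function(y) {
  n <- dim(y)[1]
  grand <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_ab <- apply(y, c(2, 3), mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_sa <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_b) + grand)^2)
  resid <- y
  for (i in 1:n) for (a in 1:2) for (b in 1:2)
    resid[i, a, b] <- y[i, a, b] - m_ab[a, b] - m_sa[i, a] - m_sb[i, b] +
      m_a[a] + m_b[b] + m_s[i] - grand
  ss_sab <- sum(resid^2)
  list(
    F_a = (ss_a / 1) / (ss_sa / (n - 1)),
    F_b = (ss_b / 1) / (ss_sb / (n - 1)),
    F_ab = (ss_ab / 1) / (ss_sab / (n - 1)),
    pes_a = ss_a / (ss_a + ss_sa),
    pes_b = ss_b / (ss_b + ss_sb),
    pes_ab = ss_ab / (ss_ab + ss_sab))
}

# small complete trial table for exclusion tests
make_toy_trials <- function() {
  grid <- expand.grid(participant = 1:3, block = 1:4, trial = 1:4)
  grid <- grid[order(grid$participant, grid$block, grid$trial), ]
  n <- nrow(grid)
  grid$eccentricity <- rep(c("near", "far"), length.out = n)
  grid$side <- rep(c("left", "right"), length.out = n)
  grid$color <- ifelse(grid$side == "left", "red", "blue")
  grid$congruency <- "congruent"
  grid$rt <- 400 + seq_len(n)
  grid$response <- grid$side
  grid$correct <- TRUE
  rownames(grid) <- NULL
  grid
}
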