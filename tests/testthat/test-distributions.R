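test_that("rt_quantiles interpolates order statistics as documented", {
  rts <- seq(100, 900, by = 100)
  q <- rt_quantiles(rts)
  # hand-computed: h = 9p + 0.5 on the sorted sample
  expect_equal(as.vector(q), c(140, 230, 320, 410, 500, 590, 680, 770, 860))
  expect_equal(unname(q["50%"]), 500)
  # constants, shifts, permutations
  expect_equal(unname(rt_quantiles(rep(42, 20))), rep(42, 9))
  expect_equal(as.vector(rt_quantiles(rts + 30)), as.vector(q) + 30)
  set.seed(1)
  expect_equal(rt_quantiles(sample(rts)), q)
  expect_error(rt_quantiles(numeric(0)), "empty")
  expect_error(rt_quantiles(c(1, NA)), "finite")
  expect_true(isTRUE(attr(rt_quantiles(1:5), "unstable")))
  expect_null(attr(rt_quantiles(1:50), "unstable"))
})

test_that("quantile routine matches the longhand oracle on many small samples", {
  set.seed(42)
  probs <- seq(0.1, 0.9, by = 0.1)
  for (n in 2:12) {
    for (rep in 1:20) {
      x <- sample(1:6, n, replace = TRUE) * 10 + round(runif(n), 2)
      expect_equal(as.vector(rt_quantiles(x, probs)),
                   oracle_quantile(x, probs), tolerance = 1e-12)
    }
  }
})

test_that("delta plots measure quantile-wise congruency differences", {
  set.seed(5)
  x <- rgamma(200, 8, 0.02) + 200
  # identical samples: zero everywhere
  d0 <- delta_plot(x, x)
  expect_equal(d0$delta, rep(0, 9))
  # pure shift: delta constant at the shift, abscissa moves by half
  d30 <- delta_plot(x, x + 30)
  expect_equal(d30$delta, rep(30, 9))
  expect_equal(d30$mean_rt, unname(rt_quantiles(x)) + 15)
  expect_true(all(diff(d30$mean_rt) >= 0))
  # 20-point fixture against the longhand oracle
  cong <- c(312, 345, 356, 367, 380, 391, 402, 410, 425, 431,
            447, 459, 470, 488, 501, 520, 544, 570, 603, 655)
  incg <- c(330, 352, 380, 391, 399, 410, 428, 441, 456, 470,
            480, 497, 510, 525, 546, 560, 588, 610, 640, 690)
  d <- delta_plot(cong, incg)
  probs <- seq(0.1, 0.9, by = 0.1)
  expect_equal(d$delta,
               oracle_quantile(incg, probs) - oracle_quantile(cong, probs))
  expect_equal(d$mean_rt,
               (oracle_quantile(incg, probs) + oracle_quantile(cong, probs)) / 2)
})

test_that("caf bins by rank with remainder spread over early bins", {
  # 10 trials, 5 bins, errors exactly the two fastest
  tr <- data.frame(rt = c(310, 320, 400, 410, 420, 430, 440, 450, 460, 470),
                   correct = c(FALSE, FALSE, rep(TRUE, 8)))
  out <- caf(tr, n_bins = 5)
  expect_equal(out$accuracy, c(0, 1, 1, 1, 1))
  expect_equal(out$n, rep(2L, 5))
  expect_equal(out$mean_rt[1], 315)
  # all correct
  expect_equal(caf(data.frame(rt = 1:12, correct = TRUE), 4)$accuracy,
               rep(1, 4))
  # rank-based: invariant to adding a constant to all RTs
  set.seed(6)
  tr2 <- data.frame(rt = runif(53, 300, 700),
                    correct = runif(53) > 0.2)
  expect_equal(caf(tr2, 5)$accuracy,
               caf(transform(tr2, rt = rt + 1000), 5)$accuracy)
  # remainder handling and agreement with the brute-force oracle
  for (n_bins in c(2, 3, 5, 7)) {
    got <- caf(tr2, n_bins)
    ora <- oracle_caf(tr2$rt, tr2$correct, n_bins)
    expect_equal(got$accuracy, ora$accuracy)
    expect_equal(got$mean_rt, ora$mean_rt)
    expect_equal(sum(got$n), nrow(tr2))
  }
  expect_error(caf(tr[1:3, ], 5), "fewer trials")
})

test_that("summarize_condition bundles CDF and CAF with counts", {
  set.seed(7)
  tr <- data.frame(rt = c(runif(80, 300, 700), NA, NA),
                   correct = c(runif(80) > 0.1, FALSE, FALSE),
                   responded = c(rep(TRUE, 80), FALSE, FALSE))
  s <- summarize_condition(tr)
  expect_s3_class(s, "condition_summary")
  expect_equal(s$n_trials, 80)
  expect_equal(s$n_correct, sum(tr$correct[1:80]))
  expect_equal(s$cdf_quantiles,
               oracle_quantile(tr$rt[1:80][tr$correct[1:80]],
                               seq(0.1, 0.9, 0.1)))
  expect_equal(s$caf$accuracy, oracle_caf(tr$rt[1:80], tr$correct[1:80],
                                          5)$accuracy)
  # error-free condition: n_correct equals n_trials
  clean <- data.frame(rt = runif(40, 300, 500), correct = TRUE,
                      responded = TRUE)
  expect_equal(summarize_condition(clean)$n_correct, 40)
  expect_error(summarize_condition(data.frame(rt = 1:5, correct = FALSE,
                                              responded = TRUE)),
               "no correct")
})

test_that("group delta plots preserve shared shifts exactly", {
  set.seed(8)
  dps <- lapply(1:6, function(i) {
    x <- rnorm(150, 450, 60) + i * 5
    delta_plot(x, x + 30)
  })
  g <- group_delta_plot(dps)
  expect_equal(g$delta, rep(30, 9))
  expect_equal(attr(g, "n_participants"), 6)
  bad <- delta_plot(rnorm(50, 400, 40), rnorm(50, 430, 40),
                    probs = c(0.25, 0.5, 0.75))
  expect_error(group_delta_plot(c(dps, list(bad))), "common probability grid")
})
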