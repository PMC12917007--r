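make_obs_pair <- function(seed = 101, n = 400, p = demo_params(tau = 30)) {
  list(congruent = summarize_condition(
         simulate_condition(p, "congruent", n, seed = seed)),
       incongruent = summarize_condition(
         simulate_condition(p, "incongruent", n, seed = seed + 1)))
}

test_that("cost_rmse pools CDF and weighted CAF residuals", {
  obs <- make_obs_pair()
  expect_equal(cost_rmse(obs, obs), 0)
  # single CDF point off by 3 ms: sqrt(9 / n_points), n = 18 + 10
  pred <- obs
  pred$congruent$cdf_quantiles[4] <- pred$congruent$cdf_quantiles[4] + 3
  expect_equal(cost_rmse(obs, pred), sqrt(9 / 28))
  # doubling the CAF weight cannot decrease the cost with a CAF residual
  pred2 <- obs
  pred2$incongruent$caf$accuracy[1] <- pred2$incongruent$caf$accuracy[1] - 0.05
  expect_gt(cost_rmse(obs, pred2, caf_weight = 400),
            cost_rmse(obs, pred2, caf_weight = 200))
  # grid mismatch
  bad <- make_obs_pair()
  bad$congruent$cdf_probs <- seq(0.05, 0.95, length.out = 9)
  expect_error(cost_rmse(obs, bad), "grids do not match")
})

test_that("predict_summaries is seed-deterministic and converges with n", {
  p <- demo_params(tau = 30)
  spec <- fit_spec(n_sim_trials = 800)
  a <- predict_summaries(p, spec, seed = 9)
  b <- predict_summaries(p, spec, seed = 9)
  expect_identical(a, b)
  # successive-seed quantile differences shrink roughly as 1/sqrt(n)
  spread <- function(n_sim) {
    sp <- fit_spec(n_sim_trials = n_sim)
    qs <- vapply(1:6, function(s)
      predict_summaries(p, sp, seed = 100 + s)$congruent$cdf_quantiles[5], 0)
    sd(qs)
  }
  expect_lt(spread(6400), spread(400))
  # amp = 0: congruent and incongruent statistically indistinguishable
  p0 <- update_params(p, amp = 0)
  big <- predict_summaries(p0, fit_spec(n_sim_trials = 20000), seed = 11)
  expect_lt(max(abs(big$congruent$cdf_quantiles -
                      big$incongruent$cdf_quantiles)), 10)
})

test_that("compiled cost path equals the R reference path exactly", {
  p <- reference_params(1, "far")
  spec <- fit_spec(n_sim_trials = 1000)
  obs <- make_obs_pair(n = 300, p = update_params(p, mu_t = 0.5))
  r_cost <- cost_rmse(obs, predict_summaries(p, spec, seed = 321),
                      spec$caf_weight)
  c_cost <- simondmc:::.dmc_cost_cpp(
    p$amp, p$tau, p$aa_shape, p$mu_t, p$sigma, p$bound, p$res_mean,
    p$res_sd, p$sp_shape, p$onset_delay, p$dt, p$t_max, spec$cdf_probs,
    spec$n_caf_bins, spec$caf_weight,
    obs$congruent$cdf_quantiles, obs$incongruent$cdf_quantiles,
    obs$congruent$caf$accuracy, obs$incongruent$caf$accuracy,
    spec$n_sim_trials, 321, spec$antithetic)
  expect_equal(c_cost, r_cost, tolerance = 1e-12)
})

test_that("differential evolution minimizes simple deterministic objectives", {
  set.seed(10)
  sphere <- function(x) sum((x - c(1, -2, 3))^2)
  res <- simondmc:::.de_optimize(sphere, lower = rep(-5, 3),
                                 upper = rep(5, 3), pop_size = 30,
                                 max_gen = 200, cr = 0.9, rel_tol = 0,
                                 stall_gen = 200)
  expect_lt(res$value, 1e-4)
  expect_equal(res$par, c(1, -2, 3), tolerance = 0.01)
  # respects bounds when the optimum lies outside
  res2 <- simondmc:::.de_optimize(function(x) sum((x - 10)^2),
                                  lower = 0, upper = 2, pop_size = 15,
                                  max_gen = 100, cr = 0.9, rel_tol = 0,
                                  stall_gen = 100)
  expect_equal(res2$par, 2, tolerance = 1e-6)
})

test_that("fit_condition runs end to end, deterministically given a seed", {
  p <- demo_params(tau = 30)
  trials <- rbind(
    cbind(simulate_condition(p, "congruent", 90, seed = 61)),
    cbind(simulate_condition(p, "incongruent", 150, seed = 62)))
  spec <- fit_spec(n_sim_trials = 500, pop_size = 14, max_gen = 8,
                   stall_gen = 8)
  expect_warning(f1 <- fit_condition(trials, spec, seed = 5), "unstable")
  expect_s3_class(f1, "fit_result")
  expect_true(is.finite(f1$rmse) && f1$rmse >= 0)
  est <- unlist(f1$params[spec$free])
  expect_true(all(est >= spec$lower - 1e-12 & est <= spec$upper + 1e-12))
  expect_warning(f2 <- fit_condition(trials, spec, seed = 5))
  expect_equal(f1$params, f2$params)
  expect_equal(f1$rmse, f2$rmse)
})

test_that("paired parameter comparisons follow textbook arithmetic", {
  mk_fit <- function(mu) {
    structure(list(params = update_params(demo_params(), mu_t = mu),
                   spec = fit_spec()), class = "fit_result")
  }
  a <- lapply(c(0.5, 0.6, 0.7), mk_fit)
  # identical vectors: t undefined but d and diff are 0
  same <- compare_fitted_params(a, a, "mu_t")
  expect_equal(same$mean_diff, 0)
  expect_equal(same$cohens_d, 0)
  # differences {1, 2, 3}: mean 2, sd 1, t = 2 sqrt(3), d = 2
  b <- lapply(c(0.5 - 1, 0.6 - 2, 0.7 - 3), function(m)
    structure(list(params = list(mu_t = m), spec = fit_spec()),
              class = "fit_result"))
  cmp <- compare_fitted_params(a, b, "mu_t")
  expect_equal(cmp$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(cmp$cohens_d, 2)
  expect_equal(cmp$df, 2)
  # antisymmetry
  rev <- compare_fitted_params(b, a, "mu_t")
  expect_equal(rev$t, -cmp$t)
  expect_error(compare_fitted_params(a[1], b[1], "mu_t"), "at least 2")
})
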