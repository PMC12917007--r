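make_cells <- function(y) {
  # y: participants x congruency(c,i) x eccentricity(near,far)
  n <- dim(y)[1]
  expand.grid(participant = seq_len(n),
              congruency = c("congruent", "incongruent"),
              eccentricity = c("near", "far"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(mean_rt = as.vector(y))
}

test_that("repeated-measures ANOVA matches the longhand sums-of-squares oracle", {
  set.seed(11)
  y <- array(450 + rnorm(4 * 2 * 2, sd = 20), dim = c(4, 2, 2))
  y[, 2, ] <- y[, 2, ] + 25          # congruency effect
  y[, 2, 2] <- y[, 2, 2] + 10        # interaction
  cells <- make_cells(y)
  got <- anova_2x2_rm(cells, "mean_rt")
  ora <- oracle_anova_2x2(y)
  expect_equal(got$F[got$effect == "congruency"], ora$F_a,
               tolerance = 1e-10)
  expect_equal(got$F[got$effect == "eccentricity"], ora$F_b,
               tolerance = 1e-10)
  expect_equal(got$F[got$effect == "congruency:eccentricity"], ora$F_ab,
               tolerance = 1e-10)
  expect_equal(got$pes, c(ora$pes_a, ora$pes_b, ora$pes_ab),
               tolerance = 1e-10)
  expect_equal(got$df1, rep(1, 3))
  expect_equal(got$df2, rep(3, 3))
})

test_that("interaction F equals the squared paired t on difference-of-differences", {
  set.seed(12)
  y <- array(500 + rnorm(24, sd = 30), dim = c(6, 2, 2))
  cells <- make_cells(y)
  got <- anova_2x2_rm(cells, "mean_rt")
  dd <- (y[, 2, 2] - y[, 1, 2]) - (y[, 2, 1] - y[, 1, 1])
  tt <- t.test(dd)
  expect_equal(got$F[got$effect == "congruency:eccentricity"],
               unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p_value[got$effect == "congruency:eccentricity"],
               tt$p.value, tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs give zero effects, incomplete cells error", {
  y <- array(rep(c(430, 470, 450, 480), each = 5), dim = c(5, 2, 2))
  y[] <- y + rnorm(20, sd = 1e-9)  # numerically flat participant noise
  flat <- make_cells(array(rep(rowMeans(y), 4), dim = c(5, 2, 2)))
  got <- anova_2x2_rm(flat, "mean_rt")
  expect_equal(got$F, rep(0, 3))
  cells <- make_cells(y)
  expect_error(anova_2x2_rm(cells[-1, ], "mean_rt"), "complete")
  expect_error(anova_2x2_rm(cells[cells$participant == 1, ], "mean_rt"),
               "at least 2")
})

test_that("simon_effects returns per-eccentricity congruency differences", {
  y <- array(0, dim = c(3, 2, 2))
  y[, 1, ] <- c(400, 420, 440)           # congruent near/far identical
  y[, 2, 1] <- c(425, 445, 465)          # +25 near
  y[, 2, 2] <- c(435, 455, 475)          # +35 far
  cells <- make_cells(y)
  cells$pe <- 0
  se <- simon_effects(cells)
  expect_equal(se$simon_rt[se$eccentricity == "near"], 25)
  expect_equal(se$simon_rt[se$eccentricity == "far"], 35)
  expect_equal(se$simon_pe, c(0, 0))
  # congruent == incongruent everywhere: zero effect
  cells0 <- make_cells(array(rep(c(400, 410, 420), 4), dim = c(3, 2, 2)))
  cells0$pe <- 3
  expect_equal(simon_effects(cells0)$simon_rt, c(0, 0))
  # averaging RT Simon effects over eccentricities equals the congruency
  # main-effect contrast
  set.seed(13)
  yr <- array(450 + rnorm(32, sd = 15), dim = c(8, 2, 2))
  cr <- make_cells(yr); cr$pe <- 0
  se2 <- simon_effects(cr)
  expect_equal(mean(se2$simon_rt),
               mean(yr[, 2, ]) - mean(yr[, 1, ]), tolerance = 1e-12)
})

test_that("delta shift test detects offsets and is antisymmetric", {
  set.seed(14)
  dps_near <- lapply(1:8, function(i) {
    x <- rnorm(200, 450, 50)
    delta_plot(x, x + 20 + rnorm(1, 0, 2))
  })
  dps_far <- lapply(1:8, function(i) {
    x <- rnorm(200, 470, 50)
    delta_plot(x, x + 30 + rnorm(1, 0, 2))
  })
  st <- delta_shift_test(dps_near, dps_far)
  expect_gt(st$overall$mean_offset, 0)
  expect_lt(st$overall$p_value, 0.05)
  expect_equal(nrow(st$per_percentile), 9)
  expect_true(all(st$per_percentile$p_holm >= st$per_percentile$p_value))
  # exact +10 shift for every participant/percentile
  shifted <- lapply(dps_near, function(d) {
    d$delta <- d$delta + 10
    d
  })
  st10 <- delta_shift_test(dps_near, shifted)
  expect_equal(st10$overall$mean_offset, 10, tolerance = 1e-12)
  expect_true(all(st10$per_percentile$mean_diff == 10))
  # identical conditions: offset exactly 0
  st0 <- delta_shift_test(dps_near, dps_near)
  expect_equal(st0$overall$mean_offset, 0)
  # antisymmetry
  rev <- delta_shift_test(dps_far, dps_near)
  expect_equal(rev$overall$mean_offset, -st$overall$mean_offset)
  expect_equal(rev$per_percentile$t, -st$per_percentile$t)
})

test_that("cell means aggregate RT and PE per participant and cell", {
  toy <- make_toy_trials()
  # period 4 against the period-2 eccentricity so all four cells occur
  toy$congruency <- rep(c("congruent", "congruent", "incongruent",
                          "incongruent"), length.out = nrow(toy))
  err <- which(toy$participant == 1 & toy$block == 3 &
                 toy$congruency == "incongruent")[1]
  toy$correct[err] <- FALSE
  prep <- apply_exclusions(toy, practice_blocks = 2)
  cm <- cell_means(prep)
  expect_equal(nrow(cm), 3 * 4)
  row <- cm[cm$participant == 1 & cm$congruency == "incongruent" &
              cm$eccentricity == toy$eccentricity[err], ]
  expect_gt(row$pe, 0)
  # RT means use correct trials only: verify every cell against a direct
  # aggregation of the RT-analysis set
  for (k in seq_len(nrow(cm))) {
    sub <- prep$rt_set[prep$rt_set$participant == cm$participant[k] &
                         prep$rt_set$congruency == cm$congruency[k] &
                         prep$rt_set$eccentricity == cm$eccentricity[k], ]
    expect_equal(cm$mean_rt[k], mean(sub$rt))
  }
})
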