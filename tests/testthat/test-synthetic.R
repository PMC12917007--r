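test_that("within-block design balances all eight displays in every block", {
  set.seed(1)
  des <- generate_design(1, participant = 3)
  expect_equal(nrow(des), 672)  # 12 x 56
  for (b in unique(des$block)) {
    blk <- des[des$block == b, ]
    expect_equal(nrow(blk), 56)
    counts <- table(blk$color, blk$side, blk$eccentricity)
    expect_true(all(counts == 7))
  }
  # congruency follows the color mapping: red -> left, blue -> right
  expect_true(all((des$congruency == "congruent") ==
                    (ifelse(des$color == "red", "left", "right") == des$side)))
  expect_error(generate_design(1, trials_per_block = 50), "divisible")
})

test_that("between-block design alternates eccentricity with parity counterbalance", {
  set.seed(2)
  odd <- generate_design(2, participant = 1)
  evn <- generate_design(2, participant = 2)
  ecc_by_block <- function(d) vapply(split(d$eccentricity, d$block),
                                     function(e) unique(e), "")
  expect_equal(unname(ecc_by_block(odd)),
               rep(c("near", "far"), 6))
  expect_equal(unname(ecc_by_block(evn)),
               rep(c("far", "near"), 6))
  for (b in unique(odd$block)) {
    blk <- odd[odd$block == b, ]
    expect_true(all(table(blk$color, blk$side) == 14))
  }
})

test_that("simulated participants respect eccentricity-specific parameters", {
  near <- reference_params(1, "near")
  far_slow <- update_params(near, mu_t = 0.40)
  set.seed(3)
  des <- generate_design(1, participant = 1)
  tab <- simulate_participant(des, near, far_slow, seed = 77)
  expect_true(all(c("rt", "response", "correct") %in% names(tab)))
  validate_trials(tab)
  ok <- !is.na(tab$rt)
  expect_gt(mean(tab$rt[ok & tab$eccentricity == "far"]),
            mean(tab$rt[ok & tab$eccentricity == "near"]))
  # byte-identical given the seed
  set.seed(3)
  des2 <- generate_design(1, participant = 1)
  tab2 <- simulate_participant(des2, near, far_slow, seed = 77)
  expect_identical(tab, tab2)
  # correct response side matches the mapping on correct trials
  corr <- tab[tab$correct, ]
  mapped <- ifelse(corr$color == "red", "left", "right")
  expect_true(all(corr$response == mapped))
})

test_that("population sampling honors SDs, truncation and zero-variance limits", {
  pop0 <- population_spec(5, sd_near = 0, sd_far = 0)
  set.seed(4)
  draws <- sample_population(pop0)
  for (d in draws) {
    expect_equal(d$params_near, reference_params(1, "near"))
    expect_equal(d$params_far, reference_params(1, "far"))
  }
  pop <- population_spec(40)
  set.seed(5)
  draws <- sample_population(pop)
  lo <- fit_spec()$lower; hi <- fit_spec()$upper
  for (d in draws) {
    v <- unlist(d$params_near[names(lo)])
    expect_true(all(v >= lo & v <= hi))
  }
  # default SDs scale the reported SEs to person level: SD(mu_t) ~ 0.02*sqrt(96)
  mus <- vapply(draws, function(d) d$params_near$mu_t, 0)
  expect_gt(sd(mus), 0.05)
  expect_lt(sd(mus), 0.5)
})

test_that("exclusion rules match hand enumeration and are idempotent", {
  toy <- make_toy_trials()  # 3 participants x 4 blocks x 4 trials, all correct
  # participant 3: accuracy 75% (< 80%): 4 of 16 trials wrong
  toy$correct[toy$participant == 3][1:4] <- FALSE
  # participant 1: two no-response trials in block 3
  sel <- which(toy$participant == 1 & toy$block == 3)[1:2]
  toy$response[sel] <- "none"; toy$rt[sel] <- NA; toy$correct[sel] <- FALSE
  # participant 2: one error in block 4
  err <- which(toy$participant == 2 & toy$block == 4)[1]
  toy$correct[err] <- FALSE
  prep <- apply_exclusions(toy, practice_blocks = 2)
  # hand counts: p3 removed (16); blocks 1-2 of p1, p2 removed (16);
  # two no-response trials removed; 14 remain; RT set drops 1 error
  expect_equal(nrow(prep$accuracy_set), 14)
  expect_equal(nrow(prep$rt_set), 13)
  expect_equal(prep$report$n_trials,
               c(16, 16, 2, 1))
  expect_equal(prep$report$n_participants[1], 1)
  expect_false(3 %in% prep$accuracy_set$participant)
  # idempotent on its own output
  again <- apply_exclusions(prep$accuracy_set, practice_blocks = 2)
  expect_equal(again$accuracy_set, prep$accuracy_set)
  expect_equal(sum(again$report$n_trials[1:3]), 0)
  # report sums account for all removed trials
  expect_equal(nrow(toy) - nrow(prep$accuracy_set),
               sum(prep$report$n_trials[1:3]))
})

test_that("an error-free dataset gives identical accuracy and RT sets", {
  toy <- make_toy_trials()
  prep <- apply_exclusions(toy, practice_blocks = 2)
  expect_equal(prep$accuracy_set, prep$rt_set)
  expect_true(all(prep$accuracy_set$block > 2))
})

test_that("trial tables round-trip and the validator pinpoints bad rows", {
  toy <- make_toy_trials()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(toy, path)
  back <- read_trials(path)
  expect_equal(back$rt, toy$rt)
  expect_equal(back$congruency, toy$congruency)
  bad <- toy
  bad$eccentricity[5] <- "middle"
  expect_error(validate_trials(bad), "row\\(s\\) 5")
  bad2 <- toy
  bad2$rt[3] <- NA  # response recorded but no RT
  expect_error(validate_trials(bad2), "without an RT")
  expect_error(validate_trials(toy[, -1]), "lacks columns: participant")
})
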