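scores_frame <- function(team, score_a, score_b, correct_a = NULL,
                         wrong_a = NULL, correct_b = NULL, wrong_b = NULL) {
  n <- length(team)
  data.frame(pair_id = 1L, trial = seq_len(n),
             correct_a = correct_a %||% pmax(score_a, 0),
             wrong_a = wrong_a %||% pmax(-score_a, 0),
             correct_b = correct_b %||% pmax(score_b, 0),
             wrong_b = wrong_b %||% pmax(-score_b, 0),
             score_a = score_a, score_b = score_b, team = team,
             n_shared = 0L, overlap = 0)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("moving average and peak use valid windows only", {
  expect_equal(moving_average(1:5, 2), c(1.5, 2.5, 3.5, 4.5))
  expect_length(moving_average(rep(1, 100), 20), 81L)
  # constant series: every window mean is the constant
  expect_equal(smoothed_peak(rep(2.5, 30), 20), 2.5)
  # a 20-trial spike of 2.0 inside 100 trials of 1.0 is caught exactly
  x <- rep(1, 100); x[40:59] <- 2
  expect_equal(smoothed_peak(x, 20), 2)
  # ramp 1..100: peak is the mean of the last window
  expect_equal(smoothed_peak(1:100, 20), mean(81:100))
  expect_error(smoothed_peak(1:5, 20), "shorter than the smoothing window")
})

test_that("smoothed_peak ignores appended values below the minimum window mean", {
  set.seed(1)
  x <- runif(60, 1, 2)
  p <- smoothed_peak(x, 20)
  low <- min(moving_average(x, 20)) - 1
  expect_equal(smoothed_peak(c(x, rep(low, 15)), 20), p)
})

test_that("collective ratios divide team by the per-trial better member", {
  sc <- scores_frame(team = c(5L, 4L), score_a = c(3L, 2L),
                     score_b = c(2L, 4L))
  b <- collective_ratio_series(sc, window = 2)
  expect_equal(b$raw, c(5 / 3, 4 / 4))
  expect_equal(b$peak, mean(c(5 / 3, 1)))
  expect_identical(b$n_excluded, 0L)
  # identical selections every trial: team equals each member, all ratios 1
  tr <- list(target_ids = 1:6, distractor_ids = 7:19,
             selections_a = 1:3, selections_b = 1:3)
  sc2 <- score_session(make_session(rep(list(tr), 25)))
  b2 <- collective_ratio_series(sc2, window = 20)
  expect_true(all(b2$raw == 1))
  expect_equal(b2$peak, 1)
})

test_that("non-positive denominators follow the exclusion policy", {
  sc <- scores_frame(team = c(5L, 3L, 4L, 2L, 6L),
                     score_a = c(3L, 0L, 2L, -1L, 3L),
                     score_b = c(2L, -2L, 2L, 0L, 2L))
  b <- collective_ratio_series(sc, window = 2)
  expect_identical(b$n_excluded, 2L)
  expect_equal(b$raw, c(5 / 3, 4 / 2, 6 / 3))
  # all trials excluded: benefit undefined
  sc_bad <- scores_frame(team = c(1L, 1L), score_a = c(0L, -1L),
                         score_b = c(-1L, 0L))
  expect_error(collective_ratio_series(sc_bad, window = 1), "undefined")
  # session-level better member variant uses one denominator throughout
  b_sess <- collective_ratio_series(
    scores_frame(team = c(5L, 4L), score_a = c(3L, 1L),
                 score_b = c(2L, 2L)),
    window = 1, better = "session")
  expect_equal(b_sess$raw, c(5 / 2, 4 / 2))
})

test_that("the analytic null expectation matches hand-computed cases", {
  expect_equal(expected_null_team_score(3, 0, 3, 0, 6, 13),
               6 * (1 - (1 - 3 / 6)^2)) # = 4.5
  expect_equal(expected_null_team_score(0, 0, 0, 0, 6, 13), 0)
  expect_equal(expected_null_team_score(6, 0, 6, 0, 6, 13), 6)
  # distractor term enters negatively
  expect_equal(expected_null_team_score(0, 2, 0, 3, 6, 13),
               -(13 * (1 - (1 - 2 / 13) * (1 - 3 / 13))))
  expect_error(expected_null_team_score(7, 0, 0, 0, 6, 13), "exceed")
  expect_error(expected_null_team_score(0, 14, 0, 0, 6, 13), "exceed")
})

test_that("Monte-Carlo null is deterministic, exact at the corners, and unbiased", {
  expect_identical(null_team_score(3, 1, 2, 0, 6, 13, n_reps = 500, seed = 1),
                   null_team_score(3, 1, 2, 0, 6, 13, n_reps = 500, seed = 1))
  # nothing to place / all targets always covered
  expect_equal(null_team_score(0, 0, 0, 0, 6, 13, n_reps = 50, seed = 1), 0)
  expect_equal(null_team_score(6, 0, 6, 0, 6, 13, n_reps = 50, seed = 1), 6)
  # law-of-large-numbers agreement with the closed form at large n_reps
  mc <- null_team_score(3, 2, 4, 1, 6, 13, n_reps = 10000, seed = 2)
  exact <- expected_null_team_score(3, 2, 4, 1, 6, 13)
  expect_lt(abs(mc - exact), 0.1)
})

test_that("the set-placement and hypergeometric samplers agree", {
  for (case in list(c(3, 0, 3, 0), c(2, 2, 4, 1), c(6, 5, 1, 3))) {
    exact <- expected_null_team_score(case[1], case[2], case[3], case[4],
                                      6, 13)
    hyp <- null_team_score(case[1], case[2], case[3], case[4], 6, 13,
                           n_reps = 4000, seed = 3)
    sets <- null_team_score(case[1], case[2], case[3], case[4], 6, 13,
                            n_reps = 4000, seed = 3, method = "sets")
    # both Monte-Carlo routes sit near the analytic expectation
    expect_lt(abs(hyp - exact), 0.15)
    expect_lt(abs(sets - exact), 0.15)
  }
})

test_that("collaborative ratios compare the pair to its independence null", {
  # perfectly divided pair: 3 + 3 disjoint all-correct selections every trial
  tr <- list(target_ids = 1:6, distractor_ids = 7:19,
             selections_a = 1:3, selections_b = 4:6)
  sc <- score_session(make_session(rep(list(tr), 30)))
  b <- collaborative_ratio_series(sc, 6, 13, window = 20, n_reps = 2000,
                                  seed = 1)
  # actual union scores 6; the null mean is ~4.5, so each ratio is ~4/3
  expect_equal(mean(b$raw), 6 / 4.5, tolerance = 0.02)
  expect_gt(b$peak, 1)
  # a trial whose actual team equals the simulated mean has ratio 1
  nulls <- b$null_means
  expect_equal(b$raw, 6 / nulls)
  # per-trial nulls are substream-reproducible
  b2 <- collaborative_ratio_series(sc, 6, 13, window = 20, n_reps = 2000,
                                   seed = 1)
  expect_identical(b$null_means, b2$null_means)
})

test_that("uniform-random selectors show no collaborative benefit", {
  # actual selections drawn by the same process as the null: mean ratio ~ 1
  set.seed(6)
  trials <- lapply(1:400, function(i) {
    list(target_ids = 1:6, distractor_ids = 7:19,
         selections_a = c(sample(1:6, 3), sample(7:19, 1)),
         selections_b = c(sample(1:6, 3), sample(7:19, 1)))
  })
  sc <- score_session(make_session(trials))
  b <- collaborative_ratio_series(sc, 6, 13, window = 20, n_reps = 500,
                                  seed = 2)
  expect_equal(mean(b$raw), 1, tolerance = 0.02)
})

test_that("performance similarity is the order-invariant max/min ratio", {
  expect_equal(performance_similarity(3, 3), 1)
  expect_equal(performance_similarity(4, 2), 2)
  expect_equal(performance_similarity(2, 4), 2)
  expect_error(performance_similarity(3, 0), "not positive")
  expect_error(performance_similarity(3, -1), "not positive")
})

test_that("pair_benefits summarizes one pair in one row", {
  s <- generate_session(n_trials = 40, seed = 12)
  sc <- score_session(s)
  row <- pair_benefits(sc, 6, 13, window = 20, n_reps = 300, seed = 7)
  expect_identical(nrow(row), 1L)
  expect_true(row$collective_peak > 0)
  expect_true(row$similarity >= 1)
  expect_equal(row$mean_overlap, mean(sc$overlap))
})
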