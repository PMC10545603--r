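#' Moving average over valid windows
#'
#' Means of all contiguous `window`-length stretches, with no edge padding, so
#' the result has `length(x) - window + 1` elements. Peak extraction from
#' partially filled windows would be biased, hence valid windows only.
#'
#' @param x numeric series.
#' @param window positive window length, at most `length(x)`.
#' @return numeric vector of window means.
#' @examples
#' moving_average(1:5, 2)
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  if (length(x) < window)
    stop("series of length ", length(x), " is shorter than the smoothing ",
         "window (", window, ")", call. = FALSE)
  out <- stats::filter(x, rep(1 / window, window), sides = 1)
  as.numeric(out[window:length(x)])
}

#' Peak of the moving-average series
#'
#' The benefit criterion used throughout: smooth a per-trial ratio series with
#' a moving average (default window 20 trials) and take the maximum.
#'
#' @inheritParams moving_average
#' @return the maximum window mean.
#' @examples
#' smoothed_peak(c(rep(1, 40), rep(2, 20), rep(1, 40)), window = 20) # 2
#' @export
smoothed_peak <- function(x, window) {
  max(moving_average(x, window))
}

benefit_series <- function(raw, window, n_excluded) {
  smoothed <- moving_average(raw, window)
  structure(list(raw = raw, smoothed = smoothed, peak = max(smoothed),
                 window = window, n_excluded = n_excluded),
            class = "benefit_series")
}

#' @export
print.benefit_series <- function(x, ...) {
  cat("benefit series:", length(x$raw), "trials (", x$n_excluded,
      "excluded ), window", x$window, ", peak", format(x$peak), "\n")
  invisible(x)
}

drop_bad_denominators <- function(num, den, policy) {
  bad <- !is.finite(den) | den <= 0
  n_excluded <- sum(bad)
  if (policy == "exclude") {
    list(raw = num[!bad] / den[!bad], n_excluded = n_excluded)
  } else { # "na": keep positions, caller beware
    r <- num / den
    r[bad] <- NA_real_
    list(raw = r, n_excluded = n_excluded)
  }
}

#' Collective benefit ratio series
#'
#' The collective benefit compares the pair to its better member: per trial,
#' the team score divided by the better member's individual score. Ratios
#' above 1 mean the pair beat its best individual on that trial. The series is
#' smoothed with a moving average (default window 20) and the peak is the
#' pair-level dependent variable.
#'
#' Individual scores can be zero or negative, where the ratio loses meaning;
#' the default policy excludes such trials from the raw series before
#' smoothing and reports the count (`n_excluded`).
#'
#' @param scores a [score_session()] data.frame.
#' @param window moving-average window in trials.
#' @param denominator_policy `"exclude"` (drop trials with denominator <= 0,
#'   then smooth the retained series) or `"na"` (keep NA placeholders; the
#'   smoothed series will propagate NA).
#' @param better `"trial"` (default: the better member is re-evaluated every
#'   trial) or `"session"` (one better member per pair, by mean score).
#' @return a `"benefit_series"`: list with `raw`, `smoothed`, `peak`,
#'   `window`, `n_excluded`.
#' @examples
#' s <- generate_session(n_trials = 30, seed = 1)
#' collective_ratio_series(score_session(s), window = 10)$peak
#' @export
collective_ratio_series <- function(scores, window = 20L,
                                    denominator_policy = c("exclude", "na"),
                                    better = c("trial", "session")) {
  denominator_policy <- match.arg(denominator_policy)
  better <- match.arg(better)
  stopifnot(nrow(scores) >= 1)
  den <- if (better == "trial") {
    pmax(scores$score_a, scores$score_b)
  } else {
    rep(max(mean(scores$score_a), mean(scores$score_b)), nrow(scores))
  }
  d <- drop_bad_denominators(scores$team, den, denominator_policy)
  if (denominator_policy == "exclude" && length(d$raw) == 0L)
    stop("collective benefit undefined: every trial was excluded by the ",
         "denominator policy", call. = FALSE)
  if (denominator_policy == "exclude" && length(d$raw) < window)
    stop("only ", length(d$raw), " trials retained, fewer than the ",
         "smoothing window (", window, ")", call. = FALSE)
  benefit_series(d$raw, window, d$n_excluded)
}

#' Exact expectation of the independence-null team score
#'
#' Under the null in which each member's `c_i` correct selections are placed
#' uniformly at random (without replacement) among the `T` targets, a given
#' target is covered by neither member with probability
#' `(1 - c1/T) (1 - c2/T)`, so the expected number of distinct correct union
#' selections is `T (1 - (1 - c1/T)(1 - c2/T))`; the distractor term is
#' analogous and enters negatively. This closed form is the analytic oracle
#' for [null_team_score()].
#'
#' @param c1,w1 member a's correct and incorrect selection counts.
#' @param c2,w2 member b's correct and incorrect selection counts.
#' @param n_targets,n_distractors pool sizes (`T` and `D`).
#' @return the exact expected null team score.
#' @examples
#' expected_null_team_score(3, 0, 3, 0, 6, 13) # 4.5
#' @export
expected_null_team_score <- function(c1, w1, c2, w2, n_targets,
                                     n_distractors) {
  check_null_counts(c1, w1, c2, w2, n_targets, n_distractors)
  tt <- n_targets * (1 - (1 - c1 / n_targets) * (1 - c2 / n_targets))
  dd <- if (n_distractors > 0) {
    n_distractors *
      (1 - (1 - w1 / n_distractors) * (1 - w2 / n_distractors))
  } else 0
  tt - dd
}

check_null_counts <- function(c1, w1, c2, w2, n_targets, n_distractors) {
  stopifnot(n_targets >= 1, n_distractors >= 0)
  if (c1 > n_targets || c2 > n_targets)
    stop("correct-selection counts exceed the number of targets",
         call. = FALSE)
  if (w1 > n_distractors || w2 > n_distractors)
    stop("incorrect-selection counts exceed the number of distractors",
         call. = FALSE)
  if (any(c(c1, w1, c2, w2) < 0))
    stop("selection counts must be non-negative", call. = FALSE)
  invisible(NULL)
}

#' Monte-Carlo independence-null team score
#'
#' Simulates the team score a pair would obtain if both members kept their
#' per-trial correct/incorrect selection counts but placed them independently
#' and uniformly at random: correct selections among the targets, incorrect
#' selections among the distractors, each without replacement. The mean over
#' `n_reps` repetitions (default 1000) is the null team score against which
#' the collaborative benefit is measured.
#'
#' Two samplers are available. `"hypergeometric"` draws the two members'
#' overlap counts directly from their exact distribution under uniform
#' placement (the intersection of two independent uniform fixed-size subsets
#' is hypergeometric), which is fast and distributionally identical to placing
#' the sets. `"sets"` literally places the selection sets and scores them with
#' [team_score()]; it exists as a cross-check.
#'
#' @inheritParams expected_null_team_score
#' @param n_reps number of Monte-Carlo repetitions.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param method `"hypergeometric"` (default) or `"sets"`.
#' @return mean simulated team score (numeric scalar).
#' @examples
#' null_team_score(3, 0, 3, 0, 6, 13, n_reps = 2000, seed = 1)
#' @export
null_team_score <- function(c1, w1, c2, w2, n_targets, n_distractors,
                            n_reps = 1000L, seed,
                            method = c("hypergeometric", "sets")) {
  method <- match.arg(method)
  check_null_counts(c1, w1, c2, w2, n_targets, n_distractors)
  stopifnot(n_reps >= 1)
  with_seed(derive_seed(seed, "null-team"), {
    if (method == "hypergeometric") {
      sh_t <- stats::rhyper(n_reps, c1, n_targets - c1, c2)
      sh_d <- if (n_distractors > 0) {
        stats::rhyper(n_reps, w1, n_distractors - w1, w2)
      } else 0
      mean((c1 + c2 - sh_t) - (w1 + w2 - sh_d))
    } else {
      targets <- seq_len(n_targets)
      distractors <- n_targets + seq_len(n_distractors)
      tot <- 0
      for (r in seq_len(n_reps)) {
        sa <- c(targets[sample.int(n_targets)[seq_len(c1)]],
                distractors[sample.int(n_distractors)[seq_len(w1)]])
        sb <- c(targets[sample.int(n_targets)[seq_len(c2)]],
                distractors[sample.int(n_distractors)[seq_len(w2)]])
        tot <- tot + team_score(sa, sb, targets)
      }
      tot / n_reps
    }
  })
}

#' Collaborative benefit ratio series
#'
#' The collaborative benefit compares the pair to a simulated version of
#' itself that does not coordinate: per trial, the actual team score divided
#' by the mean team score of the Monte-Carlo independence null
#' ([null_team_score()]) run with that trial's correct/incorrect counts.
#' Ratios above 1 indicate coordination beyond statistical facilitation.
#' Smoothing and peak extraction follow [collective_ratio_series()].
#'
#' Each trial's null uses its own seed substream, so per-trial nulls are
#' reproducible independently of trial order.
#'
#' @param scores a [score_session()] data.frame (needs the per-member
#'   correct/wrong count columns).
#' @param n_targets,n_distractors pool sizes of the task.
#' @param window moving-average window in trials.
#' @param n_reps Monte-Carlo repetitions per trial.
#' @param seed integer seed.
#' @param denominator_policy as in [collective_ratio_series()].
#' @param method sampler passed to [null_team_score()].
#' @return a `"benefit_series"` with an extra element `null_means`, the
#'   per-trial simulated null team scores.
#' @examples
#' s <- generate_session(n_trials = 30, seed = 1)
#' collaborative_ratio_series(score_session(s), 6, 13, window = 10,
#'                            n_reps = 200, seed = 1)$peak
#' @export
collaborative_ratio_series <- function(scores, n_targets, n_distractors,
                                       window = 20L, n_reps = 1000L, seed,
                                       denominator_policy = c("exclude", "na"),
                                       method = "hypergeometric") {
  denominator_policy <- match.arg(denominator_policy)
  stopifnot(nrow(scores) >= 1)
  nulls <- vapply(seq_len(nrow(scores)), function(t) {
    null_team_score(scores$correct_a[t], scores$wrong_a[t],
                    scores$correct_b[t], scores$wrong_b[t],
                    n_targets, n_distractors, n_reps = n_reps,
                    seed = derive_seed(seed, "trial-null", t),
                    method = method)
  }, numeric(1))
  d <- drop_bad_denominators(scores$team, nulls, denominator_policy)
  if (denominator_policy == "exclude" && length(d$raw) == 0L)
    stop("collaborative benefit undefined: every trial was excluded by the ",
         "denominator policy", call. = FALSE)
  if (denominator_policy == "exclude" && length(d$raw) < window)
    stop("only ", length(d$raw), " trials retained, fewer than the ",
         "smoothing window (", window, ")", call. = FALSE)
  out <- benefit_series(d$raw, window, d$n_excluded)
  out$null_means <- nulls
  out
}

#' Performance similarity of a pair
#'
#' The better member's mean individual score divided by the worse member's:
#' always at least 1, equal to 1 only for identical means. Small values mean
#' similar ability.
#'
#' @param mean_a,mean_b the two members' mean individual scores across trials.
#' @return numeric ratio `>= 1`.
#' @examples
#' performance_similarity(4, 2) # 2
#' @export
performance_similarity <- function(mean_a, mean_b) {
  if (!is.finite(mean_a) || !is.finite(mean_b) || min(mean_a, mean_b) <= 0)
    stop("performance similarity undefined: the worse member's mean score ",
         "is not positive", call. = FALSE)
  max(mean_a, mean_b) / min(mean_a, mean_b)
}

#' Pair-level benefit summary
#'
#' One row per pair: collective and collaborative peaks, mean overlap,
#' performance similarity, and how many trials each ratio excluded.
#'
#' @param scores a [score_session()] data.frame for one pair.
#' @param n_targets,n_distractors pool sizes.
#' @param window moving-average window.
#' @param n_reps Monte-Carlo repetitions per trial for the null.
#' @param seed integer seed for the null simulations.
#' @param ... passed to the ratio-series functions.
#' @return one-row data.frame: `pair_id`, `collective_peak`,
#'   `collaborative_peak`, `mean_overlap`, `similarity`,
#'   `n_excluded_collective`, `n_excluded_collaborative`.
#' @examples
#' s <- generate_session(n_trials = 30, seed = 1)
#' pair_benefits(score_session(s), 6, 13, window = 10, n_reps = 200, seed = 1)
#' @export
pair_benefits <- function(scores, n_targets, n_distractors, window = 20L,
                          n_reps = 1000L, seed, ...) {
  cb <- collective_ratio_series(scores, window = window, ...)
  xb <- collaborative_ratio_series(scores, n_targets, n_distractors,
                                   window = window, n_reps = n_reps,
                                   seed = seed, ...)
  sim <- tryCatch(performance_similarity(mean(scores$score_a),
                                         mean(scores$score_b)),
                  error = function(e) NA_real_)
  data.frame(pair_id = scores$pair_id[1],
             collective_peak = cb$peak,
             collaborative_peak = xb$peak,
             mean_overlap = mean(scores$overlap),
             similarity = sim,
             n_excluded_collective = cb$n_excluded,
             n_excluded_collaborative = xb$n_excluded)
}
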