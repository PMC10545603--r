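#' Individual MOT score
#'
#' Each correct selection adds one point, each incorrect selection deducts
#' one: `|selection intersect targets| - |selection \ targets|`. Scores can be
#' negative.
#'
#' @param selection integer id set of one member's selections.
#' @param targets integer id set of targets.
#' @return integer score.
#' @examples
#' individual_score(c(1, 2, 3), targets = 1:6) # 3
#' individual_score(c(1, 2, 3, 4, 10, 11), targets = 1:6) # 4 - 2 = 2
#' @export
individual_score <- function(selection, targets) {
  check_id_set(selection, "selection")
  check_id_set(targets, "targets")
  length(intersect(selection, targets)) - length(setdiff(selection, targets))
}

#' Union-based team score
#'
#' The pair's selections are pooled as a set union, so a selection made by
#' both members counts only once: correct union selections add one point each
#' and incorrect union selections deduct one point each. With three correct
#' selections per member and exactly one shared, the team scores 5 rather
#' than 6.
#'
#' @param sel_a,sel_b integer id sets of the two members' selections.
#' @param targets integer id set of targets.
#' @return integer team score.
#' @examples
#' team_score(c(1, 2, 3), c(3, 4, 5), targets = 1:6) # union of 5 correct
#' @export
team_score <- function(sel_a, sel_b, targets) {
  check_id_set(sel_a, "sel_a")
  check_id_set(sel_b, "sel_b")
  u <- union(sel_a, sel_b)
  length(intersect(u, targets)) - length(setdiff(u, targets))
}

#' Fraction of overlapping selections
#'
#' How much of the pair's selecting was redundant. The default ("union")
#' convention divides the number of selections made by both members by the
#' number of distinct selections made by either (intersection over union):
#' identical selections give 1, disjoint selections give 0. The alternative
#' "sum" convention divides by the summed selection counts
#' (`|a intersect b| / (|a| + |b|)`), which tops out at 1/2 for identical
#' sets; it is provided for sensitivity checks.
#'
#' A trial in which neither member selected anything has no defined overlap;
#' such trials return `empty_value` (default 0) and raise a condition of class
#' `"jointmot_empty_overlap"` (a message) so callers can audit.
#'
#' @param sel_a,sel_b integer id sets.
#' @param method `"union"` (default) or `"sum"`.
#' @param empty_value value returned when both sets are empty.
#' @return numeric fraction in `[0, 1]`.
#' @examples
#' overlap_fraction(c(1, 2, 3), c(2, 3, 4)) # 2/4
#' overlap_fraction(c(1, 2, 3), c(2, 3, 4), method = "sum") # 2/6
#' @export
overlap_fraction <- function(sel_a, sel_b, method = c("union", "sum"),
                             empty_value = 0) {
  method <- match.arg(method)
  check_id_set(sel_a, "sel_a")
  check_id_set(sel_b, "sel_b")
  if (length(sel_a) == 0L && length(sel_b) == 0L) {
    message_cond <- simpleMessage(
      "overlap undefined for a trial with no selections; returning the configured empty-trial value\n")
    class(message_cond) <- c("jointmot_empty_overlap", class(message_cond))
    message(message_cond)
    return(empty_value)
  }
  n_shared <- length(intersect(sel_a, sel_b))
  denom <- switch(method,
                  union = length(union(sel_a, sel_b)),
                  sum = length(sel_a) + length(sel_b))
  n_shared / denom
}

check_id_set <- function(x, what) {
  if (length(x) && anyDuplicated(x))
    stop(what, " contains duplicate ids (selections are sets)", call. = FALSE)
  invisible(x)
}

#' Score every trial of a session
#'
#' Applies [individual_score()], [team_score()] and [overlap_fraction()] to
#' each trial, and records the per-member correct/incorrect counts that the
#' Monte-Carlo independence null consumes.
#'
#' @param session a `"pair_session"` (or any list with `trials`, `n_objects`,
#'   `n_targets` and optionally `pair_id`).
#' @param overlap_method passed to [overlap_fraction()].
#' @param empty_value passed to [overlap_fraction()].
#' @return data.frame with one row per trial: `pair_id`, `trial`,
#'   `correct_a`, `wrong_a`, `correct_b`, `wrong_b`, `score_a`, `score_b`,
#'   `team`, `n_shared`, `overlap`.
#' @examples
#' s <- generate_session(n_trials = 5, seed = 1)
#' score_session(s)
#' @export
score_session <- function(session, overlap_method = "union", empty_value = 0) {
  trials <- session$trials
  n <- length(trials)
  universe <- seq_len(session$n_objects)
  out <- data.frame(
    pair_id = rep(if (is.null(session$pair_id)) NA_integer_ else
      session$pair_id, n),
    trial = seq_len(n), correct_a = NA_integer_, wrong_a = NA_integer_,
    correct_b = NA_integer_, wrong_b = NA_integer_, score_a = NA_integer_,
    score_b = NA_integer_, team = NA_integer_, n_shared = NA_integer_,
    overlap = NA_real_
  )
  for (t in seq_len(n)) {
    tr <- trials[[t]]
    for (nm in c("selections_a", "selections_b")) {
      bad <- setdiff(tr[[nm]], universe)
      if (length(bad))
        stop("trial ", t, ": ", nm, " contains ids outside the object ",
             "universe (", paste(bad, collapse = ", "), ")", call. = FALSE)
      if (anyDuplicated(tr[[nm]]))
        stop("trial ", t, ": ", nm, " contains duplicate ids", call. = FALSE)
    }
    tg <- tr$target_ids
    out$correct_a[t] <- length(intersect(tr$selections_a, tg))
    out$wrong_a[t] <- length(setdiff(tr$selections_a, tg))
    out$correct_b[t] <- length(intersect(tr$selections_b, tg))
    out$wrong_b[t] <- length(setdiff(tr$selections_b, tg))
    out$score_a[t] <- out$correct_a[t] - out$wrong_a[t]
    out$score_b[t] <- out$correct_b[t] - out$wrong_b[t]
    out$team[t] <- team_score(tr$selections_a, tr$selections_b, tg)
    out$n_shared[t] <- length(intersect(tr$selections_a, tr$selections_b))
    out$overlap[t] <- suppressMessages(
      overlap_fraction(tr$selections_a, tr$selections_b,
                       method = overlap_method, empty_value = empty_value))
  }
  out
}
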