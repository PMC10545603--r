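# Shared fixtures, built in code at test time.

# The worked-example trial: each member selects three correct targets, none
# incorrect, with exactly one selection shared.
worked_example_trial <- function() {
  list(target_ids = 1:6, distractor_ids = 7:19,
       selections_a = c(1L, 2L, 3L), selections_b = c(3L, 4L, 5L))
}

# A tiny deterministic session wrapping arbitrary trials.
make_session <- function(trials, n_objects = 19L, n_targets = 6L,
                         pair_id = 1L) {
  structure(list(pair_id = pair_id, n_objects = n_objects,
                 n_targets = n_targets, trials = trials),
            class = "pair_session")
}

# Random well-formed trial for property-style loops.
random_trial <- function(n_objects = 19L, n_targets = 6L) {
  targets <- sort(sample.int(n_objects, n_targets))
  distractors <- setdiff(seq_len(n_objects), targets)
  pick <- function() {
    k <- sample(0:n_objects, 1)
    sort(sample.int(n_objects, k))
  }
  list(target_ids = targets, distractor_ids = distractors,
       selections_a = pick(), selections_b = pick())
}

# Independent brute-force re-implementation of the three trial scores,
# straight from the set definitions (used as the oracle for score_session).
oracle_trial_scores <- function(tr) {
  correct <- function(s) sum(s %in% tr$target_ids)
  wrong <- function(s) sum(!(s %in% tr$target_ids))
  u <- unique(c(tr$selections_a, tr$selections_b))
  list(score_a = correct(tr$selections_a) - wrong(tr$selections_a),
       score_b = correct(tr$selections_b) - wrong(tr$selections_b),
       team = sum(u %in% tr$target_ids) - sum(!(u %in% tr$target_ids)),
       overlap_union = {
         inter <- length(intersect(tr$selections_a, tr$selections_b))
         uni <- length(u)
         if (uni == 0) 0 else inter / uni
       })
}
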