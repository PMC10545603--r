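#' Behavioral profile of a simulated tracker
#'
#' A small generative model of one participant's selection behavior in a MOT
#' trial: the member attends a subset of targets ("tracked" targets), reports
#' each tracked target correctly with probability `accuracy`, and additionally
#' clicks a Poisson-distributed number of distractors ("guesses").
#'
#' @param capacity expected number of targets tracked per trial (non-negative
#'   real; non-integer values are realized by probabilistic rounding so the
#'   expectation is preserved).
#' @param accuracy probability in `[0, 1]` that a tracked target is selected.
#' @param guess_rate expected number of distractor selections per trial
#'   (non-negative real; realized as Poisson, capped at the distractor count).
#' @return an object of class `"agent_profile"`.
#' @examples
#' agent_profile(capacity = 3, accuracy = 0.9, guess_rate = 0.5)
#' @export
agent_profile <- function(capacity = 3, accuracy = 0.9, guess_rate = 0.5) {
  stopifnot(is.numeric(capacity), capacity >= 0,
            is.numeric(accuracy), accuracy >= 0, accuracy <= 1,
            is.numeric(guess_rate), guess_rate >= 0)
  structure(list(capacity = capacity, accuracy = accuracy,
                 guess_rate = guess_rate),
            class = "agent_profile")
}

#' Coordination strategy of a simulated pair
#'
#' Either the two members select independently, or -- from `onset_trial`
#' onwards -- they divide the labor left/right: each member draws its tracked
#' targets only from its own half of the screen (member a left, member b
#' right, the vertical screen midline at cue offset as the boundary). On any
#' given trial a division-strategy member adheres to its side with probability
#' `adherence` and otherwise behaves independently, emulating imperfect
#' coordination. Labor divisions emerge within only a few trials in practice,
#' hence the default onset of trial 5.
#'
#' @param kind `"independent"` or `"left_right_division"`.
#' @param onset_trial first trial (1-based) at which division behavior begins.
#' @param adherence probability in `[0, 1]` of staying on one's own side.
#' @return an object of class `"strategy_spec"`.
#' @examples
#' strategy_spec("left_right_division", onset_trial = 5, adherence = 0.95)
#' @export
strategy_spec <- function(kind = c("independent", "left_right_division"),
                          onset_trial = 5L, adherence = 1) {
  kind <- match.arg(kind)
  stopifnot(onset_trial >= 1, adherence >= 0, adherence <= 1)
  structure(list(kind = kind, onset_trial = as.integer(onset_trial),
                 adherence = adherence),
            class = "strategy_spec")
}

# Realize an expected count as an integer with the same expectation:
# floor(x) plus a Bernoulli on the fractional part.
realize_count <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(1) < (x - f)))
}

#' Simulate both members' selections for one trial
#'
#' Under the independent strategy each member's tracked targets are drawn
#' uniformly from all targets, without reference to the partner. Under the
#' left-right division strategy (from `onset_trial` onwards) each adhering
#' member draws only from the targets on its own side of the screen midline.
#' Tracked targets are reported with probability `accuracy`; guesses are
#' drawn uniformly among distractors. Selections are sets: no duplicates.
#'
#' @param stimulus a `"trial_stimulus"` (from [simulate_trial_kinematics()])
#'   or any list with `target_ids`, `distractor_ids`, `cue_x` and a `config`
#'   holding `field_width`.
#' @param agents list of two [agent_profile()]s (member a, member b).
#' @param strategy a [strategy_spec()].
#' @param trial_index 1-based trial number (division starts at `onset_trial`).
#' @param seed integer seed.
#' @return list with integer id sets `selections_a` and `selections_b`.
#' @examples
#' st <- simulate_trial_kinematics(kinematics_config(), seed = 1)
#' simulate_selections(st, list(agent_profile(), agent_profile()),
#'                     strategy_spec(), trial_index = 10, seed = 2)
#' @export
simulate_selections <- function(stimulus, agents, strategy = strategy_spec(),
                                trial_index = 1L, seed) {
  stopifnot(length(agents) == 2L, trial_index >= 1)
  targets <- stimulus$target_ids
  distractors <- stimulus$distractor_ids
  midline <- stimulus$config$field_width / 2
  left <- targets[stimulus$cue_x[targets] < midline]
  right <- setdiff(targets, left)
  with_seed(derive_seed(seed, "selections", trial_index), {
    sel <- vector("list", 2L)
    for (m in 1:2) {
      prof <- agents[[m]]
      capacity <- prof$capacity
      if (capacity > length(targets)) {
        warning("agent capacity ", capacity, " exceeds the number of targets (",
                length(targets), "); capped", call. = FALSE)
        capacity <- length(targets)
      }
      divided <- strategy$kind == "left_right_division" &&
        trial_index >= strategy$onset_trial &&
        stats::runif(1) < strategy$adherence
      pool <- if (!divided) targets else if (m == 1L) left else right
      k <- min(realize_count(capacity), length(pool))
      tracked <- pool[sample.int(length(pool))[seq_len(k)]]
      correct <- tracked[stats::runif(length(tracked)) < prof$accuracy]
      g <- min(stats::rpois(1, prof$guess_rate), length(distractors))
      guesses <- distractors[sample.int(length(distractors))[seq_len(g)]]
      sel[[m]] <- sort(as.integer(c(correct, guesses)))
    }
    list(selections_a = sel[[1L]], selections_b = sel[[2L]])
  })
}
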