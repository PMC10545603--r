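# Shared settings for the numbered analysis scripts. Each script can be run
# as `Rscript analysis/0X_*.R [--seed <int>]` from the repository root; they
# write their tables under results/.

suppressPackageStartupMessages(library(jointmot))

args <- commandArgs(trailingOnly = TRUE)
seed_ix <- which(args == "--seed")
SEED <- if (length(seed_ix) == 1L && seed_ix < length(args)) {
  as.integer(args[seed_ix + 1L])
} else 1L

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# The synthetic study: 16 pairs in each of the 8 information conditions,
# 100 trials per pair, 4 pairs with incomplete questionnaires. Labor-division
# adoption is made more likely by team-score feedback and by seeing the
# partner's selections, mirroring the qualitative pattern the task shows.
study_spec <- function(seed = SEED) {
  cohort_spec(n_pairs_per_condition = 16, n_trials = 100,
              effect_map = list(team_score = 2.2, selections = 2.2),
              base_rate = 0.1, n_incomplete = 4,
              seed = derive_seed(seed, "study"))
}

N_TARGETS <- 6L
N_DISTRACTORS <- 13L
WINDOW <- 20L
NULL_REPS <- 1000L

res_path <- function(...) file.path(RESULTS_DIR, ...)
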