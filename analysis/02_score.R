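# Score every trial of the simulated study: individual scores, union-based
# team score, and the selection-overlap fraction.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE)[1])), "common.R"))

cohort <- read_trials_csv(res_path("trials.csv"))
cat("scoring", length(cohort), "sessions read back from",
    res_path("trials.csv"), "\n")

scores <- do.call(rbind, lapply(cohort, score_session))
utils::write.csv(scores, res_path("scores.csv"), row.names = FALSE)

cat(sprintf("mean individual score %.2f, mean team score %.2f, mean overlap %.3f\n",
            mean(c(scores$score_a, scores$score_b)), mean(scores$team),
            mean(scores$overlap)))
cat("wrote", res_path("scores.csv"), "\n")
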