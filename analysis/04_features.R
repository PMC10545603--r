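# Build the pair-level regression table: condition flags, performance
# similarity, IRI questionnaire predictors (pair mean and absolute
# difference per factor), overlap, and both benefit DVs.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE)[1])), "common.R"))

# the cohort is a pure function of its spec, so regenerating it recovers the
# questionnaire/condition data that the flat trial table does not carry
cohort <- generate_cohort(study_spec())
scores <- utils::read.csv(res_path("scores.csv"))
scores_list <- lapply(split(scores, scores$pair_id), identity)
scores_list <- scores_list[order(as.integer(names(scores_list)))]
benefits <- utils::read.csv(res_path("benefits.csv"))

features <- build_features(cohort, scores_list, benefits)
utils::write.csv(features, res_path("features.csv"), row.names = FALSE)

excl <- exclude_incomplete_pairs(features)
cat(nrow(features), "pairs;", excl$n_excluded,
    "excluded for incomplete questionnaires ->", nrow(excl$retained),
    "retained for all models\n")

# internal consistency of the questionnaire factors before using them
key <- iri_key()
items <- do.call(rbind, lapply(cohort, function(s)
  rbind(s$questionnaire_a, s$questionnaire_b)))
items <- items[stats::complete.cases(items), , drop = FALSE]
for (f in names(key$factor_map)) {
  m <- items[, key$factor_map[[f]], drop = FALSE]
  rev_cols <- colnames(m) %in% sprintf("item_%02d", key$reverse)
  m[, rev_cols] <- 6 - m[, rev_cols]
  cat(sprintf("Cronbach's alpha, %s: %.2f\n", f, cronbach_alpha(m)))
}
cat("wrote", res_path("features.csv"), "\n")
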