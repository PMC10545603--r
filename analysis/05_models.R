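# Staged regression of both benefit DVs, leave-one-out cross-validation of
# the predict-ahead model, and the ridge lambda sweep.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE)[1])), "common.R"))

features <- utils::read.csv(res_path("features.csv"))
retained <- exclude_incomplete_pairs(features)$retained
cat("modeling", nrow(retained), "retained pairs\n\n")

plans <- list(
  dv_collective_peak = list(
    c("individual_scores", "team_score", "selections"),
    "similarity",
    c("empathic_concern_mean", "empathic_concern_diff",
      "personal_distress_mean", "personal_distress_diff"),
    "mean_overlap"),
  dv_collaborative_peak = list(
    c("individual_scores", "team_score", "selections",
      "individual_scores:team_score", "individual_scores:selections",
      "team_score:selections", "individual_scores:team_score:selections"),
    c("personal_distress_mean", "personal_distress_diff"),
    "mean_overlap"))

for (dv in names(plans)) {
  cat("==", dv, "==\n")
  sp <- stepwise_pipeline(retained, dv, plans[[dv]])
  print(sp$steps[, c("step", "added", "r_squared", "delta_r_squared", "F",
                     "p_value")], row.names = FALSE, digits = 3)
  utils::write.csv(sp$steps, res_path(paste0("steps_", dv, ".csv")),
                   row.names = FALSE)
  utils::write.csv(format_step_table(sp),
                   res_path(paste0("table_", dv, ".csv")), row.names = FALSE)
  cat("\n")
}

# predict-ahead model: only predictors knowable before the pair ever
# performs the task together
pred_ahead <- c("individual_scores", "team_score", "selections", "similarity",
                "empathic_concern_mean", "empathic_concern_diff",
                "personal_distress_mean", "personal_distress_diff")
cv <- loocv_rmse(retained, "dv_collective_peak", pred_ahead)
cat(sprintf("LOOCV RMSE %.4f vs in-sample %.4f (+%.2f%%), SD units\n",
            cv$rmse_cv, cv$rmse_insample, cv$percent_increase))

sweep <- lambda_sweep(retained, "dv_collective_peak", pred_ahead,
                      grid = exp(seq(log(0.01), log(100), length.out = 25)))
cv_r <- loocv_rmse(retained, "dv_collective_peak", pred_ahead,
                   method = "ridge", lambda = sweep$best_lambda)
cat(sprintf("ridge: best lambda %.3g, LOOCV RMSE %.4f (OLS %.4f)\n",
            sweep$best_lambda, cv_r$rmse_cv, cv$rmse_cv))
utils::write.csv(sweep$trace, res_path("lambda_sweep.csv"),
                 row.names = FALSE)
cat("wrote step tables and", res_path("lambda_sweep.csv"), "\n")
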