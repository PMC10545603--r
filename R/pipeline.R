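#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run: the cohort to
#' simulate (or files to load), benefit and null-simulation settings, the
#' staged-regression plans, and the master seed every substream derives from.
#'
#' @param mode `"simulate"` (generate a cohort) or `"load"` (read a trial
#'   table previously written by this package).
#' @param cohort a [cohort_spec()] (simulate mode).
#' @param trials_path flat trial CSV to read (load mode).
#' @param window moving-average window for the benefit series.
#' @param n_reps Monte-Carlo repetitions per trial for the independence null.
#' @param overlap_method overlap convention, `"union"` or `"sum"`.
#' @param plan_collective,plan_collaborative staged-regression block plans
#'   (lists of character vectors); defaults follow the standard analysis
#'   order: experimental factors (plus, for the collaborative model, their
#'   interactions), then performance similarity, then the questionnaire
#'   blocks that survive screening, then overlap.
#' @param seed master integer seed.
#' @param verbose print stage progress.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       cohort = cohort_spec(),
                       trials_path = NULL,
                       window = 20L, n_reps = 1000L,
                       overlap_method = "union",
                       plan_collective = list(
                         c("individual_scores", "team_score", "selections"),
                         "similarity",
                         c("empathic_concern_mean", "empathic_concern_diff",
                           "personal_distress_mean", "personal_distress_diff"),
                         "mean_overlap"),
                       plan_collaborative = list(
                         c("individual_scores", "team_score", "selections",
                           "individual_scores:team_score",
                           "individual_scores:selections",
                           "team_score:selections",
                           "individual_scores:team_score:selections"),
                         c("personal_distress_mean", "personal_distress_diff"),
                         "mean_overlap"),
                       seed = 1L, verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "load" && (is.null(trials_path) || !file.exists(trials_path)))
    stop("load mode requires an existing trials_path", call. = FALSE)
  structure(list(mode = mode, cohort = cohort, trials_path = trials_path,
                 window = as.integer(window), n_reps = as.integer(n_reps),
                 overlap_method = overlap_method,
                 plan_collective = plan_collective,
                 plan_collaborative = plan_collaborative,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Validate session invariants
#'
#' Checks every trial record of every session: targets and distractors
#' disjoint and jointly exhausting the object universe, target count
#' constant, selections inside the universe and free of duplicates. Nothing
#' is mutated; violations are reported.
#'
#' @param sessions a session, a list of sessions, or a path to a trial CSV /
#'   session JSON file.
#' @return data.frame with columns `pair_id`, `trial`, `problem` (zero rows
#'   when everything is clean).
#' @export
validate_sessions <- function(sessions) {
  if (is.character(sessions)) {
    sessions <- if (grepl("\\.json$", sessions)) {
      list(read_session_json(sessions))
    } else {
      read_trials_csv(sessions)
    }
  }
  if (inherits(sessions, "pair_session")) sessions <- list(sessions)
  bad <- list()
  note <- function(pid, trial, problem) {
    bad[[length(bad) + 1L]] <<- data.frame(pair_id = pid, trial = trial,
                                           problem = problem)
  }
  for (s in sessions) {
    universe <- seq_len(s$n_objects)
    for (t in seq_along(s$trials)) {
      tr <- s$trials[[t]]
      if (length(intersect(tr$target_ids, tr$distractor_ids)))
        note(s$pair_id, t, "targets and distractors not disjoint")
      if (length(tr$target_ids) + length(tr$distractor_ids) != s$n_objects)
        note(s$pair_id, t, "targets + distractors != n_objects")
      if (length(tr$target_ids) != s$n_targets)
        note(s$pair_id, t, "target count differs from session n_targets")
      for (nm in c("selections_a", "selections_b")) {
        if (anyDuplicated(tr[[nm]]))
          note(s$pair_id, t, paste(nm, "contains duplicate ids"))
        if (length(setdiff(tr[[nm]], universe)))
          note(s$pair_id, t, paste(nm, "outside object universe"))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(pair_id = integer(0), trial = integer(0),
               problem = character(0))
}

#' Build the pair-level feature table
#'
#' Joins, for every pair: the condition flags, benefit peaks and mean
#' overlap, performance similarity, familiarity, and the questionnaire
#' predictors (pair mean and absolute difference per IRI factor). Pairs with
#' incomplete questionnaires keep `NA`s here; [exclude_incomplete_pairs()]
#' removes them before modeling.
#'
#' @param cohort list of `"pair_session"`s.
#' @param scores_list list of [score_session()] frames, one per pair (in
#'   cohort order).
#' @param benefits data.frame of [pair_benefits()] rows, one per pair.
#' @return data.frame with one row per pair.
#' @export
build_features <- function(cohort, scores_list, benefits) {
  stopifnot(length(cohort) == length(scores_list),
            nrow(benefits) == length(cohort))
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    safe_iri <- function(q) {
      if (is.null(q)) return(NULL)
      tryCatch(score_iri(q), jointmot_incomplete = function(e) NULL)
    }
    iri_a <- safe_iri(s$questionnaire_a)
    iri_b <- safe_iri(s$questionnaire_b)
    qp <- function(f) {
      if (is.null(iri_a) || is.null(iri_b))
        return(c(mean = NA_real_, abs_difference = NA_real_))
      pair_predictors(iri_a[[f]], iri_b[[f]])
    }
    fa <- qp("fantasy"); pt <- qp("perspective_taking")
    ec <- qp("empathic_concern"); pd <- qp("personal_distress")
    fl <- if (is.null(s$condition)) {
      c(individual_scores = NA, team_score = NA, selections = NA)
    } else s$condition
    data.frame(
      pair_id = s$pair_id,
      individual_scores = as.numeric(fl[["individual_scores"]]),
      team_score = as.numeric(fl[["team_score"]]),
      selections = as.numeric(fl[["selections"]]),
      similarity = benefits$similarity[i],
      fantasy_mean = fa[["mean"]], fantasy_diff = fa[["abs_difference"]],
      perspective_taking_mean = pt[["mean"]],
      perspective_taking_diff = pt[["abs_difference"]],
      empathic_concern_mean = ec[["mean"]],
      empathic_concern_diff = ec[["abs_difference"]],
      personal_distress_mean = pd[["mean"]],
      personal_distress_diff = pd[["abs_difference"]],
      familiarity = if (is.null(s$familiarity)) NA_real_ else
        as.numeric(s$familiarity),
      mean_overlap = benefits$mean_overlap[i],
      dv_collective_peak = benefits$collective_peak[i],
      dv_collaborative_peak = benefits$collaborative_peak[i]
    )
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> score -> benefits -> features ->
#' staged models end-to-end, writing every interchange table plus a run
#' manifest under `out_dir`. The same configuration and seed reproduce
#' byte-identical numeric outputs.
#'
#' Files written: `trials.csv` (flat trial table), `cohort_manifest.csv`
#' (simulate mode), `scores.csv` (per-trial scores), `benefits.csv`
#' (pair-level benefit summaries), `features.csv` (regression rows),
#' `steps_<dv>.csv` and `table_<dv>.csv` (staged-regression summaries and
#' formatted weight tables), and `manifest.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly: a list with the seed, a config
#'   fingerprint, stage row counts and file names.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempdir()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) cat(..., "\n")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- stage: simulate / load ------------------------------------------------
  cohort <- stage("simulate", {
    if (config$mode == "simulate") {
      say("simulating cohort:", 8 * config$cohort$n_pairs_per_condition,
          "pairs x", config$cohort$n_trials, "trials")
      generate_cohort(config$cohort)
    } else {
      say("loading sessions from", config$trials_path)
      read_trials_csv(config$trials_path)
    }
  })
  stage("validate", {
    v <- validate_sessions(cohort)
    if (nrow(v) > 0L)
      stop("session validation found ", nrow(v), " violation(s); first: ",
           "pair ", v$pair_id[1], " trial ", v$trial[1], " (", v$problem[1],
           ")", call. = FALSE)
  })
  write_trials_csv(cohort, file.path(out_dir, "trials.csv"))
  if (config$mode == "simulate")
    write_cohort_manifest(cohort, file.path(out_dir, "cohort_manifest.csv"))

  # -- stage: score ----------------------------------------------------------
  scores_list <- stage("score", {
    say("scoring", length(cohort), "sessions")
    lapply(cohort, score_session, overlap_method = config$overlap_method)
  })
  scores <- do.call(rbind, scores_list)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)

  # -- stage: benefits -------------------------------------------------------
  n_targets <- cohort[[1]]$n_targets
  n_distractors <- cohort[[1]]$n_objects - n_targets
  benefits <- stage("benefits", {
    say("computing benefit series (window", config$window, ", null reps",
        config$n_reps, ")")
    do.call(rbind, lapply(seq_along(cohort), function(i) {
      pair_benefits(scores_list[[i]], n_targets, n_distractors,
                    window = config$window, n_reps = config$n_reps,
                    seed = derive_seed(config$seed, "benefits",
                                       cohort[[i]]$pair_id))
    }))
  })
  utils::write.csv(benefits, file.path(out_dir, "benefits.csv"),
                   row.names = FALSE)

  # -- stage: features -------------------------------------------------------
  features <- stage("features", build_features(cohort, scores_list, benefits))
  excl <- exclude_incomplete_pairs(features)
  say("feature table:", nrow(features), "pairs,", excl$n_excluded,
      "excluded for incomplete questionnaires")
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  # -- stage: models ---------------------------------------------------------
  models <- stage("model", {
    retained <- excl$retained
    out <- list()
    for (dv in c("dv_collective_peak", "dv_collaborative_peak")) {
      plan <- if (dv == "dv_collective_peak") config$plan_collective else
        config$plan_collaborative
      sp <- stepwise_pipeline(retained, dv, plan)
      utils::write.csv(sp$steps,
                       file.path(out_dir, paste0("steps_", dv, ".csv")),
                       row.names = FALSE)
      utils::write.csv(format_step_table(sp),
                       file.path(out_dir, paste0("table_", dv, ".csv")),
                       row.names = FALSE)
      out[[dv]] <- sp
    }
    out
  })

  manifest <- list(
    seed = config$seed,
    config_hash = fnv1a_hash(paste(deparse(unclass(
      config[setdiff(names(config), "verbose")])), collapse = "")),
    package_version = as.character(utils::packageVersion("jointmot")),
    r_version = R.version.string,
    n_pairs = length(cohort),
    n_trials = nrow(scores),
    n_excluded_pairs = excl$n_excluded,
    files = c("trials.csv", "scores.csv", "benefits.csv", "features.csv",
              "steps_dv_collective_peak.csv", "steps_dv_collaborative_peak.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, features = features,
                 benefits = benefits, models = models))
}
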