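#' Write a pair session to JSON
#'
#' One session per file: condition flags, familiarity, questionnaire
#' responses, and every trial's explicit target/distractor/selection id
#' lists. Object ids are written 0-based (internally the package uses
#' 1-based ids).
#'
#' @param session a `"pair_session"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_session_json()]
#' @export
write_session_json <- function(session, path) {
  to0 <- function(x) as.integer(x) - 1L
  obj <- list(
    pair_id = session$pair_id,
    condition = as.list(unclass(session$condition)),
    n_objects = session$n_objects,
    n_targets = session$n_targets,
    familiarity = session$familiarity,
    questionnaire_a = unname(as.integer(session$questionnaire_a)),
    questionnaire_b = unname(as.integer(session$questionnaire_b)),
    seed = session$seed,
    trials = lapply(session$trials, function(tr) list(
      target_ids = to0(tr$target_ids),
      distractor_ids = to0(tr$distractor_ids),
      selections_a = to0(tr$selections_a),
      selections_b = to0(tr$selections_b)
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pair session from JSON
#'
#' Inverse of [write_session_json()]; ids in the file are 0-based and are
#' converted back to the package's 1-based convention.
#'
#' @param path file written by [write_session_json()].
#' @return a `"pair_session"`.
#' @export
read_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to1 <- function(x) as.integer(unlist(x)) + 1L
  trials <- lapply(seq_len(nrow(obj$trials)), function(i) list(
    target_ids = to1(obj$trials$target_ids[[i]]),
    distractor_ids = to1(obj$trials$distractor_ids[[i]]),
    selections_a = to1(obj$trials$selections_a[[i]]),
    selections_b = to1(obj$trials$selections_b[[i]])
  ))
  qa <- as.integer(obj$questionnaire_a)
  qb <- as.integer(obj$questionnaire_b)
  structure(list(
    pair_id = obj$pair_id,
    condition = condition_flags(obj$condition$individual_scores,
                                obj$condition$team_score,
                                obj$condition$selections),
    n_objects = as.integer(obj$n_objects),
    n_targets = as.integer(obj$n_targets),
    trials = trials,
    questionnaire_a = stats::setNames(qa, sprintf("item_%02d", 1:28)),
    questionnaire_b = stats::setNames(qb, sprintf("item_%02d", 1:28)),
    familiarity = as.integer(obj$familiarity),
    seed = as.integer(obj$seed)
  ), class = "pair_session")
}

#' Flatten sessions to the long trial table
#'
#' One row per (pair, trial, object): `pair_id`, `trial`, `object_id`
#' (0-based in the file format), `is_target`, `selected_by_a`,
#' `selected_by_b`.
#'
#' @param sessions a `"pair_session"` or list of them.
#' @return data.frame in the flat interchange layout (0-based object ids).
#' @seealso [write_trials_csv()], [trials_df_to_sessions()]
#' @export
sessions_to_trials_df <- function(sessions) {
  if (inherits(sessions, "pair_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    nt <- length(s$trials)
    n <- s$n_objects
    do.call(rbind, lapply(seq_len(nt), function(t) {
      tr <- s$trials[[t]]
      data.frame(pair_id = s$pair_id, trial = t,
                 object_id = seq_len(n) - 1L,
                 is_target = as.integer(seq_len(n) %in% tr$target_ids),
                 selected_by_a = as.integer(seq_len(n) %in% tr$selections_a),
                 selected_by_b = as.integer(seq_len(n) %in% tr$selections_b))
    }))
  })
  do.call(rbind, rows)
}

#' Rebuild minimal sessions from a flat trial table
#'
#' Inverse of [sessions_to_trials_df()] up to the information the flat format
#' carries (no questionnaires, condition or familiarity -- those travel in
#' the JSON format or the cohort manifest).
#'
#' @param df data.frame in the flat layout (0-based object ids).
#' @return list of `"pair_session"`-shaped lists (trials + object counts).
#' @export
trials_df_to_sessions <- function(df) {
  need <- c("pair_id", "trial", "object_id", "is_target",
            "selected_by_a", "selected_by_b")
  if (!all(need %in% names(df)))
    stop("trial table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$pair_id), function(d) {
    n <- length(unique(d$object_id))
    trials <- lapply(split(d, d$trial), function(tt) {
      id <- tt$object_id + 1L
      list(target_ids = sort(id[tt$is_target == 1L]),
           distractor_ids = sort(id[tt$is_target == 0L]),
           selections_a = sort(id[tt$selected_by_a == 1L]),
           selections_b = sort(id[tt$selected_by_b == 1L]))
    })
    trials <- trials[order(as.integer(names(trials)))]
    structure(list(pair_id = d$pair_id[1], n_objects = n,
                   n_targets = length(trials[[1]]$target_ids),
                   trials = unname(trials)),
              class = "pair_session")
  })
}

#' Write / read the flat trial CSV
#'
#' @param sessions sessions (for writing).
#' @param path CSV path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` returns the list of rebuilt sessions.
#' @rdname trials_csv
#' @export
write_trials_csv <- function(sessions, path) {
  utils::write.csv(sessions_to_trials_df(sessions), path, row.names = FALSE)
  invisible(path)
}

#' @param path CSV path.
#' @rdname trials_csv
#' @export
read_trials_csv <- function(path) {
  trials_df_to_sessions(utils::read.csv(path))
}

#' Write the cohort ground-truth manifest
#'
#' Pair-level ground truth of a synthetic cohort (condition flags, member
#' profiles, planted strategy and adoption probability) as CSV.
#'
#' @param cohort a `"pair_cohort"` from [generate_cohort()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt))
    stop("cohort carries no ground-truth attribute", call. = FALSE)
  utils::write.csv(gt, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' A single structured key-value document mirroring the configuration
#' constructors' field names ([kinematics_config()], [cohort_spec()], benefit
#' and null-simulation settings). JSON is always supported; YAML is used when
#' the file extension is `.yml`/`.yaml` and the yaml package is installed.
#'
#' @param path config file path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
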