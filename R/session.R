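#' Information-condition flags
#'
#' The eight experimental conditions of the joint-MOT design are the eight
#' combinations of three binary information types shown after each trial:
#' individual performance scores, the team score, and the partner's
#' selections.
#'
#' @param individual_scores,team_score,selections logical flags.
#' @return an object of class `"condition_flags"` (a named logical vector).
#' @seealso [encode_condition()] for the experiment-number to flag bijection.
#' @examples
#' condition_flags(team_score = TRUE, selections = TRUE)
#' @export
condition_flags <- function(individual_scores = FALSE, team_score = FALSE,
                            selections = FALSE) {
  structure(c(individual_scores = as.logical(individual_scores),
              team_score = as.logical(team_score),
              selections = as.logical(selections)),
            class = "condition_flags")
}

#' Simulate one participant's Interpersonal Reactivity Index responses
#'
#' A latent-factor Likert model: each of the four factors gets one latent
#' score per person, each of its 7 items is the latent score plus independent
#' item noise, rounded and clipped to the 1-5 scale.
#'
#' @param latent named numeric vector of latent factor levels on the 1-5
#'   scale (names `fantasy`, `perspective_taking`, `empathic_concern`,
#'   `personal_distress`); defaults to draws around 3.
#' @param item_sd standard deviation of the per-item noise.
#' @param key an [iri_key()] giving the item-to-factor map and reverse key.
#' @param seed integer seed.
#' @return integer vector of 28 ratings in 1..5 (named `item_01`..`item_28`).
#' @examples
#' simulate_iri_responses(seed = 1)
#' @export
simulate_iri_responses <- function(latent = NULL, item_sd = 0.8,
                                   key = iri_key(), seed) {
  with_seed(derive_seed(seed, "questionnaire"), {
    factors <- names(key$factor_map)
    if (is.null(latent)) {
      latent <- stats::setNames(stats::rnorm(length(factors), 3, 0.5), factors)
    }
    items <- numeric(28L)
    for (f in factors) {
      idx <- key$factor_map[[f]]
      items[idx] <- latent[[f]] + stats::rnorm(length(idx), 0, item_sd)
    }
    # an agree-worded and a reverse-worded item express the same latent level
    # at opposite ends of the scale
    items[key$reverse] <- 6 - items[key$reverse]
    items <- pmin(5L, pmax(1L, as.integer(round(items))))
    stats::setNames(items, sprintf("item_%02d", 1:28))
  })
}

#' Generate a full pair session
#'
#' Simulates `n_trials` joint-MOT trials for one pair under a given
#' information condition, coordination strategy and pair of behavioral
#' profiles, plus both members' questionnaire responses and a familiarity
#' rating. Sessions are pure functions of their seed.
#'
#' By default trials use a lightweight stimulus draw (random target identities
#' and cue-time x-positions, which is all the selection model consumes); set
#' `trajectories = TRUE` to run the full 2D kinematics for every trial.
#'
#' @param condition a [condition_flags()].
#' @param agents list of two [agent_profile()]s.
#' @param strategy a [strategy_spec()].
#' @param kinematics a [kinematics_config()].
#' @param n_trials number of trials (the standard session has 100).
#' @param seed integer seed.
#' @param pair_id identifier stored with the session.
#' @param trajectories if `TRUE`, simulate full object motion per trial.
#' @param familiarity optional 1-5 rating; drawn uniformly if `NULL`.
#' @return an object of class `"pair_session"`: list with `pair_id`,
#'   `condition`, `n_objects`, `n_targets`, `trials` (each a list with
#'   `target_ids`, `distractor_ids`, `selections_a`, `selections_b`),
#'   `questionnaire_a`, `questionnaire_b`, `familiarity`, `seed`.
#' @examples
#' s <- generate_session(condition_flags(), n_trials = 5, seed = 1)
#' length(s$trials)
#' @export
generate_session <- function(condition = condition_flags(),
                             agents = list(agent_profile(), agent_profile()),
                             strategy = strategy_spec(),
                             kinematics = kinematics_config(),
                             n_trials = 100L, seed, pair_id = 1L,
                             trajectories = FALSE, familiarity = NULL) {
  stopifnot(n_trials >= 1)
  validate_kinematics_config(kinematics)
  n <- kinematics$n_objects
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    if (trajectories) {
      st <- simulate_trial_kinematics(kinematics,
                                      seed = derive_seed(seed, "trial", t))
    } else {
      st <- with_seed(derive_seed(seed, "stimulus", t), {
        tid <- sort(sample.int(n, kinematics$n_targets))
        list(target_ids = tid, distractor_ids = setdiff(seq_len(n), tid),
             cue_x = stats::runif(n, 0, kinematics$field_width),
             config = kinematics)
      })
    }
    sel <- simulate_selections(st, agents, strategy, trial_index = t,
                               seed = derive_seed(seed, "pair"))
    trials[[t]] <- list(target_ids = st$target_ids,
                        distractor_ids = st$distractor_ids,
                        selections_a = sel$selections_a,
                        selections_b = sel$selections_b)
  }
  if (is.null(familiarity)) {
    familiarity <- with_seed(derive_seed(seed, "familiarity"),
                             sample.int(5L, 1L))
  }
  structure(list(
    pair_id = pair_id,
    condition = condition,
    n_objects = n,
    n_targets = kinematics$n_targets,
    trials = trials,
    questionnaire_a = simulate_iri_responses(seed = derive_seed(seed, "qa")),
    questionnaire_b = simulate_iri_responses(seed = derive_seed(seed, "qb")),
    familiarity = as.integer(familiarity),
    seed = as.integer(seed)
  ), class = "pair_session")
}

#' Cohort specification
#'
#' Parameters of a synthetic multi-pair study: how many pairs per information
#' condition, trials per pair, and a map of planted effects on the log-odds of
#' a pair adopting the left-right labor-division strategy. The defaults mirror
#' the study design this package emulates: 16 pairs in each of the 8
#' conditions, 100 trials per pair.
#'
#' `effect_map` entries are additive log-odds contributions to division
#' adoption: recognized names are `individual_scores`, `team_score`,
#' `selections` (condition flags), `similarity` (centred ability ratio) and
#' `personal_distress_diff` (centred absolute latent difference). An empty map
#' yields the null model in which adoption depends on nothing.
#'
#' @param n_pairs_per_condition pairs per condition.
#' @param n_trials trials per pair.
#' @param effect_map named list of planted log-odds effects (see details).
#' @param base_rate baseline division-adoption probability with all
#'   predictors at reference level.
#' @param n_incomplete number of pairs whose questionnaires are planted as
#'   incomplete (missing items), to exercise pair exclusion.
#' @param seed integer master seed.
#' @param kinematics a [kinematics_config()].
#' @return an object of class `"cohort_spec"`.
#' @examples
#' cohort_spec(n_pairs_per_condition = 2, n_trials = 10, seed = 1)
#' @export
cohort_spec <- function(n_pairs_per_condition = 16L, n_trials = 100L,
                        effect_map = list(team_score = 2.2, selections = 2.2),
                        base_rate = 0.1, n_incomplete = 0L, seed = 1L,
                        kinematics = kinematics_config()) {
  stopifnot(n_pairs_per_condition >= 1, n_trials >= 1,
            base_rate > 0, base_rate < 1)
  bad <- setdiff(names(effect_map),
                 c("individual_scores", "team_score", "selections",
                   "similarity", "personal_distress_diff"))
  if (length(bad))
    stop("unknown effect_map entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(effect_map) && !all(vapply(effect_map, is.finite, logical(1))))
    stop("planted effects must be finite", call. = FALSE)
  structure(list(n_pairs_per_condition = as.integer(n_pairs_per_condition),
                 n_trials = as.integer(n_trials), effect_map = effect_map,
                 base_rate = base_rate, n_incomplete = as.integer(n_incomplete),
                 seed = as.integer(seed), kinematics = kinematics),
            class = "cohort_spec")
}

effect_of <- function(effect_map, name) {
  if (is.null(effect_map[[name]])) 0 else effect_map[[name]]
}

#' Generate a synthetic cohort of pair sessions
#'
#' Assigns `n_pairs_per_condition` pairs to each of the 8 information
#' conditions, draws heterogeneous member abilities, decides per pair whether
#' it adopts the left-right labor division (a Bernoulli draw whose log-odds
#' follow the spec's `effect_map`), and simulates every session. The
#' ground-truth pair parameters (profiles, strategy, adoption probability)
#' are attached as the `"ground_truth"` attribute, one row per pair, and can
#' be written with [write_cohort_manifest()].
#'
#' @param spec a [cohort_spec()].
#' @return list of [generate_session()] results with attribute
#'   `"ground_truth"` (a data.frame) and `"spec"`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_pairs_per_condition = 1,
#'                                    n_trials = 5, seed = 1))
#' length(coh)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_cond <- 8L
  n_pairs <- n_cond * spec$n_pairs_per_condition
  sessions <- vector("list", n_pairs)
  gt <- vector("list", n_pairs)
  base_logit <- stats::qlogis(spec$base_rate)
  pid <- 0L
  for (cond in seq_len(n_cond)) {
    flags <- encode_condition(cond)
    for (k in seq_len(spec$n_pairs_per_condition)) {
      pid <- pid + 1L
      pseed <- derive_seed(spec$seed, "pair-setup", pid)
      setup <- with_seed(pseed, {
        cap <- stats::runif(2, 2.2, 4.8)
        acc <- stats::runif(2, 0.75, 0.98)
        gr <- stats::runif(2, 0.2, 0.9)
        pd_lat <- stats::rnorm(2, 3, 0.6)
        list(cap = cap, acc = acc, gr = gr, pd_lat = pd_lat,
             u = stats::runif(1),
             adherence = stats::runif(1, 0.85, 1),
             onset = sample(3:8, 1L))
      })
      sim <- max(setup$cap) / min(setup$cap)
      pd_diff <- abs(setup$pd_lat[1] - setup$pd_lat[2])
      logit <- base_logit +
        effect_of(spec$effect_map, "individual_scores") * flags["individual_scores"] +
        effect_of(spec$effect_map, "team_score") * flags["team_score"] +
        effect_of(spec$effect_map, "selections") * flags["selections"] +
        effect_of(spec$effect_map, "similarity") * (sim - 1.3) +
        effect_of(spec$effect_map, "personal_distress_diff") * (pd_diff - 0.7)
      p_adopt <- stats::plogis(logit)
      adopt <- setup$u < p_adopt
      strategy <- if (adopt) {
        strategy_spec("left_right_division", onset_trial = setup$onset,
                      adherence = setup$adherence)
      } else strategy_spec("independent")
      agents <- list(
        agent_profile(setup$cap[1], setup$acc[1], setup$gr[1]),
        agent_profile(setup$cap[2], setup$acc[2], setup$gr[2])
      )
      sessions[[pid]] <- generate_session(
        condition = flags, agents = agents, strategy = strategy,
        kinematics = spec$kinematics, n_trials = spec$n_trials,
        seed = derive_seed(spec$seed, "session", pid), pair_id = pid
      )
      gt[[pid]] <- data.frame(
        pair_id = pid, experiment = cond,
        individual_scores = unname(flags["individual_scores"]),
        team_score = unname(flags["team_score"]),
        selections = unname(flags["selections"]),
        capacity_a = setup$cap[1], capacity_b = setup$cap[2],
        accuracy_a = setup$acc[1], accuracy_b = setup$acc[2],
        guess_rate_a = setup$gr[1], guess_rate_b = setup$gr[2],
        p_adopt = p_adopt, adopted_division = adopt,
        adherence = ifelse(adopt, setup$adherence, NA_real_),
        onset_trial = ifelse(adopt, setup$onset, NA_integer_)
      )
    }
  }
  # plant incomplete questionnaires on the configured number of pairs
  if (spec$n_incomplete > 0L) {
    drop <- with_seed(derive_seed(spec$seed, "incomplete"),
                      sample.int(n_pairs, min(spec$n_incomplete, n_pairs)))
    for (i in drop) sessions[[i]]$questionnaire_a[c(2L, 17L)] <- NA_integer_
  }
  structure(sessions,
            ground_truth = do.call(rbind, gt),
            spec = spec,
            class = "pair_cohort")
}

#' Generate a feature-level cohort with planted standardized effects
#'
#' For parameter-recovery experiments it is the standardized regression
#' weights themselves that must be known exactly, so this generator works at
#' the level of the regression rows rather than of behavior: condition flags
#' come from a balanced assignment of pairs to the 8 conditions, the
#' continuous predictors are independent standard normals, and the dependent
#' variable is the planted linear combination of z-scored predictors plus
#' Gaussian noise scaled so the DV has unit variance in expectation.
#'
#' @param n_pairs number of rows (default 128, i.e. 16 per condition).
#' @param betas named numeric vector of planted standardized effects; names
#'   must be predictor columns (`individual_scores`, `team_score`,
#'   `selections`, `similarity`, and the questionnaire predictor names).
#' @param seed integer seed.
#' @return data.frame of one row per pair with attribute `"betas"`.
#' @examples
#' f <- generate_feature_cohort(betas = c(team_score = 0.4), seed = 1)
#' nrow(f)
#' @export
generate_feature_cohort <- function(n_pairs = 128L,
                                    betas = c(individual_scores = 0,
                                              team_score = 0.4,
                                              selections = 0.4),
                                    seed = 1L) {
  stopifnot(n_pairs >= 8)
  with_seed(derive_seed(seed, "feature-cohort"), {
    experiment <- rep(1:8, length.out = n_pairs)
    flags <- t(vapply(experiment, function(e) as.numeric(encode_condition(e)),
                      numeric(3)))
    colnames(flags) <- c("individual_scores", "team_score", "selections")
    cont <- c("similarity", "empathic_concern_mean",
              "empathic_concern_diff", "personal_distress_mean",
              "personal_distress_diff", "overlap_mean")
    X <- cbind(as.data.frame(flags),
               stats::setNames(as.data.frame(
                 matrix(stats::rnorm(n_pairs * length(cont)), n_pairs)), cont))
    bad <- setdiff(names(betas), names(X))
    if (length(bad))
      stop("unknown planted predictors: ", paste(bad, collapse = ", "),
           call. = FALSE)
    Z <- scale(as.matrix(X))
    eta <- as.numeric(Z[, names(betas), drop = FALSE] %*% betas)
    sigma <- sqrt(max(1 - sum(betas^2), 0.05))
    dv <- eta + stats::rnorm(n_pairs, 0, sigma)
    out <- cbind(data.frame(pair_id = seq_len(n_pairs),
                            experiment = experiment),
                 X, dv = dv)
    attr(out, "betas") <- betas
    attr(out, "sigma") <- sigma
    out
  })
}
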