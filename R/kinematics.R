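#' Kinematics configuration for a joint-MOT trial
#'
#' Describes the stimulus display: object count and size, the target subset
#' size, the speed range, movement duration and field extent. Defaults follow
#' the standard joint-MOT display: 19 objects of 0.56 visual degrees radius,
#' 6 targets, per-object speeds drawn uniformly from 0.90-1.21 deg/s, and 11 s
#' of motion. The field defaults to 30 x 17 visual degrees, an
#' order-of-magnitude match for a 24" monitor viewed at 90 cm.
#'
#' @param n_objects total number of objects on screen.
#' @param n_targets number of target objects (`0 < n_targets < n_objects`).
#' @param object_radius object radius in visual degrees.
#' @param speed_min,speed_max per-object speed range in visual degrees/second.
#' @param movement_duration motion phase duration in seconds.
#' @param field_width,field_height field extent in visual degrees.
#' @param timestep integration step in seconds.
#' @param min_separation minimum initial centre-to-centre distance; defaults
#'   to `2 * object_radius` (objects placed at least touching, never
#'   overlapping) so that trials do not open with an instant collision.
#' @return an object of class `"kinematics_config"`.
#' @examples
#' cfg <- kinematics_config()
#' cfg$n_targets
#' @export
kinematics_config <- function(n_objects = 19L, n_targets = 6L,
                              object_radius = 0.56,
                              speed_min = 0.90, speed_max = 1.21,
                              movement_duration = 11,
                              field_width = 30, field_height = 17,
                              timestep = 0.02,
                              min_separation = 2 * object_radius) {
  cfg <- list(
    n_objects = as.integer(n_objects), n_targets = as.integer(n_targets),
    object_radius = object_radius,
    speed_min = speed_min, speed_max = speed_max,
    movement_duration = movement_duration,
    field_width = field_width, field_height = field_height,
    timestep = timestep, min_separation = min_separation
  )
  class(cfg) <- "kinematics_config"
  validate_kinematics_config(cfg)
  cfg
}

validate_kinematics_config <- function(cfg) {
  stopifnot(inherits(cfg, "kinematics_config"))
  if (!(cfg$n_targets > 0L && cfg$n_targets < cfg$n_objects))
    stop("n_targets must satisfy 0 < n_targets < n_objects", call. = FALSE)
  if (cfg$speed_min > cfg$speed_max)
    stop("speed_min must not exceed speed_max", call. = FALSE)
  if (cfg$speed_min < 0)
    stop("speeds must be non-negative", call. = FALSE)
  if (any(c(cfg$object_radius, cfg$field_width, cfg$field_height,
            cfg$timestep) <= 0))
    stop("object_radius, field extents and timestep must be positive",
         call. = FALSE)
  if (cfg$movement_duration < 0)
    stop("movement_duration must be non-negative", call. = FALSE)
  invisible(cfg)
}

# Rejection-sample n non-overlapping centres within the field, keeping every
# centre at least `radius` from the border and `min_sep` from other centres.
place_objects <- function(n, width, height, radius, min_sep, max_tries = 500L) {
  lo_x <- radius; hi_x <- width - radius
  lo_y <- radius; hi_y <- height - radius
  if (hi_x <= lo_x || hi_y <= lo_y)
    stop("field too small to place objects: increase field extent or ",
         "decrease object_radius", call. = FALSE)
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
      if (i == 1L) { placed <- TRUE }
      else {
        d2 <- (pos[seq_len(i - 1L), 1] - p[1])^2 +
              (pos[seq_len(i - 1L), 2] - p[2])^2
        placed <- all(d2 >= min_sep^2)
      }
      if (placed) { pos[i, ] <- p; break }
    }
    if (!placed)
      stop("field too small to place ", n, " objects without overlap",
           call. = FALSE)
  }
  pos
}

#' Simulate the 2D kinematics of one MOT trial
#'
#' Objects are placed at non-overlapping random positions, each is assigned a
#' constant speed drawn uniformly from `[speed_min, speed_max]` and a random
#' fixed direction, and then moves in a straight line. At the field border and
#' on object-object contact the velocity is reflected specularly (the angle of
#' incidence equals the angle of reflection, mirrored about the wall or the
#' contact normal), so each object's speed is conserved throughout the trial.
#'
#' @param config a [kinematics_config()].
#' @param seed integer seed; the trial is a pure function of `(config, seed)`.
#' @return an object of class `"trial_stimulus"`: a list with `target_ids`,
#'   `distractor_ids` (1-based object ids), `cue_x` (object x-positions at cue
#'   offset, used as the left/right labor-division reference), `speeds`,
#'   `times`, and `trajectories`, an array `[n_steps + 1, n_objects, 2]` of
#'   positions.
#' @examples
#' st <- simulate_trial_kinematics(kinematics_config(), seed = 1)
#' range(st$speeds)
#' @export
simulate_trial_kinematics <- function(config = kinematics_config(), seed) {
  validate_kinematics_config(config)
  with_seed(derive_seed(seed, "kinematics"), {
    n <- config$n_objects
    r <- config$object_radius
    pos <- place_objects(n, config$field_width, config$field_height, r,
                         config$min_separation)
    speeds <- stats::runif(n, config$speed_min, config$speed_max)
    theta <- stats::runif(n, 0, 2 * pi)
    vel <- cbind(speeds * cos(theta), speeds * sin(theta))
    n_steps <- max(0L, as.integer(round(config$movement_duration /
                                          config$timestep)))
    traj <- array(NA_real_, c(n_steps + 1L, n, 2L))
    traj[1L, , ] <- pos
    target_ids <- sort(sample.int(n, config$n_targets))

    lims <- c(r, config$field_width - r, r, config$field_height - r)
    dt <- config$timestep
    if (n_steps > 0L) {
      for (s in seq_len(n_steps)) {
        pos <- pos + vel * dt
        # wall reflection: mirror the overshoot, flip the velocity component
        for (k in 1:2) {
          lo <- lims[2L * k - 1L]; hi <- lims[2L * k]
          below <- pos[, k] < lo; above <- pos[, k] > hi
          pos[below, k] <- 2 * lo - pos[below, k]
          pos[above, k] <- 2 * hi - pos[above, k]
          flip <- below | above
          vel[flip, k] <- -vel[flip, k]
        }
        # object-object contact: specular reflection about the contact normal
        # for approaching pairs only (receding pairs are already separating)
        d <- stats::dist(pos)
        hits <- which(as.matrix(d) < 2 * r & upper.tri(as.matrix(d)),
                      arr.ind = TRUE)
        if (nrow(hits) > 0L) {
          for (h in seq_len(nrow(hits))) {
            i <- hits[h, 1L]; j <- hits[h, 2L]
            nrm <- pos[j, ] - pos[i, ]
            nn <- sqrt(sum(nrm^2))
            if (nn < 1e-12) next
            nrm <- nrm / nn
            if (sum((vel[i, ] - vel[j, ]) * nrm) <= 0) next # not approaching
            vel[i, ] <- vel[i, ] - 2 * sum(vel[i, ] * nrm) * nrm
            vel[j, ] <- vel[j, ] - 2 * sum(vel[j, ] * nrm) * nrm
          }
        }
        traj[s + 1L, , ] <- pos
      }
    }
    # specular reflections preserve each object's speed; track the largest
    # numerical deviation of |v| from the assigned speed across the trial
    speed_drift <- max(abs(sqrt(rowSums(vel^2)) - speeds))
    structure(list(
      target_ids = target_ids,
      distractor_ids = setdiff(seq_len(n), target_ids),
      cue_x = traj[1L, , 1L],
      speeds = speeds,
      final_velocities = vel,
      speed_drift = speed_drift,
      times = seq(0, by = dt, length.out = n_steps + 1L),
      trajectories = traj,
      config = config
    ), class = "trial_stimulus")
  })
}
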