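# Closed-loop pick-and-place trial execution with a simulated user, and the
# offline reconstruction procedure (replaying recorded shoulder motion
# through each control).

#' Trial configuration: validation zone and time limit
#'
#' @param distance_tolerance Metres.
#' @param angle_tolerance Degrees (between grasp axes; rotation about the
#'   axis is unconstrained, the object being cylindrical).
#' @param time_limit Seconds.
#' @param freq Simulation rate, Hz.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(distance_tolerance = 0.03, angle_tolerance = 10,
                         time_limit = 6, freq = 90) {
  stopifnot(distance_tolerance > 0, angle_tolerance > 0, time_limit > 0,
            freq > 0)
  structure(list(distance_tolerance = distance_tolerance,
                 angle_tolerance = angle_tolerance,
                 time_limit = time_limit, freq = freq),
            class = "trial_config")
}

#' Preset trial configurations
#'
#' The validation constraints used in the study phases: the first
#' experiment's test phase (4 cm, 10 degrees, 10 s), the second
#' experiment's test phase (3 cm, 10 degrees, 6 s), and the first
#' experiment's familiarization phase (2 cm, 5 degrees, 5 s).
#'
#' @param phase One of `"exp1_test"`, `"exp2_test"`,
#'   `"exp1_familiarization"`.
#' @return A [trial_config()].
#' @export
trial_config_preset <- function(phase = c("exp2_test", "exp1_test",
                                          "exp1_familiarization")) {
  phase <- match.arg(phase)
  switch(phase,
    exp1_test = trial_config(0.04, 10, 10),
    exp2_test = trial_config(0.03, 10, 6),
    exp1_familiarization = trial_config(0.02, 5, 5))
}

#' Is a hand pose inside the target validation zone?
#'
#' True iff the hand position is within the distance tolerance of the
#' target position and the angle between the hand's grasp axis and the
#' target's grasp axis is within the angle tolerance. Spin about the grasp
#' axis is unconstrained (cylindrical object).
#'
#' @param pose A `hand_pose`.
#' @param target A [target_spec()].
#' @param cfg A [trial_config()].
#' @return Logical.
#' @export
validate_pose <- function(pose, target, cfg) {
  if (vnorm(pose$position - target$position) > cfg$distance_tolerance)
    return(FALSE)
  taxis <- axis_from_alpha_beta(target$alpha, target$beta)
  deg_angle_between(pose$axis, taxis) <= cfg$angle_tolerance
}

#' Simulated user of the hybrid arm
#'
#' A stand-in for the human participant: drives the two proximal joints
#' from the trial's start posture toward a goal shoulder configuration with
#' a minimum-jerk (or constant-speed) reach, then hunts --- it keeps
#' stepping the shoulder in a direction that lowered the observed pose
#' error on the previous tick, picking a fresh direction whenever the
#' error grew (observation-driven hill climbing, emulating the visually
#' guided shoulder adjustments participants make until the object
#' validates). Optional Gaussian angle noise models tracking jitter; a
#' nonzero reaction delay models the time a human takes to press the
#' validation button after zone entry.
#'
#' @param goal_proximal Named `c(sfe =, saa =)` degrees the user aims for.
#' @param reach_duration Duration of the initial reach, seconds.
#' @param profile `"minimum_jerk"` or `"constant_speed"` for the reach.
#' @param noise_sd Gaussian angle noise sd per tick, degrees (0 = none).
#' @param search_step Hunting step per tick, degrees (0 disables hunting:
#'   the user freezes at the end of the reach).
#' @param reaction_delay Seconds between zone entry and button press.
#' @return Object of class `simulated_user`.
#' @export
simulated_user <- function(goal_proximal, reach_duration = 1.5,
                           profile = c("minimum_jerk", "constant_speed"),
                           noise_sd = 0, search_step = 0.9,
                           reaction_delay = 0) {
  profile <- match.arg(profile)
  stopifnot(reach_duration > 0, noise_sd >= 0, search_step >= 0,
            reaction_delay >= 0)
  structure(list(goal_proximal = goal_proximal[PROXIMAL_NAMES],
                 reach_duration = reach_duration, profile = profile,
                 noise_sd = noise_sd, search_step = search_step,
                 reaction_delay = reaction_delay),
            class = "simulated_user")
}

# user-perceived pose error: normalized position error plus normalized
# excess of the axis angle over half the tolerance margins
perceived_cost <- function(pose, target, target_axis, cfg) {
  pe <- vnorm(pose$position - target$position)
  ae <- deg_angle_between(pose$axis, target_axis)
  max(0, pe - 0.5 * cfg$distance_tolerance) / cfg$distance_tolerance +
    max(0, ae - 0.5 * cfg$angle_tolerance) / cfg$angle_tolerance
}

#' Run one closed-loop pick-or-place trial
#'
#' Ticks at `cfg$freq`: the simulated user emits proximal angles, the
#' chosen control emits distal angles, and the trial succeeds at the first
#' validated tick (after the user's reaction delay) or fails at the time
#' limit. Controls: `"interpolation"` (angular-interpolation law over a
#' PC+ or C+ goal prediction), `"direct"` (predictions applied verbatim,
#' historically with a PC- network), `"natural_replay"` (the virtual arm
#' mimics the full 7-joint natural movement to the target's generating
#' posture --- the gold standard; requires the target to carry one).
#'
#' @param control `"interpolation"`, `"direct"` or `"natural_replay"`.
#' @param predictor A trained predictor (not used by natural_replay).
#' @param user A [simulated_user()] (its goal is ignored by natural_replay,
#'   which replays the generating movement over `user$reach_duration`).
#' @param target A [target_spec()] (see [target_from_set()]).
#' @param geometry,rom Arm geometry and range of motion.
#' @param cfg A [trial_config()].
#' @param start Full 7-joint start posture, degrees.
#' @param seed RNG seed for user noise.
#' @return Object of class `trial_record`: list with `target`,
#'   `trajectory` (data frame `t`, joint angles, hand `x`,`y`,`z`,
#'   `valid`), `success`, `movement_time`, `validation_time`,
#'   `zone_entry_times`, `final_angles`.
#' @export
run_trial <- function(control = c("interpolation", "direct",
                                  "natural_replay"),
                      predictor = NULL, user, target, geometry, rom,
                      cfg = trial_config_preset("exp2_test"),
                      start, seed = NULL) {
  control <- match.arg(control)
  if (control != "natural_replay" && is.null(predictor))
    stop("control '", control, "' requires a predictor")
  if (control == "natural_replay" && is.null(target$posture))
    stop("natural_replay requires a target with a generating posture")
  start <- as_joint_angles(start)
  with_local_seed(seed, {
    freq <- cfg$freq
    nmax <- ceiling(cfg$time_limit * freq)
    # precompute the open-loop part of the user's motion
    n_reach <- max(1L, round(user$reach_duration * freq))
    s_reach <- if (user$profile == "constant_speed") (1:n_reach) / n_reach
               else min_jerk_profile((1:n_reach) / n_reach)
    replay <- NULL
    if (control == "natural_replay")
      replay <- generate_natural_movement(start, target$posture,
                                          user$reach_duration, freq)
    state <- controller_state(distal_of(start),
                              forward_kinematics(geometry, start)$position,
                              time = 0,
                              target_id = target_identifier(target))
    prox <- proximal_of(start)
    prox_goal <- user$goal_proximal
    angles <- start
    target_axis <- axis_from_alpha_beta(target$alpha, target$beta)
    hunt_dir <- c(0, 0)
    last_cost <- Inf
    last_cost_grew <- TRUE
    rows <- matrix(NA_real_, nmax, 12)
    colnames(rows) <- c("t", JOINT_NAMES, "x", "y", "z", "valid")
    success <- FALSE
    movement_time <- NA_real_
    validation_time <- NA_real_
    entry_time <- NA_real_
    entries <- numeric(0)
    prev_valid <- FALSE
    for (k in seq_len(nmax)) {
      t_now <- k / freq
      # --- user: proximal command
      if (control == "natural_replay") {
        idx <- min(k + 1L, nrow(replay))
        angles_nat <- as_joint_angles(stats::setNames(
          as.numeric(replay[idx, JOINT_NAMES]), JOINT_NAMES))
        prox <- proximal_of(angles_nat)
      } else if (k <= n_reach) {
        prox <- proximal_of(start) +
          s_reach[k] * (prox_goal - proximal_of(start))
      } else if (user$search_step > 0) {
        if (!is.finite(last_cost) || last_cost_grew) {
          a <- stats::runif(1, 0, 2 * pi)
          hunt_dir <- c(cos(a), sin(a))
        }
        prox <- prox + user$search_step * stats::setNames(hunt_dir,
                                                          PROXIMAL_NAMES)
      }
      if (user$noise_sd > 0 && control != "natural_replay")
        prox <- prox + stats::rnorm(2, 0, user$noise_sd)
      # --- control: distal command
      if (control == "interpolation") {
        st <- interpolation_step(geometry, predictor, rom, target, prox,
                                 state, t_now,
                                 controller_config(freq = freq))
        distal <- st$distal
        state <- st$state
      } else if (control == "direct") {
        distal <- direct_step(predictor, rom, target, prox)
      } else {
        distal <- distal_of(angles_nat)
      }
      angles <- as_joint_angles(c(prox[PROXIMAL_NAMES], distal))
      pose <- forward_kinematics(geometry, angles)
      valid <- validate_pose(pose, target, cfg)
      cost <- perceived_cost(pose, target, target_axis, cfg)
      last_cost_grew <- cost >= last_cost
      last_cost <- cost
      rows[k, ] <- c(t_now, angles, pose$position, as.numeric(valid))
      if (valid && !prev_valid) {
        entry_time <- t_now
        entries <- c(entries, t_now)
      }
      prev_valid <- valid
      if (valid && t_now - entry_time >= user$reaction_delay) {
        success <- TRUE
        movement_time <- t_now
        validation_time <- t_now - entry_time
        rows <- rows[seq_len(k), , drop = FALSE]
        break
      }
    }
    traj <- as.data.frame(rows)
    traj$valid <- as.logical(traj$valid)
    class(traj) <- c("arm_trajectory", "data.frame")
    structure(list(target = target, trajectory = traj, success = success,
                   movement_time = movement_time,
                   validation_time = validation_time,
                   zone_entry_times = entries,
                   final_angles = angles),
              class = "trial_record")
  })
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial: %s%s\n",
              if (x$success) "success" else "failure",
              if (x$success) sprintf(" (MT %.2f s, VT %.2f s)",
                                     x$movement_time, x$validation_time)
              else ""))
  invisible(x)
}

#' Replay recorded shoulder motion through a control (general form)
#'
#' Drives a control tick-by-tick with the proximal angles of a recorded
#' trajectory, under a possibly changing target, and returns the
#' reconstructed full 7-joint trajectory. `natural_replay` is the identity
#' on the distal joints.
#'
#' @param trajectory An `arm_trajectory` (timestamps + seven joints).
#' @param targets List of [target_spec()]s.
#' @param target_of_tick Integer vector (length `nrow(trajectory)`) giving
#'   the active target index per frame.
#' @param control,predictor,geometry,rom,cfg As in [run_trial()].
#' @return An `arm_trajectory` of equal length.
#' @export
reconstruct_trajectory <- function(trajectory, targets, target_of_tick,
                                   control = c("interpolation", "direct",
                                               "natural_replay"),
                                   predictor = NULL, geometry, rom,
                                   cfg = trial_config_preset("exp2_test")) {
  control <- match.arg(control)
  n <- nrow(trajectory)
  stopifnot(length(target_of_tick) == n)
  out <- as.matrix(trajectory[c("t", JOINT_NAMES)])
  if (control == "natural_replay") {
    res <- as.data.frame(out)
    class(res) <- c("arm_trajectory", "data.frame")
    return(res)
  }
  start <- as_joint_angles(stats::setNames(as.numeric(out[1, JOINT_NAMES]),
                                           JOINT_NAMES))
  state <- controller_state(distal_of(start),
                            forward_kinematics(geometry, start)$position,
                            time = out[1, "t"],
                            target_id = target_identifier(
                              targets[[target_of_tick[1]]]))
  for (k in 2:n) {
    tg <- targets[[target_of_tick[k]]]
    prox <- stats::setNames(as.numeric(out[k, PROXIMAL_NAMES]),
                            PROXIMAL_NAMES)
    if (control == "interpolation") {
      state <- reset_on_target_change(state, tg)
      st <- interpolation_step(geometry, predictor, rom, tg, prox, state,
                               out[k, "t"],
                               controller_config(freq = cfg$freq))
      out[k, DISTAL_NAMES] <- st$distal
      state <- st$state
    } else {
      out[k, DISTAL_NAMES] <- direct_step(predictor, rom, tg, prox)
    }
  }
  res <- as.data.frame(out)
  class(res) <- c("arm_trajectory", "data.frame")
  res
}

#' Offline reconstruction of a successful natural trial
#'
#' Applies a control strategy to the shoulder movement recorded in a
#' successful natural trial, as if the user's proximal motion had driven a
#' hybrid arm, and returns the reconstructed trajectory for comparison
#' against the natural one (see [offline_distances()]).
#'
#' @param control,predictor,geometry,rom,cfg As in [run_trial()].
#' @param natural_trial A successful `trial_record`.
#' @return An `arm_trajectory` of the same length as the input.
#' @export
offline_reconstruct <- function(control, natural_trial, predictor = NULL,
                                geometry, rom,
                                cfg = trial_config_preset("exp2_test")) {
  if (!isTRUE(natural_trial$success))
    stop("offline reconstruction requires a successful trial")
  tr <- natural_trial$trajectory
  reconstruct_trajectory(tr, list(natural_trial$target),
                         rep(1L, nrow(tr)), control, predictor,
                         geometry, rom, cfg)
}

#' Default trial-exclusion filter
#'
#' Drops trials exhibiting a physically implausible hand jump between
#' consecutive ticks (default over 0.5 m), emulating the exclusion of
#' motion-capture measurement artifacts.
#'
#' @param record A `trial_record`.
#' @param max_jump Metres.
#' @return TRUE to keep the trial.
#' @export
default_trial_filter <- function(record, max_jump = 0.5) {
  p <- as.matrix(record$trajectory[c("x", "y", "z")])
  if (nrow(p) < 2) return(TRUE)
  max(sqrt(rowSums(diff(p)^2))) <= max_jump
}

#' Run a phase: a sequence of pick-and-place trials
#'
#' Runs all targets in order, each trial starting from the previous
#' trial's final posture (pick/place alternation), applies the
#' trial-exclusion filter, and aggregates the per-phase metrics.
#'
#' @param targets A `target_set` data frame with generating postures.
#' @param control,predictor,geometry,rom,cfg As in [run_trial()].
#' @param user_args List of arguments for [simulated_user()] (the per-trial
#'   `goal_proximal` is filled in from each target's generating posture).
#' @param start Start posture of the first trial; defaults to the mid-range
#'   posture of `rom`.
#' @param seed RNG seed (per-trial seeds are derived from it).
#' @param trial_filter Function `trial_record -> logical` (keep); `NULL`
#'   disables filtering.
#' @return Object of class `phase_result`: list with `records` (kept
#'   trials), `excluded` (count), and `metrics` (a [phase_metrics()]
#'   report).
#' @export
run_phase <- function(targets, control, predictor = NULL, geometry, rom,
                      cfg = trial_config_preset("exp2_test"),
                      user_args = list(), start = NULL, seed = NULL,
                      trial_filter = default_trial_filter) {
  stopifnot(nrow(targets) > 0)
  if (is.null(start)) {
    start <- as_joint_angles(stats::setNames(
      (rom$min_deg + rom$max_deg) / 2, JOINT_NAMES))
  }
  records <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- target_from_set(targets, i)
    if (is.null(tg$posture))
      stop("run_phase requires targets with generating postures (gen_* columns)")
    user <- do.call(simulated_user,
                    c(list(goal_proximal = proximal_of(tg$posture)),
                      user_args))
    records[[i]] <- run_trial(control, predictor, user, tg, geometry, rom,
                              cfg, start,
                              seed = if (is.null(seed)) NULL else seed + i)
    start <- records[[i]]$final_angles
  }
  keep <- if (is.null(trial_filter)) rep(TRUE, length(records))
          else vapply(records, trial_filter, logical(1))
  kept <- records[keep]
  structure(list(records = kept, excluded = sum(!keep),
                 metrics = phase_metrics(kept, geometry)),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("phase: %d trials kept, %d excluded, success rate %.1f%%\n",
              length(x$records), x$excluded, x$metrics$summary$success_rate))
  invisible(x)
}
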