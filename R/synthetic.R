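# Synthetic natural-movement generation: minimum-jerk pick-and-place
# trajectories, target sets, training samples and a simulated user's
# shoulder motion. Stands in for recorded human movements so the whole
# control stack can be exercised and tested without any capture hardware.

#' Minimum-jerk joint-space movement between two postures
#'
#' Each joint follows the minimum-jerk position profile
#' `10*tau^3 - 15*tau^4 + 6*tau^5`, giving zero velocity and acceleration at
#' both endpoints and a single-peaked, bell-shaped speed profile --- the
#' standard model of natural point-to-point reaching.
#'
#' @param start,end Joint angles (degrees), coerced with [as_joint_angles()].
#' @param duration Movement duration, seconds (> 0).
#' @param freq Sampling frequency, Hz (default 90).
#' @return A trajectory: data frame of class `arm_trajectory` with column
#'   `t` (seconds) and one column per joint (degrees).
#' @export
generate_natural_movement <- function(start, end, duration, freq = 90) {
  stopifnot(duration > 0, freq > 0)
  start <- as_joint_angles(start)
  end <- as_joint_angles(end)
  n <- max(1L, round(duration * freq))
  tau <- (0:n) / n
  s <- min_jerk_profile(tau)
  ang <- outer(s, end - start) + rep(start, each = n + 1L)
  colnames(ang) <- JOINT_NAMES
  out <- data.frame(t = (0:n) / freq, ang)
  class(out) <- c("arm_trajectory", "data.frame")
  out
}

#' Sample joint configurations uniformly inside a range of motion
#'
#' @param rom A [range_of_motion()].
#' @param n Number of configurations.
#' @param elbow_scale Fraction of the elbow span kept (about its midpoint)
#'   before sampling; 1 means the full range.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return n x 7 matrix of angles (degrees), canonical column order.
#' @export
sample_rom_postures <- function(rom, n, elbow_scale = 1, seed = NULL) {
  stopifnot(n > 0)
  if (elbow_scale < 1) rom <- scale_rom_joint(rom, "efe", elbow_scale)
  with_local_seed(seed, {
    m <- vapply(JOINT_NAMES, function(j)
      stats::runif(n, rom[j, "min_deg"], rom[j, "max_deg"]), numeric(n))
    matrix(m, nrow = n, dimnames = list(NULL, JOINT_NAMES))
  })
}

# FK over the rows of an angle matrix; returns data.frame x,y,z,alpha,beta
context_of_postures <- function(geometry, angles) {
  n <- nrow(angles)
  out <- matrix(0, n, 5, dimnames = list(NULL, c("x", "y", "z", "alpha", "beta")))
  for (i in seq_len(n)) {
    p <- forward_kinematics(geometry, angles[i, ])
    out[i, ] <- c(p$position, p$alpha, p$beta)
  }
  as.data.frame(out)
}

#' Generate a 'plausible' target set from the range of motion
#'
#' Each target is the pose of a hypothetical object held by a hand at a
#' joint configuration drawn uniformly within the range of motion (elbow
#' interval shrunk to `elbow_scale` of its span about its midpoint, default
#' 85%, to avoid fully-extended arm postures). Every target is reachable by
#' construction; the generating posture is retained in `gen_*` columns.
#'
#' @param geometry An [arm_geometry()].
#' @param rom A [range_of_motion()].
#' @param n Number of targets (default 300).
#' @param elbow_scale Elbow span fraction in (0, 1], default 0.85.
#' @param seed RNG seed; the same seed reproduces the set bit-for-bit.
#' @return Data frame of class `target_set`: columns `id`, `x`, `y`, `z`,
#'   `alpha`, `beta` and `gen_sfe` ... `gen_wfe`.
#' @export
sample_plausible_targets <- function(geometry, rom, n = 300,
                                     elbow_scale = 0.85, seed = NULL) {
  stopifnot(n > 0, elbow_scale > 0, elbow_scale <= 1)
  ang <- sample_rom_postures(rom, n, elbow_scale = elbow_scale, seed = seed)
  ctx <- context_of_postures(geometry, ang)
  gen <- as.data.frame(ang)
  names(gen) <- paste0("gen_", JOINT_NAMES)
  out <- cbind(data.frame(id = seq_len(n)), ctx, gen)
  class(out) <- c("target_set", "data.frame")
  out
}

#' Generate a 'possible' target set from performed movements
#'
#' Targets are drawn from configurations actually visited by the supplied
#' trajectories, mimicking a target set derived from a user's own movements
#' during an acquisition phase.
#'
#' @param trajectories Non-empty list of trajectory data frames.
#' @param geometry An [arm_geometry()].
#' @param n Number of targets (default 200).
#' @param seed RNG seed.
#' @return A `target_set` data frame (see [sample_plausible_targets()]).
#' @export
sample_possible_targets <- function(trajectories, geometry, n = 200,
                                    seed = NULL) {
  if (length(trajectories) == 0) stop("empty trajectory pool")
  frames <- do.call(rbind, lapply(trajectories, function(tr)
    as.matrix(tr[JOINT_NAMES])))
  idx <- with_local_seed(seed,
    sample.int(nrow(frames), n, replace = n > nrow(frames)))
  ang <- frames[idx, , drop = FALSE]
  ctx <- context_of_postures(geometry, ang)
  gen <- as.data.frame(ang)
  names(gen) <- paste0("gen_", JOINT_NAMES)
  out <- cbind(data.frame(id = seq_len(n)), ctx, gen)
  class(out) <- c("target_set", "data.frame")
  out
}

# one row of a target_set -> target_spec (generating posture kept if present)
#' Extract one target from a target set
#'
#' @param targets A `target_set` data frame.
#' @param i Row index.
#' @return A [target_spec()]; the generating posture, when present, is
#'   attached as field `posture`.
#' @export
target_from_set <- function(targets, i) {
  row <- targets[i, ]
  tg <- target_spec(c(row$x, row$y, row$z), row$alpha, row$beta, id = row$id)
  gcols <- paste0("gen_", JOINT_NAMES)
  if (all(gcols %in% names(row))) {
    tg$posture <- as_joint_angles(stats::setNames(as.numeric(row[gcols]),
                                                  JOINT_NAMES))
  }
  tg
}

#' Synthesize a natural pick-and-place movement database
#'
#' Emulates a multi-participant database of natural 7-joint pick-and-place
#' movements: each synthetic participant gets an independently jittered
#' range of motion, and performs a chain of minimum-jerk movements between
#' postures sampled inside it (each trial starting from the previous trial's
#' end posture, as in alternating pick and place).
#'
#' @param geometry An [arm_geometry()].
#' @param rom Base [range_of_motion()].
#' @param n_movements Total number of movements (default 400, giving on the
#'   order of 5e4 frames at 90 Hz with 1--2 s durations).
#' @param n_participants Number of synthetic participants (default 12).
#' @param duration_range Min/max movement duration, seconds (uniform).
#' @param freq Sampling rate, Hz.
#' @param rom_jitter Half-width (degrees) of the uniform jitter applied to
#'   each participant's ROM limits.
#' @param elbow_scale Elbow span fraction used when sampling postures.
#' @param seed RNG seed.
#' @return List of `arm_trajectory` data frames.
#' @export
synthesize_movement_database <- function(geometry, rom, n_movements = 400,
                                         n_participants = 12,
                                         duration_range = c(1, 2), freq = 90,
                                         rom_jitter = 5, elbow_scale = 0.85,
                                         seed = NULL) {
  stopifnot(n_movements > 0, n_participants > 0)
  with_local_seed(seed, {
    per <- diff(round(seq(0, n_movements, length.out = n_participants + 1)))
    out <- vector("list", n_movements)
    k <- 0L
    for (p in seq_len(n_participants)) {
      if (per[p] == 0) next
      jit_lo <- stats::runif(7, -rom_jitter, rom_jitter)
      jit_hi <- stats::runif(7, -rom_jitter, rom_jitter)
      prom <- range_of_motion(
        stats::setNames(rom$min_deg + jit_lo, JOINT_NAMES),
        stats::setNames(rom$max_deg + jit_hi, JOINT_NAMES))
      post <- sample_rom_postures(prom, per[p] + 1L, elbow_scale = elbow_scale)
      dur <- stats::runif(per[p], duration_range[1], duration_range[2])
      for (m in seq_len(per[p])) {
        k <- k + 1L
        out[[k]] <- generate_natural_movement(post[m, ], post[m + 1L, ],
                                              duration = dur[m], freq = freq)
      }
    }
    out[seq_len(k)]
  })
}

#' Build a training set from movements and a user's arm geometry
#'
#' Morphology retargeting: the recorded angular configurations are applied
#' to a virtual arm with the user's segment lengths, and for every frame the
#' pose of a hypothetical target placed in that hand (position x, y, z and
#' grasp-axis angles alpha, beta) is computed in the shoulder frame. Each
#' frame yields one sample pairing that context with the seven joint angles.
#'
#' @param trajectories List of trajectory data frames.
#' @param geometry The user's [arm_geometry()].
#' @return Data frame of class `training_set`: columns `x`, `y`, `z`,
#'   `alpha`, `beta`, then the seven joint angles.
#' @export
build_training_set <- function(trajectories, geometry) {
  stopifnot(length(trajectories) > 0)
  ang <- do.call(rbind, lapply(trajectories, function(tr)
    as.matrix(tr[JOINT_NAMES])))
  ctx <- context_of_postures(geometry, ang)
  out <- cbind(ctx, as.data.frame(ang))
  class(out) <- c("training_set", "data.frame")
  out
}

#' Simulated user shoulder motion toward a goal
#'
#' Proximal-only trajectory from a start to a goal shoulder configuration,
#' standing in for the human participant driving the hybrid arm.
#'
#' @param start_proximal,goal_proximal Named `c(sfe =, saa =)` degrees.
#' @param duration Seconds.
#' @param freq Hz.
#' @param profile `"minimum_jerk"` (bell-shaped speed), `"constant_speed"`
#'   (linear ramp), or `"noisy"` (minimum jerk plus i.i.d. Gaussian angle
#'   noise of sd `noise_sd`).
#' @param noise_sd Noise standard deviation, degrees (noisy profile).
#' @param seed RNG seed for the noisy profile.
#' @return Data frame with columns `t`, `sfe`, `saa`.
#' @export
simulate_user_shoulder <- function(start_proximal, goal_proximal, duration,
                                   freq = 90,
                                   profile = c("minimum_jerk",
                                               "constant_speed", "noisy"),
                                   noise_sd = 0, seed = NULL) {
  profile <- match.arg(profile)
  stopifnot(duration > 0)
  start_proximal <- start_proximal[PROXIMAL_NAMES]
  goal_proximal <- goal_proximal[PROXIMAL_NAMES]
  n <- max(1L, round(duration * freq))
  tau <- (0:n) / n
  s <- if (profile == "constant_speed") tau else min_jerk_profile(tau)
  ang <- outer(s, goal_proximal - start_proximal) +
    rep(start_proximal, each = n + 1L)
  if (profile == "noisy" && noise_sd > 0) {
    ang <- ang + with_local_seed(seed,
      matrix(stats::rnorm(length(ang), 0, noise_sd), nrow(ang)))
  }
  colnames(ang) <- PROXIMAL_NAMES
  data.frame(t = (0:n) / freq, ang)
}

#' Read/write trajectories and target sets as CSV
#'
#' Trajectories are tidy CSV with columns `t`, `sfe` ... `wfe`; target sets
#' with columns `id`, `x`, `y`, `z`, `alpha`, `beta` (plus any `gen_*`
#' generating-posture columns).
#'
#' @param x Object to write.
#' @param file Path.
#' @return Readers return the object; writers return `file` invisibly.
#' @export
write_trajectory <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  out <- utils::read.csv(file)
  if (!all(c("t", JOINT_NAMES) %in% names(out)))
    stop("trajectory CSV must have columns t, ", paste(JOINT_NAMES, collapse = ", "))
  if (any(diff(out$t) <= 0)) stop("timestamps must be strictly increasing")
  class(out) <- c("arm_trajectory", "data.frame")
  out
}

#' @rdname write_trajectory
#' @export
write_targets <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_targets <- function(file) {
  out <- utils::read.csv(file)
  if (!all(c("x", "y", "z", "alpha", "beta") %in% names(out)))
    stop("target CSV must have columns x, y, z, alpha, beta")
  if (is.null(out$id)) out$id <- seq_len(nrow(out))
  class(out) <- c("target_set", "data.frame")
  out
}
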