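# Angular-interpolation control of the five distal joints.
#
# At every tick the controller (i) predicts and saturates a 'goal' distal
# configuration, (ii) measures the user's locked-hand displacement (hand
# motion with the distal joints frozen, so only proximal motion counts),
# and (iii) moves each distal joint a fraction of its remaining angular gap
# equal to the ratio of that displacement to the remaining hand-to-target
# distance. A joint within 1 degree of its goal latches onto the prediction
# until the target changes. The historical direct control (predictions
# applied verbatim each tick) is provided for comparison.

#' Controller configuration
#'
#' @param freq Control-loop frequency, Hz (default 90).
#' @param latch_threshold Gap below which a joint latches onto the
#'   prediction, degrees (default 1).
#' @param clip Clip the per-tick interpolation fraction to \[0, 1\] so a
#'   joint never overshoots its goal when the locked-hand displacement
#'   exceeds the remaining distance (default TRUE).
#' @return Object of class `controller_config`.
#' @export
controller_config <- function(freq = 90, latch_threshold = 1, clip = TRUE) {
  stopifnot(freq > 0, latch_threshold > 0)
  structure(list(freq = freq, latch_threshold = latch_threshold, clip = clip),
            class = "controller_config")
}

#' Controller state
#'
#' The interpolation controller's memory between ticks: the distal angles
#' and hand position it last commanded, the time of that command, the
#' per-joint latch flags, and the identifier of the current target.
#'
#' @param distal Named distal angles at t-1, degrees.
#' @param hand Hand position at t-1 (3-vector, metres) --- the forward
#'   kinematics of the full configuration last commanded.
#' @param time Time of the last command, seconds.
#' @param target_id Identifier of the current target.
#' @return Object of class `controller_state`.
#' @export
controller_state <- function(distal, hand, time = 0, target_id = NULL) {
  distal <- distal[DISTAL_NAMES]
  stopifnot(all(is.finite(distal)), length(hand) == 3L)
  structure(list(distal_prev = distal, hand_prev = as.numeric(hand),
                 time_prev = time,
                 latched = stats::setNames(rep(FALSE, 5), DISTAL_NAMES),
                 target_id = target_id),
            class = "controller_state")
}

target_identifier <- function(target) {
  if (!is.null(target$id)) return(as.character(target$id))
  paste(signif(c(target$position, target$alpha, target$beta), 12),
        collapse = "|")
}

#' Remaining angular gap to the goal
#'
#' Per-joint angular displacement yet to be achieved: the difference
#' between the (saturated) predicted goal and the previously commanded
#' distal angles.
#'
#' @param goal Named distal goal angles, degrees (post-saturation).
#' @param state A [controller_state()].
#' @return Named numeric vector, degrees.
#' @export
compute_gap <- function(goal, state) {
  goal[DISTAL_NAMES] - state$distal_prev
}

#' Locked-hand speed
#'
#' Hand speed approximated from the displacement of the locked-hand
#' position (distal joints frozen at their previous values) over the tick
#' interval, so that controller-driven distal motion cannot feed back into
#' its own rate.
#'
#' @param geometry An [arm_geometry()].
#' @param proximal_now Current proximal angles, degrees.
#' @param state A [controller_state()].
#' @param time_now Current time, seconds (> `state$time_prev`).
#' @return Speed in m/s.
#' @export
locked_hand_speed <- function(geometry, proximal_now, state, time_now) {
  dt <- time_now - state$time_prev
  if (dt <= 0) stop("time must strictly increase across controller updates")
  ph <- locked_hand_position(geometry, proximal_now, state$distal_prev)
  vnorm(ph - state$hand_prev) / dt
}

#' Estimated movement time to target
#'
#' Remaining hand-to-target distance divided by the current (locked-hand)
#' speed.
#'
#' @param target A [target_spec()].
#' @param hand_now Current hand position, metres.
#' @param speed Hand speed, m/s (> 0; the zero-speed branch is handled by
#'   [interpolation_step()], which holds the distal joints still).
#' @return Seconds.
#' @export
estimate_movement_time <- function(target, hand_now, speed) {
  if (speed <= 0) stop("speed must be > 0")
  vnorm(target$position - hand_now) / speed
}

#' Low-level angular interpolation update
#'
#' One tick of the interpolation law for the five distal joints, expressed
#' either as the distance-ratio form (gap times locked-hand displacement
#' over remaining distance) or the equivalent estimated-movement-time form
#' (gap over estimated movement time times loop frequency). The two forms
#' coincide when the update rate equals the sampling rate.
#'
#' Per joint: a latched joint, or one whose |gap| falls below
#' `latch_threshold`, outputs the goal directly (and stays latched); with
#' zero locked-hand displacement the joint holds its previous value;
#' otherwise it moves by gap times the interpolation fraction, optionally
#' clipped to \[0, 1\].
#'
#' @param prev Named distal angles at t-1, degrees.
#' @param goal Named (saturated) goal angles, degrees.
#' @param displacement Locked-hand displacement over the tick, metres.
#' @param remaining Remaining hand-to-target distance, metres.
#' @param latched Named logical latch flags.
#' @param latch_threshold Degrees (default 1).
#' @param form `"distance_ratio"` or `"time_estimate"`.
#' @param dt Tick interval, seconds (time-estimate form).
#' @param freq Loop frequency, Hz (time-estimate form).
#' @param clip Clip the fraction to \[0, 1\].
#' @return List with `angles` (named distal angles) and `latched`.
#' @export
angular_update <- function(prev, goal, displacement, remaining, latched,
                           latch_threshold = 1,
                           form = c("distance_ratio", "time_estimate"),
                           dt = NULL, freq = NULL, clip = TRUE) {
  form <- match.arg(form)
  prev <- prev[DISTAL_NAMES]
  goal <- goal[DISTAL_NAMES]
  gap <- goal - prev
  now_latched <- latched[DISTAL_NAMES] | abs(gap) < latch_threshold
  out <- prev
  out[now_latched] <- goal[now_latched]
  free <- !now_latched
  if (any(free) && displacement > 0) {
    frac <- if (form == "distance_ratio") {
      if (remaining > 0) displacement / remaining else 1
    } else {
      stopifnot(!is.null(dt), !is.null(freq), dt > 0)
      speed <- displacement / dt
      if (remaining > 0) 1 / ((remaining / speed) * freq) else 1
    }
    if (clip) frac <- max(0, min(1, frac))
    out[free] <- prev[free] + gap[free] * frac
  }
  list(angles = out, latched = now_latched)
}

#' One tick of interpolation control
#'
#' Computes the saturated goal prediction for the current target, measures
#' the locked-hand displacement since the last tick, and applies
#' [angular_update()]. The state advances: the commanded distal angles,
#' the hand position of the full new configuration, and the time are
#' stored for the next tick.
#'
#' @param geometry An [arm_geometry()].
#' @param predictor A trained [train_predictor()] (PC+ or C+ typically).
#' @param rom A [range_of_motion()] for goal saturation.
#' @param target A [target_spec()]; must match `state$target_id` (call
#'   [reset_on_target_change()] when the target changes).
#' @param proximal_now Current proximal angles, degrees.
#' @param state A [controller_state()].
#' @param time_now Current time, seconds.
#' @param config A [controller_config()].
#' @return List with `distal` (commanded angles) and `state` (advanced).
#' @export
interpolation_step <- function(geometry, predictor, rom, target,
                               proximal_now, state, time_now,
                               config = controller_config()) {
  tid <- target_identifier(target)
  if (is.null(state$target_id)) {
    state$target_id <- tid
  } else if (!identical(state$target_id, tid)) {
    stop("target changed without reset_on_target_change()")
  }
  prox <- if (predictor$spec$variant == "C+") NULL else proximal_now
  goal <- saturate(predict_goal(predictor, target, prox), rom)
  ph_lock <- locked_hand_position(geometry, proximal_now, state$distal_prev)
  displacement <- vnorm(ph_lock - state$hand_prev)
  remaining <- vnorm(target$position - ph_lock)
  upd <- angular_update(state$distal_prev, goal, displacement, remaining,
                        state$latched, config$latch_threshold,
                        clip = config$clip)
  state$distal_prev <- upd$angles
  state$latched <- upd$latched
  state$hand_prev <- forward_kinematics(
    geometry, c(proximal_now[PROXIMAL_NAMES], upd$angles))$position
  state$time_prev <- time_now
  list(distal = upd$angles, state = state)
}

#' One tick of direct control
#'
#' The historical comparison control: the (saturated) network prediction is
#' applied verbatim to the five distal joints, with no state and no
#' smoothing --- at a target change the output may jump by the full
#' prediction gap in a single tick.
#'
#' @param predictor A trained predictor (variant PC- in the original
#'   control; any variant is accepted).
#' @param rom A [range_of_motion()].
#' @param target A [target_spec()].
#' @param proximal_now Current proximal angles (ignored for C+).
#' @return Named distal angles, degrees.
#' @export
direct_step <- function(predictor, rom, target, proximal_now) {
  prox <- if (predictor$spec$variant == "C+") NULL else proximal_now
  saturate(predict_goal(predictor, target, prox), rom)
}

#' Reset the controller on a target change
#'
#' Clears the per-joint latch flags for the new target while preserving the
#' distal angles, hand position and time --- the arm continues from where
#' it is, with no jump; the new goal is approached by interpolation. A
#' reset with the unchanged target id is a no-op.
#'
#' @param state A [controller_state()].
#' @param new_target Either a [target_spec()] or a target id.
#' @return Updated `controller_state`.
#' @export
reset_on_target_change <- function(state, new_target) {
  tid <- if (inherits(new_target, "target_spec"))
    target_identifier(new_target) else as.character(new_target)
  if (identical(state$target_id, tid)) return(state)
  state$latched <- stats::setNames(rep(FALSE, 5), DISTAL_NAMES)
  state$target_id <- tid
  state
}
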