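# per-joint ranges of motion

#' Range of motion for the seven joints
#'
#' @param min_deg,max_deg Named numeric vectors (canonical joint names) of
#'   per-joint lower and upper angular limits in degrees.
#' @return Object of class `range_of_motion`: data frame with columns
#'   `joint`, `min_deg`, `max_deg`.
#' @examples
#' rom <- default_rom()
#' rom["efe", ]
#' @export
range_of_motion <- function(min_deg, max_deg) {
  min_deg <- as_joint_angles(min_deg)
  max_deg <- as_joint_angles(max_deg)
  if (!all(min_deg < max_deg)) stop("min_deg must be < max_deg for every joint")
  structure(
    data.frame(joint = JOINT_NAMES, min_deg = unname(min_deg),
               max_deg = unname(max_deg), row.names = JOINT_NAMES),
    class = c("range_of_motion", "data.frame")
  )
}

#' Default anatomical ranges of motion
#'
#' Representative adult ranges (degrees) for the seven joints, emulating the
#' per-participant limits a calibration procedure would estimate from the
#' extreme values a user can reach: shoulder flexion/extension -40..160,
#' adduction/abduction -30..100, humeral rotation -80..60, elbow
#' flexion 0..145, pronation/supination -80..80, radial/ulnar
#' deviation -30..30, wrist flexion/extension -70..70.
#'
#' @return A [range_of_motion()].
#' @export
default_rom <- function() {
  range_of_motion(
    min_deg = c(sfe = -40, saa = -30, hr = -80, efe = 0, fps = -80,
                wru = -30, wfe = -70),
    max_deg = c(sfe = 160, saa = 100, hr = 60, efe = 145, fps = 80,
                wru = 30, wfe = 70)
  )
}

#' Shrink one joint's interval about its midpoint
#'
#' Used to reduce the elbow range to a fraction of its span (default use:
#' 85%) so that target-generating postures avoid the fully-extended arm,
#' where the hand position becomes insensitive to elbow flexion.
#'
#' @param rom A [range_of_motion()].
#' @param joint Joint name.
#' @param scale Fraction of the span to keep, in (0, 1].
#' @return A [range_of_motion()] with the joint's interval shrunk.
#' @export
scale_rom_joint <- function(rom, joint = "efe", scale = 0.85) {
  stopifnot(joint %in% JOINT_NAMES, scale > 0, scale <= 1)
  mid <- (rom[joint, "min_deg"] + rom[joint, "max_deg"]) / 2
  half <- (rom[joint, "max_deg"] - rom[joint, "min_deg"]) / 2 * scale
  rom[joint, "min_deg"] <- mid - half
  rom[joint, "max_deg"] <- mid + half
  rom
}

#' Clamp distal predictions to the range of motion
#'
#' Emulates a physical prosthesis that cannot execute commands beyond its
#' joint limits: each distal angle is clamped to its ROM interval.
#' Idempotent; joints already in range are untouched.
#'
#' @param distal Named numeric vector of distal angles (degrees); any subset
#'   of joints named in `rom` is accepted.
#' @param rom A [range_of_motion()].
#' @return The clamped vector, same names and order.
#' @export
saturate <- function(distal, rom) {
  nm <- names(distal)
  if (is.null(nm)) stop("distal angles must be named")
  pmin(pmax(distal, rom[nm, "min_deg"]), rom[nm, "max_deg"])
}

#' ROM from an observed movement database
#'
#' Builds the range of motion used to generate targets for a user whose own
#' distal joints cannot be calibrated: the user's shoulder limits are kept,
#' while each distal joint's interval is taken as a quantile envelope
#' (default 5% to 95%) of the excursions observed in a movement database.
#'
#' @param trajectories List of trajectory data frames (see
#'   [generate_natural_movement()]).
#' @param shoulder_rom A [range_of_motion()] providing the `sfe`/`saa` rows.
#' @param probs Lower/upper quantile probabilities for the distal envelope.
#' @return A [range_of_motion()].
#' @export
rom_from_database <- function(trajectories, shoulder_rom,
                              probs = c(0.05, 0.95)) {
  stopifnot(length(trajectories) > 0)
  frames <- do.call(rbind, lapply(trajectories, function(tr) tr[JOINT_NAMES]))
  lo <- vapply(frames, stats::quantile, numeric(1), probs = probs[1])
  hi <- vapply(frames, stats::quantile, numeric(1), probs = probs[2])
  names(lo) <- names(hi) <- JOINT_NAMES
  lo[PROXIMAL_NAMES] <- shoulder_rom[PROXIMAL_NAMES, "min_deg"]
  hi[PROXIMAL_NAMES] <- shoulder_rom[PROXIMAL_NAMES, "max_deg"]
  range_of_motion(lo, hi)
}
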