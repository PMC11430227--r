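# 7-DoF kinematic arm chain: joint angles -> hand pose in the shoulder frame.

#' Canonical joint order of the 7-DoF arm model
#'
#' The seven anatomical angles, in the fixed order used everywhere in the
#' package: shoulder flexion/extension (`sfe`), shoulder adduction/abduction
#' (`saa`), humeral rotation (`hr`), elbow flexion/extension (`efe`), forearm
#' pronation/supination (`fps`), wrist radial/ulnar deviation (`wru`) and
#' wrist flexion/extension (`wfe`). All angles are in degrees.
#'
#' @format Character vector of length 7.
#' @export
JOINT_NAMES <- c("sfe", "saa", "hr", "efe", "fps", "wru", "wfe")

#' @rdname JOINT_NAMES
#' @format `PROXIMAL_NAMES` and `DISTAL_NAMES` partition `JOINT_NAMES` into
#'   the two user-controlled proximal joints and the five machine-controlled
#'   distal joints.
#' @export
PROXIMAL_NAMES <- c("sfe", "saa")

#' @rdname JOINT_NAMES
#' @format NULL
#' @export
DISTAL_NAMES <- c("hr", "efe", "fps", "wru", "wfe")

#' Construct a joint-angle vector
#'
#' @param sfe,saa,hr,efe,fps,wru,wfe Joint angles in degrees.
#' @return Named numeric vector of length 7 in canonical order.
#' @examples
#' joint_angles(efe = 90)
#' @export
joint_angles <- function(sfe = 0, saa = 0, hr = 0, efe = 0, fps = 0,
                         wru = 0, wfe = 0) {
  ang <- c(sfe = sfe, saa = saa, hr = hr, efe = efe, fps = fps,
           wru = wru, wfe = wfe)
  as_joint_angles(ang)
}

#' Validate and order a joint-angle vector
#'
#' @param x Numeric vector with names covering the seven canonical joints, or
#'   an unnamed numeric vector of length 7 taken to be in canonical order.
#' @return Named numeric vector of length 7 in canonical order.
#' @export
as_joint_angles <- function(x) {
  x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) != 7L) stop("joint angles must have length 7")
    names(x) <- JOINT_NAMES
  }
  if (!all(JOINT_NAMES %in% names(x)))
    stop("joint angles must be named with: ", paste(JOINT_NAMES, collapse = ", "))
  x <- x[JOINT_NAMES]
  if (!all(is.finite(x))) stop("joint angles must be finite")
  x
}

#' Arm geometry: segment lengths and the rotation chain
#'
#' Defines the 7-DoF anthropomorphic chain used by [forward_kinematics()].
#' The reference frame has its origin at the shoulder and is trunk-aligned:
#' +x rightward, +y upward, +z forward. In the reference posture (all angles
#' zero) the arm hangs along -y.
#'
#' The chain has three intersecting shoulder axes, one elbow axis, one
#' forearm axis and two intersecting wrist axes. Each joint rotates about a
#' fixed axis of its local frame; flexion-type joints (sfe, efe, wfe) rotate
#' about -x so that positive flexion moves the limb forward (+z), abduction
#' (saa) rotates about +z moving the arm laterally (+x, right arm), the two
#' long-axis rotations (hr, fps) are about the segment axis -y (stored as y),
#' and radial/ulnar deviation (wru) is about +z. Segment translations run
#' along the local -y axis, equivalent to a Denavit-Hartenberg chain with
#' +/-90 degree twists between successive axes.
#'
#' @param upper_arm,forearm,hand Segment lengths in metres; the hand length
#'   runs from the wrist to the middle-of-grasp point.
#' @return Object of class `arm_geometry`: list with the segment lengths and
#'   a `chain` data frame (one row per joint: rotation `axis`, `sign`, and
#'   the index of the translation applied after the joint, 0 for none).
#' @examples
#' geom <- arm_geometry()
#' forward_kinematics(geom, joint_angles())$position
#' @export
arm_geometry <- function(upper_arm = 0.30, forearm = 0.26, hand = 0.08) {
  if (any(c(upper_arm, forearm, hand) <= 0))
    stop("all segment lengths must be > 0")
  chain <- data.frame(
    joint = JOINT_NAMES,
    axis  = c("x", "z", "y", "x", "y", "z", "x"),
    sign  = c(-1,   1,   1,  -1,   1,   1,  -1),
    # segment translated along local -y after this joint (0 = none)
    translate_after = c(0L, 0L, 1L, 0L, 2L, 0L, 3L),
    stringsAsFactors = FALSE
  )
  structure(
    list(upper_arm = upper_arm, forearm = forearm, hand = hand,
         chain = chain),
    class = "arm_geometry"
  )
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("7-DoF arm geometry (shoulder frame: +x right, +y up, +z forward)\n")
  cat(sprintf("  upper arm %.3f m, forearm %.3f m, hand %.3f m\n",
              x$upper_arm, x$forearm, x$hand))
  invisible(x)
}

#' Read/write arm geometry as a YAML config block
#'
#' @param file Path to a YAML file with fields `upper_arm`, `forearm`,
#'   `hand` (metres).
#' @return `read_arm_geometry()` returns an `arm_geometry`;
#'   `write_arm_geometry()` returns `file` invisibly.
#' @export
read_arm_geometry <- function(file) {
  cfg <- yaml::read_yaml(file)
  arm_geometry(upper_arm = cfg$upper_arm, forearm = cfg$forearm,
               hand = cfg$hand)
}

#' @rdname read_arm_geometry
#' @param geometry An `arm_geometry` object.
#' @export
write_arm_geometry <- function(geometry, file) {
  yaml::write_yaml(list(upper_arm = geometry$upper_arm,
                        forearm = geometry$forearm,
                        hand = geometry$hand), file)
  invisible(file)
}

# Elementary rotation matrices, angle in degrees.
rot3 <- function(axis, deg) {
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3),
    stop("unknown axis"))
}

#' Forward kinematics of the 7-DoF arm
#'
#' Maps the seven anatomical joint angles to the hand pose: the
#' middle-of-grasp position (metres, shoulder frame), the unit grasp-axis
#' direction of the cylindrical grasp, and its frontal- and sagittal-plane
#' projection angles `alpha` and `beta` (degrees, zero for a vertically
#' hanging axis, signed in (-180, 180]).
#'
#' @param geometry An [arm_geometry()].
#' @param angles Joint angles (degrees), coerced with [as_joint_angles()].
#' @return Object of class `hand_pose`: list with `position` (3-vector),
#'   `axis` (unit 3-vector), `alpha`, `beta` (degrees).
#' @export
forward_kinematics <- function(geometry, angles) {
  angles <- as_joint_angles(angles)
  seg <- c(geometry$upper_arm, geometry$forearm, geometry$hand)
  chain <- geometry$chain
  R <- diag(3)
  p <- c(0, 0, 0)
  for (k in seq_len(7L)) {
    R <- R %*% rot3(chain$axis[k], chain$sign[k] * angles[[k]])
    ti <- chain$translate_after[k]
    if (ti > 0L) p <- p + R %*% c(0, -seg[ti], 0)
  }
  axis <- as.numeric(R %*% c(0, -1, 0))
  ab <- alpha_beta_from_axis(axis)
  structure(list(position = as.numeric(p), axis = axis,
                 alpha = ab[["alpha"]], beta = ab[["beta"]]),
            class = "hand_pose")
}

#' @export
print.hand_pose <- function(x, ...) {
  cat(sprintf("hand pose: position (%.3f, %.3f, %.3f) m, alpha %.1f deg, beta %.1f deg\n",
              x$position[1], x$position[2], x$position[3], x$alpha, x$beta))
  invisible(x)
}

#' Grasp-axis orientation angles
#'
#' `alpha_beta_from_axis()` projects a grasp-axis direction onto the frontal
#' (x-y) and sagittal (y-z) planes and returns the signed angles from the
#' vertically-hanging direction (0, -1, 0). `axis_from_alpha_beta()` inverts
#' the map (up to the inherent degeneracy at a horizontal axis, where the
#' two projection angles no longer identify a unique direction).
#'
#' @param axis Numeric 3-vector (need not be unit length).
#' @return `alpha_beta_from_axis()`: named vector `c(alpha =, beta =)` in
#'   degrees; `axis_from_alpha_beta()`: unit 3-vector.
#' @export
alpha_beta_from_axis <- function(axis) {
  c(alpha = atan2(axis[1], -axis[2]) * 180 / pi,
    beta  = atan2(axis[3], -axis[2]) * 180 / pi)
}

#' @rdname alpha_beta_from_axis
#' @param alpha,beta Projection angles in degrees.
#' @export
axis_from_alpha_beta <- function(alpha, beta) {
  a <- alpha * pi / 180
  b <- beta * pi / 180
  sgn <- if (cos(a) + cos(b) >= 0) 1 else -1
  v <- sgn * c(cos(b) * sin(a), -cos(a) * cos(b), cos(a) * sin(b))
  n <- sqrt(sum(v^2))
  if (n < 1e-8) {
    # horizontal axis: both projections are degenerate, split the difference
    v <- c(sin(a), 0, sin(b))
    n <- sqrt(sum(v^2))
  }
  v / n
}

#' Hand position with the distal joints frozen
#'
#' The locked-hand position: forward kinematics evaluated with the current
#' proximal angles but the distal joints held at their previous values, so
#' that only user-driven proximal motion can displace it. This is the
#' position whose displacement defines the locked-hand speed used by the
#' interpolation controller (it prevents a spurious feedback loop in which
#' controller-driven distal motion would feed back into its own rate).
#'
#' @param geometry An [arm_geometry()].
#' @param proximal_now Named numeric `c(sfe =, saa =)` in degrees.
#' @param distal_prev Named numeric for the five distal joints, degrees.
#' @return Numeric 3-vector, metres.
#' @export
locked_hand_position <- function(geometry, proximal_now, distal_prev) {
  forward_kinematics(geometry, c(proximal_now[PROXIMAL_NAMES],
                                 distal_prev[DISTAL_NAMES]))$position
}

#' Target implied by a hand pose
#'
#' The context of a hypothetical target placed in the hand: the target a
#' hand at this pose would be grasping, given as position plus the frontal
#' and sagittal grasp-axis angles.
#'
#' @param pose A `hand_pose` from [forward_kinematics()].
#' @return Object of class `target_spec`: list with `position` (3-vector,
#'   metres), `alpha`, `beta` (degrees).
#' @export
context_from_pose <- function(pose) {
  target_spec(pose$position, pose$alpha, pose$beta)
}

#' Construct a target specification
#'
#' @param position Numeric 3-vector, metres, shoulder frame.
#' @param alpha,beta Grasp-axis orientation angles, degrees.
#' @param id Optional target identifier.
#' @return Object of class `target_spec`.
#' @export
target_spec <- function(position, alpha, beta, id = NULL) {
  stopifnot(length(position) == 3L, is.finite(position),
            is.finite(alpha), is.finite(beta))
  structure(list(position = as.numeric(position),
                 alpha = as.numeric(alpha), beta = as.numeric(beta),
                 id = id),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("target: (%.3f, %.3f, %.3f) m, alpha %.1f deg, beta %.1f deg\n",
              x$position[1], x$position[2], x$position[3], x$alpha, x$beta))
  invisible(x)
}

#' Split a joint-angle vector into proximal and distal parts
#'
#' @param angles Named joint angles.
#' @return The proximal pair (`sfe`, `saa`) or the five distal angles.
#' @export
proximal_of <- function(angles) angles[PROXIMAL_NAMES]

#' @rdname proximal_of
#' @export
distal_of <- function(angles) angles[DISTAL_NAMES]
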