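# Online and offline trajectory metrics.

#' Success rate of a set of trials
#'
#' @param records List of `trial_record`s.
#' @return Percentage in \[0, 100\].
#' @export
success_rate <- function(records) {
  stopifnot(length(records) > 0)
  100 * mean(vapply(records, function(r) isTRUE(r$success), logical(1)))
}

#' Movement and validation times of a successful trial
#'
#' Movement time: from target appearance to the (simulated) button press.
#' Validation time: from the last entry into the validation zone to the
#' press.
#'
#' @param record A successful `trial_record`.
#' @return Seconds.
#' @export
movement_time <- function(record) {
  if (!isTRUE(record$success)) stop("movement time is defined for successful trials")
  record$movement_time
}

#' @rdname movement_time
#' @export
validation_time <- function(record) {
  if (!isTRUE(record$success)) stop("validation time is defined for successful trials")
  record$validation_time
}

#' Shoulder spread volume
#'
#' Volume of the covariance-aligned ellipsoid expected to encompass a given
#' fraction (default 97%) of the shoulder positions under a Gaussian model:
#' `(4/3) * pi * sqrt(det(Sigma)) * q^(3/2)` with `q` the corresponding
#' chi-squared(3 df) quantile. An index of compensatory trunk/shoulder
#' translation; reported in cubic decimetres.
#'
#' @param positions n x 3 matrix of shoulder positions, metres (n >= 4).
#' @param coverage Coverage fraction (default 0.97).
#' @return Volume in dm^3.
#' @export
shoulder_spread_volume <- function(positions, coverage = 0.97) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 4) stop("need at least 4 shoulder positions")
  if (!all(is.finite(positions))) stop("non-finite shoulder positions")
  sigma <- stats::cov(positions)
  d <- det(sigma)
  q <- stats::qchisq(coverage, df = 3)
  (4 / 3) * pi * sqrt(max(d, 0)) * q^(3 / 2) * 1000
}

#' Spectral arc length (smoothness of the hand speed profile)
#'
#' The negative arc length of the normalized magnitude spectrum of the hand
#' speed profile over the normalized frequency band \[0, cutoff\]:
#' frequencies are scaled by the cutoff and magnitudes by the
#' zero-frequency magnitude, and the arc length of the resulting curve is
#' negated. Ranges from -1 (perfectly smooth limit) to -Inf; more negative
#' means less smooth. Original parameterization: 20 Hz cutoff,
#' zero-padding factor 4 (the spectrum endpoint is interpolated onto the
#' exact cutoff).
#'
#' @param positions n x 3 matrix of hand positions, metres.
#' @param timestamps Length-n increasing vector, seconds, uniform rate.
#' @param cutoff Cutoff frequency, Hz.
#' @param pad_factor Zero-padding: FFT length is
#'   `2^(nextpow2(n) + pad_factor)`.
#' @return Dimensionless, <= -1.
#' @export
spectral_arc_length <- function(positions, timestamps, cutoff = 20,
                                pad_factor = 4) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 8) stop("need at least 8 samples")
  dt <- diff(timestamps)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (max(dt) / min(dt) > 1.1) stop("sampling must be (near) uniform")
  fs <- 1 / stats::median(dt)
  v <- sqrt(rowSums(diff(positions)^2)) / dt
  if (all(v == 0)) stop("speed profile is identically zero")
  nfft <- 2^(ceiling(log2(length(v))) + pad_factor)
  V <- Mod(stats::fft(c(v, rep(0, nfft - length(v)))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  sel <- which(f <= cutoff)
  Vn <- V[sel] / V[1]
  fn <- f[sel] / cutoff
  # interpolate the spectrum onto the exact cutoff frequency
  last <- sel[length(sel)]
  if (f[last] < cutoff && last < nfft) {
    w <- (cutoff - f[last]) / (f[last + 1] - f[last])
    Vn <- c(Vn, ((1 - w) * V[last] + w * V[last + 1]) / V[1])
    fn <- c(fn, 1)
  }
  -sum(sqrt(diff(fn)^2 + diff(Vn)^2))
}

#' Curvature of a hand trajectory
#'
#' Maximum distance of the hand from the straight line connecting the
#' initial and final hand positions.
#'
#' @param positions n x 3 matrix, metres; endpoints must be distinct.
#' @return Metres (>= 0).
#' @export
curvature_of_trajectory <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 points")
  a <- positions[1, ]
  u <- positions[n, ] - a
  L <- vnorm(u)
  if (L == 0) stop("endpoints must be distinct")
  u <- u / L
  rel <- sweep(positions, 2, a)
  proj <- rel %*% u
  perp <- rel - proj %*% t(u)
  max(sqrt(rowSums(perp^2)))
}

#' Distance index of a hand trajectory
#'
#' Total distance travelled by the hand divided by the straight-line
#' distance between the initial and final positions; 1 for a monotone
#' straight path, larger otherwise.
#'
#' @param positions n x 3 matrix, metres; endpoints must be distinct.
#' @return Dimensionless (>= 1 for equal endpoints-connecting paths).
#' @export
distance_index <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 points")
  straight <- vnorm(positions[n, ] - positions[1, ])
  if (straight == 0) stop("endpoints must be distinct")
  sum(sqrt(rowSums(diff(positions)^2))) / straight
}

#' Offline reconstruction error distances
#'
#' Frame-wise comparison of a reconstructed trajectory against the actual
#' one: the median (over frames) of the mean absolute joint-angle error,
#' separately for the two proximal and the five distal joints; the median
#' Euclidean distance between the reconstructed and actual hand positions;
#' and the median angle between the two hands' grasp axes (spin about the
#' axis being unconstrained).
#'
#' @param actual,reconstructed `arm_trajectory` data frames of equal
#'   length with aligned timestamps.
#' @param geometry An [arm_geometry()].
#' @return List: `mmae_proximal`, `mmae_distal` (degrees), `mhpd` (metres),
#'   `mhod` (degrees).
#' @export
offline_distances <- function(actual, reconstructed, geometry) {
  if (nrow(actual) != nrow(reconstructed))
    stop("trajectories must have equal length")
  n <- nrow(actual)
  da <- abs(as.matrix(actual[JOINT_NAMES]) -
            as.matrix(reconstructed[JOINT_NAMES]))
  mmae_prox <- stats::median(rowMeans(da[, PROXIMAL_NAMES, drop = FALSE]))
  mmae_dist <- stats::median(rowMeans(da[, DISTAL_NAMES, drop = FALSE]))
  pd <- numeric(n)
  od <- numeric(n)
  for (i in seq_len(n)) {
    pa <- forward_kinematics(geometry, stats::setNames(
      as.numeric(actual[i, JOINT_NAMES]), JOINT_NAMES))
    pr <- forward_kinematics(geometry, stats::setNames(
      as.numeric(reconstructed[i, JOINT_NAMES]), JOINT_NAMES))
    pd[i] <- vnorm(pa$position - pr$position)
    od[i] <- deg_angle_between(pa$axis, pr$axis)
  }
  list(mmae_proximal = mmae_prox, mmae_distal = mmae_dist,
       mhpd = stats::median(pd), mhod = stats::median(od))
}

#' Per-trial and per-phase metric report
#'
#' Computes the per-trial metrics (movement and validation times, spectral
#' arc length, curvature, distance index --- on successful trials only, as
#' in the study) and the phase summary (success rate and medians; the
#' shoulder spread volume when shoulder positions are supplied).
#'
#' @param records List of `trial_record`s.
#' @param geometry An [arm_geometry()] (reserved for derived quantities).
#' @param shoulder_positions Optional n x 3 matrix of shoulder positions
#'   for the spread volume.
#' @return Object of class `metrics_report`: list with `per_trial` (data
#'   frame) and `summary` (list).
#' @export
phase_metrics <- function(records, geometry = NULL,
                          shoulder_positions = NULL) {
  stopifnot(length(records) > 0)
  per <- data.frame(
    trial = seq_along(records),
    success = vapply(records, function(r) isTRUE(r$success), logical(1)),
    movement_time = NA_real_, validation_time = NA_real_,
    sal = NA_real_, curvature = NA_real_, distance_index = NA_real_)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (!isTRUE(r$success)) next
    per$movement_time[i] <- r$movement_time
    per$validation_time[i] <- r$validation_time
    p <- as.matrix(r$trajectory[c("x", "y", "z")])
    tt <- r$trajectory$t
    per$sal[i] <- tryCatch(spectral_arc_length(p, tt), error = function(e) NA_real_)
    per$curvature[i] <- tryCatch(curvature_of_trajectory(p), error = function(e) NA_real_)
    per$distance_index[i] <- tryCatch(distance_index(p), error = function(e) NA_real_)
  }
  med <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  summary <- list(
    n_trials = length(records),
    success_rate = success_rate(records),
    median_movement_time = med(per$movement_time),
    median_validation_time = med(per$validation_time),
    median_sal = med(per$sal),
    median_curvature = med(per$curvature),
    median_distance_index = med(per$distance_index),
    shoulder_spread_volume = if (is.null(shoulder_positions)) NA_real_
                             else shoulder_spread_volume(shoulder_positions))
  structure(list(per_trial = per, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("metrics over %d trials: SR %.1f%%, median MT %.2f s, median SAL %.2f\n",
              s$n_trials, s$success_rate, s$median_movement_time,
              s$median_sal))
  invisible(x)
}

#' Write a metrics report to JSON (summary) and CSV (per trial)
#'
#' @param report A `metrics_report`.
#' @param json_file,csv_file Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_metrics <- function(report, json_file = NULL, csv_file = NULL) {
  if (!is.null(json_file))
    jsonlite::write_json(report$summary, json_file, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(csv_file))
    utils::write.csv(report$per_trial, csv_file, row.names = FALSE)
  invisible(report)
}
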