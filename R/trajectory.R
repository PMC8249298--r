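#' Head trajectory container
#'
#' @param times frame times (s).
#' @param positions n x 3 head positions (um).
#' @param head_angle optional head-orientation angle series (rad,
#'   unwrapped; the angle of the head long axis projected on the lab
#'   xy-plane).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(times, positions, head_angle = NULL) {
  positions <- as.matrix(positions)
  stopifnot(length(times) == nrow(positions))
  structure(list(times = times, positions = positions,
                 head_angle = head_angle),
            class = "trajectory")
}

#' Head-orientation angle from head-axis vectors
#'
#' atan2 of the lab xy-projection of the head long axis, unwrapped.
#'
#' @param head_axis n x 3 matrix of unit vectors.
#' @return unwrapped angle series (rad).
#' @export
head_orientation_angle <- function(head_axis) {
  unwrap_angle(atan2(head_axis[, 2], head_axis[, 1]))
}

#' Averaged swimming path
#'
#' Removes the beat-frequency head wiggling with a centered moving average
#' whose window is one beat period; the trimmed endpoints are dropped.
#'
#' @param traj [trajectory]
#' @param T_beat beat period (s), resolved by at least 8 samples.
#' @return [trajectory] of the averaged path (head_angle, if present, is
#'   smoothed the same way).
#' @export
averaged_path <- function(traj, T_beat) {
  dt <- stats::median(diff(traj$times))
  w <- round(T_beat / dt)
  if (w < 8) stop("beat period must be resolved by >= 8 samples")
  if (length(traj$times) < 2 * w) stop("track shorter than 2 beat periods")
  sm <- apply(traj$positions, 2, running_mean, k = w)
  keep <- !is.na(sm[, 1])
  ang <- NULL
  if (!is.null(traj$head_angle)) {
    ang <- running_mean(traj$head_angle, w)[keep]
  }
  trajectory(traj$times[keep], sm[keep, , drop = FALSE], ang)
}

#' Speed along the averaged path
#'
#' Total arclength of the averaged path divided by its elapsed time.
#'
#' @param path [trajectory] (averaged).
#' @return speed (um/s).
#' @export
path_speed <- function(path) {
  if (nrow(path$positions) < 2) stop("path needs at least 2 points")
  len <- sum(sqrt(rowSums(diff(path$positions)^2)))
  len / diff(range(path$times))
}

#' Circle radius, yaw rate and path class of an averaged path
#'
#' The circle radius comes from a Taubin fit to the xy-projection of the
#' averaged path. The yaw rotation velocity Omega_yaw is the slope of a
#' linear fit to the unwrapped head-orientation angle versus time (the
#' slow trend under the beat-frequency oscillation). The path is
#' "circular" when the total yaw turn exceeds pi/4 and the circle-fit
#' residual is below 5% of the radius, else "curvilinear".
#'
#' @param path [trajectory] (averaged), with `head_angle` present or
#'   supplied separately.
#' @param head_angle optional angle series overriding `path$head_angle`.
#' @return list with `r` (um; NA for straight paths), `Omega_yaw` (rad/s),
#'   `class`, `fit_residual`.
#' @export
fit_circle_and_yaw <- function(path, head_angle = NULL) {
  ang <- if (!is.null(head_angle)) head_angle else path$head_angle
  if (is.null(ang)) stop("head-orientation angle series required")
  tt <- path$times[seq_along(ang)]
  Omega_yaw <- unname(stats::coef(stats::lm(ang ~ tt))[2])
  xy <- path$positions[, 1:2, drop = FALSE]
  fit <- taubin_circle_fit(xy)
  if (fit$collinear || !is.finite(fit$radius)) {
    return(list(r = NA_real_, Omega_yaw = Omega_yaw, class = "curvilinear",
                fit_residual = NA_real_))
  }
  resid <- sqrt(mean((sqrt(colSums((t(xy) - fit$center)^2)) - fit$radius)^2))
  duration <- diff(range(path$times))
  cls <- if (abs(Omega_yaw) * duration > pi / 4 &&
             resid < 0.05 * fit$radius) "circular" else "curvilinear"
  list(r = fit$radius, Omega_yaw = Omega_yaw, class = cls,
       fit_residual = resid)
}

#' Out-of-plane excursion and beat frequency from head wiggling
#'
#' Delta z is the maximal deviation of the z-coordinate from its running
#' mean (window = one beat period). The beat frequency is the dominant
#' spectral peak of the detrended head-orientation angle (head wiggling is
#' a proxy for the flagellar beat), refined by parabolic interpolation of
#' the periodogram.
#'
#' @param traj [trajectory] (raw, un-averaged).
#' @param head_angle head-orientation angle series (rad).
#' @param T_window running-mean window for the z baseline (s); defaults to
#'   the beat period found spectrally.
#' @return list with `delta_z` (um), `beat_frequency` (Hz).
#' @export
wiggling_metrics <- function(traj, head_angle, T_window = NULL) {
  dt <- stats::median(diff(traj$times))
  n <- length(head_angle)
  tt <- traj$times[seq_len(n)]
  detr <- unname(stats::residuals(stats::lm(head_angle ~ tt)))
  spec <- Mod(stats::fft(detr))[seq_len(floor(n / 2))]
  spec[1] <- 0
  pk <- which.max(spec)
  if (spec[pk] <= 0) stop("flat spectrum: beat frequency undetermined")
  # parabolic refinement around the peak bin
  delta <- 0
  if (pk > 1 && pk < length(spec)) {
    y1 <- spec[pk - 1]; y2 <- spec[pk]; y3 <- spec[pk + 1]
    den <- y1 - 2 * y2 + y3
    if (den != 0) delta <- 0.5 * (y1 - y3) / den
  }
  beat_frequency <- (pk - 1 + delta) / (n * dt)
  if (is.null(T_window)) T_window <- 1 / beat_frequency
  w <- max(3, round(T_window / dt))
  zbase <- running_mean(traj$positions[, 3], w)
  dz <- abs(traj$positions[, 3] - zbase)
  list(delta_z = max(dz, na.rm = TRUE), beat_frequency = beat_frequency)
}
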