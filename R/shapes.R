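#' Flagellar centerline for a single video frame
#'
#' A `flagellar_shape` is an ordered 3D polyline sampled at (close to)
#' uniform spacing along the flagellum, with arclength coordinate `s`
#' starting at 0 at the head-proximal end. All coordinates are micrometers.
#'
#' @param points numeric matrix, n x 3, ordered head-proximal to distal (um).
#' @param ds target uniform spacing in um; the polyline is resampled with a
#'   cubic spline so that consecutive points are exactly `ds` apart.
#' @param resample if `FALSE`, `points` are taken as-is and `s` is the
#'   cumulative chord length (used by generators whose points already lie at
#'   uniform arclength on the true curve).
#' @return object of class `flagellar_shape`: list with `points` (n x 3),
#'   `s` (arclength per point), `ds`.
#' @export
flagellar_shape <- function(points, ds = 0.5, resample = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  if (nrow(points) < 10) stop("a flagellar shape needs at least 10 points")
  if (any(!is.finite(points))) stop("points contain non-finite values")
  if (resample) {
    points <- resample_polyline(points, ds)
    s <- (seq_len(nrow(points)) - 1) * ds
  } else {
    seg <- sqrt(rowSums(diff(points)^2))
    s <- c(0, cumsum(seg))
    ds <- stats::median(seg)
  }
  structure(list(points = points, s = s, ds = ds), class = "flagellar_shape")
}

#' @export
print.flagellar_shape <- function(x, ...) {
  cat(sprintf("<flagellar_shape> %d points, length %.2f um, ds = %.3g um\n",
              nrow(x$points), max(x$s), x$ds))
  invisible(x)
}

arc_length <- function(shape) max(shape$s)

#' Resample a 3D polyline to exactly uniform spacing
#'
#' Fits a natural cubic spline through the points (parameterized by
#' cumulative chord length), samples it finely, and then marches along the
#' fine polyline placing output points at exact chord distance `ds` from the
#' previous one. Consecutive output points are `ds` apart to within
#' round-off.
#'
#' @param points n x 3 matrix (um).
#' @param ds spacing (um).
#' @return m x 3 matrix of resampled points.
#' @export
resample_polyline <- function(points, ds = 0.5) {
  points <- as.matrix(points)
  n <- nrow(points)
  u <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  if (any(diff(u) == 0)) {
    keep <- c(TRUE, diff(u) > 0)
    points <- points[keep, , drop = FALSE]
    u <- u[keep]
    n <- nrow(points)
  }
  fx <- stats::splinefun(u, points[, 1], method = "natural")
  fy <- stats::splinefun(u, points[, 2], method = "natural")
  fz <- stats::splinefun(u, points[, 3], method = "natural")
  uf <- seq(0, u[n], length.out = max(20L * n, 2000L))
  fine <- cbind(fx(uf), fy(uf), fz(uf))
  out <- list(fine[1, ])
  cur <- fine[1, ]
  j <- 1L
  nf <- nrow(fine)
  repeat {
    # advance j until fine[j+1] is at least ds from cur
    while (j < nf && vnorm(fine[j + 1L, ] - cur) < ds) j <- j + 1L
    if (j >= nf) break
    # solve |a + t d - cur| = ds on segment [fine[j], fine[j+1]]
    a <- fine[j, ]
    d <- fine[j + 1L, ] - a
    w <- a - cur
    A <- sum(d * d)
    B <- 2 * sum(w * d)
    C <- sum(w * w) - ds^2
    disc <- B^2 - 4 * A * C
    if (disc < 0) break
    t1 <- (-B + sqrt(disc)) / (2 * A)
    t1 <- min(max(t1, 0), 1)
    cur <- a + t1 * d
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

#' Parameters of a synthetic flagellar beat
#'
#' Collects the wave parameters of the synthetic traveling-wave beats. The
#' curvature wave is kappa(s, t) = K0 + K1 sin(2 pi s / lambda_w - 2 pi t / T).
#'
#' @param L flagellum length (um).
#' @param ds arclength sampling (um).
#' @param K0 mean (static) curvature (1/um).
#' @param K1 curvature wave amplitude (1/um).
#' @param lambda_w wavelength of the traveling curvature wave (um).
#' @param T_beat beat period (s).
#' @param tau0 torsion amplitude (1/um); meaning depends on `torsion_mode`.
#' @param torsion_mode one of `"none"`, `"constant"`,
#'   `"pulse_at_low_curvature"`.
#' @param frame_rate sampling rate (frames/s).
#' @param duration recording duration (s).
#' @param noise_sd isotropic tracking-noise s.d. per coordinate (um).
#' @param rng_seed integer seed for the noise generator.
#' @return object of class `beat_params`.
#' @export
beat_params <- function(L = 45, ds = 0.5, K0 = 0, K1 = 0.08, lambda_w = 45,
                        T_beat = 1 / 30, tau0 = 0, torsion_mode = "none",
                        frame_rate = 1000, duration = 0.2, noise_sd = 0,
                        rng_seed = 1L) {
  torsion_mode <- match.arg(torsion_mode,
                            c("none", "constant", "pulse_at_low_curvature"))
  stopifnot(L > 0, ds > 0, T_beat > 0, frame_rate > 0, duration > 0,
            noise_sd >= 0, lambda_w > 0)
  n_points <- floor(L / ds) + 1L
  if (n_points < 10) stop("L/ds must give at least 10 points")
  if (frame_rate * T_beat < 8) {
    stop("frame_rate * T_beat must be >= 8 so the beat is resolved")
  }
  structure(list(L = L, ds = ds, n_points = n_points, K0 = K0, K1 = K1,
                 lambda_w = lambda_w, T_beat = T_beat, tau0 = tau0,
                 torsion_mode = torsion_mode, frame_rate = frame_rate,
                 duration = duration, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "beat_params")
}

#' Time series of flagellar shapes with head pose
#'
#' @param frames list of [flagellar_shape] objects, one per video frame.
#' @param times numeric vector of frame times (s), strictly increasing and
#'   uniformly spaced.
#' @param head_center n_frames x 3 matrix of head-center positions (um).
#' @param head_axis n_frames x 3 matrix of unit head long-axis vectors.
#' @param truth optional list of ground-truth functions (generators attach
#'   `kappa(s, t)` and `tau(s, t)` here).
#' @return object of class `beat_recording`.
#' @export
beat_recording <- function(frames, times, head_center, head_axis,
                           truth = NULL) {
  stopifnot(is.list(frames), length(frames) == length(times))
  head_center <- as.matrix(head_center)
  head_axis <- as.matrix(head_axis)
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * stats::median(dt)) {
      stop("times must be uniformly spaced")
    }
  }
  nrm <- sqrt(rowSums(head_axis^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("head_axis rows must be unit vectors")
  structure(list(frames = frames, times = times, head_center = head_center,
                 head_axis = head_axis, truth = truth),
            class = "beat_recording")
}

#' @export
print.beat_recording <- function(x, ...) {
  cat(sprintf(
    "<beat_recording> %d frames, %.3f s, %d points/frame, L = %.1f um\n",
    length(x$frames), diff(range(x$times)),
    nrow(x$frames[[1]]$points), arc_length(x$frames[[1]])))
  invisible(x)
}

n_frames <- function(rec) length(rec$frames)

frame_dt <- function(rec) {
  if (length(rec$times) < 2) stop("recording has fewer than 2 frames")
  stats::median(diff(rec$times))
}
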