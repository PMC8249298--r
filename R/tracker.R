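#' Cone-search tracker configuration
#'
#' @param cone_length cone height (um).
#' @param half_angle cone half-opening angle (degrees).
#' @param yaw_range,pitch_range scan ranges around the previous direction
#'   (degrees).
#' @param angular_step scan grid step (degrees, <= 10).
#' @param termination_fraction stop when the winning cone integral falls
#'   below this fraction of the running median of previous integrals.
#' @param max_length maximum tracked length (um).
#' @param ds spacing of the returned resampled centerline (um).
#' @return object of class `tracker_config`.
#' @export
tracker_config <- function(cone_length = 3, half_angle = 20,
                           yaw_range = 45, pitch_range = 30,
                           angular_step = 5, termination_fraction = 0.2,
                           max_length = 60, ds = 0.5) {
  stopifnot(half_angle > 0, half_angle < yaw_range, angular_step <= 10,
            cone_length > 0, termination_fraction > 0,
            termination_fraction < 1)
  structure(list(cone_length = cone_length, half_angle = half_angle,
                 yaw_range = yaw_range, pitch_range = pitch_range,
                 angular_step = angular_step,
                 termination_fraction = termination_fraction,
                 max_length = max_length, ds = ds),
            class = "tracker_config")
}

# voxel-center coordinates (um) inside a cube of half-size r around p
local_voxels <- function(vol, p, r) {
  lo <- vol$origin
  dims <- dim(vol$data)
  i1 <- pmax(floor((p - r - lo) / vol$voxel) + 1, 1)
  i2 <- pmin(ceiling((p + r - lo) / vol$voxel) + 1, dims)
  if (any(i1 > i2)) return(NULL)
  ix <- i1[1]:i2[1]; iy <- i1[2]:i2[2]; iz <- i1[3]:i2[3]
  g <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
  pos <- sweep((g - 1) * vol$voxel, 2, lo, `+`)
  val <- as.numeric(vol$data[cbind(g[, 1], g[, 2], g[, 3])])
  list(pos = pos, val = val)
}

# direction unit vectors for a (yaw, pitch) grid around axis d
scan_directions <- function(d, yaw_range, pitch_range, step) {
  B <- perp_basis(d)
  yaws <- seq(-yaw_range, yaw_range, by = step) * pi / 180
  pitches <- seq(-pitch_range, pitch_range, by = step) * pi / 180
  g <- expand.grid(yaw = yaws, pitch = pitches)
  dirs <- t(vapply(seq_len(nrow(g)), function(i) {
    R1 <- rotation_exp(B[, 2] * g$pitch[i])
    R2 <- rotation_exp(B[, 1] * g$yaw[i])
    as.numeric(R2 %*% R1 %*% d)
  }, numeric(3)))
  dirs
}

# integral and centroid of intensity within a cone (apex, axis, cfg);
# vectorized over candidate axes (matrix dirs, rows unit vectors)
cone_scores <- function(lv, apex, dirs, cone_length, cos_half) {
  rel <- sweep(lv$pos, 2, apex)
  d2 <- rowSums(rel^2)
  proj <- rel %*% t(dirs) # n_vox x n_dirs
  inside0 <- d2 <= cone_length^2 & d2 > 0
  scores <- numeric(nrow(dirs))
  for (j in seq_len(nrow(dirs))) {
    inside <- inside0 & proj[, j] > 0 & proj[, j]^2 >= cos_half^2 * d2
    scores[j] <- sum(lv$val[inside])
  }
  scores
}

cone_centroid <- function(lv, apex, dir, cone_length, cos_half) {
  rel <- sweep(lv$pos, 2, apex)
  d2 <- rowSums(rel^2)
  proj <- as.numeric(rel %*% dir)
  inside <- d2 <= cone_length^2 & d2 > 0 & proj > 0 &
    proj^2 >= cos_half^2 * d2
  wsum <- sum(lv$val[inside])
  if (wsum <= 0) return(NULL)
  colSums(lv$pos[inside, , drop = FALSE] * lv$val[inside]) / wsum
}

#' Detect a tracking seed in an intensity volume
#'
#' The seed point is the global intensity maximum (ties resolved
#' first-in-scan-order with a warning). The initial direction is found by
#' an exhaustive cone scan over a full sphere of directions.
#'
#' @param vol `intensity_volume`
#' @param cfg [tracker_config]
#' @return list with `seed_point` (um), `seed_direction` (unit vector).
#' @export
detect_seed <- function(vol, cfg = tracker_config()) {
  if (all(vol$data <= 0)) stop("empty volume: no seed")
  mx <- max(vol$data)
  hits <- which(vol$data == mx)
  if (length(hits) > 1) {
    warning(sprintf("%d tied intensity maxima; using the first in scan order",
                    length(hits)))
  }
  idx <- arrayInd(hits[1], dim(vol$data))
  seed <- vol$origin + (as.numeric(idx) - 1) * vol$voxel
  lv <- local_voxels(vol, seed, cfg$cone_length)
  # full-sphere grid via z-axis yaw/pitch scans of the 6 axis directions
  base <- rbind(diag(3), -diag(3))
  dirs <- do.call(rbind, lapply(seq_len(6), function(k) {
    scan_directions(base[k, ], 40, 40, cfg$angular_step * 2)
  }))
  cos_half <- cos(cfg$half_angle * pi / 180)
  sc <- cone_scores(lv, seed, dirs, cfg$cone_length, cos_half)
  list(seed_point = seed, seed_direction = dirs[which.max(sc), ])
}

#' Track a filament centerline through an intensity volume
#'
#' Iterative cone search: from the current control point, a cone of length
#' `cone_length` and half-angle `half_angle` is rotated over a (yaw,
#' pitch) grid around the previous direction; the orientation maximizing
#' the intensity integral inside the cone wins, and the intensity-weighted
#' centroid of the winning cone becomes the next control point. Tracking
#' stops when the winning integral drops below
#' `termination_fraction` times the running median of previous integrals,
#' when the cone leaves the volume, or at `max_length`.
#'
#' @param vol `intensity_volume`
#' @param seed_point start point (um), inside the volume.
#' @param seed_direction initial unit direction.
#' @param cfg [tracker_config]
#' @return [flagellar_shape] resampled at `cfg$ds`.
#' @export
track_filament <- function(vol, seed_point, seed_direction,
                           cfg = tracker_config()) {
  dims <- dim(vol$data)
  hi <- vol$origin + (dims - 1) * vol$voxel
  if (any(seed_point < vol$origin) || any(seed_point > hi)) {
    stop("seed point outside volume")
  }
  cos_half <- cos(cfg$half_angle * pi / 180)
  pts <- list(seed_point)
  dir <- unitize(seed_direction)
  integrals <- numeric(0)
  total_len <- 0
  repeat {
    apex <- pts[[length(pts)]]
    lv <- local_voxels(vol, apex, cfg$cone_length)
    if (is.null(lv)) break
    dirs <- scan_directions(dir, cfg$yaw_range, cfg$pitch_range,
                            cfg$angular_step)
    sc <- cone_scores(lv, apex, dirs, cfg$cone_length, cos_half)
    best <- which.max(sc)
    if (length(integrals) == 0 && sc[best] <= 0) {
      stop("empty track: seed below threshold")
    }
    if (length(integrals) >= 3 &&
        sc[best] < cfg$termination_fraction * stats::median(integrals)) {
      break
    }
    ctr <- cone_centroid(lv, apex, dirs[best, ], cfg$cone_length, cos_half)
    if (is.null(ctr)) break
    step <- vnorm(ctr - apex)
    if (step < 0.25 * vol$voxel) break
    total_len <- total_len + step
    dir <- unitize(ctr - apex)
    pts[[length(pts) + 1L]] <- ctr
    integrals <- c(integrals, sc[best])
    if (total_len >= cfg$max_length) break
  }
  if (length(pts) < 4) stop("empty track: tracking terminated immediately")
  ctrl <- do.call(rbind, pts)
  fine <- resample_polyline(ctrl, cfg$ds)
  if (nrow(fine) < 10) stop("tracked filament too short")
  flagellar_shape(fine, ds = cfg$ds, resample = FALSE)
}
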