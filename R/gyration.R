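#' Gyration tensor and principal-axis frame of a flagellar shape
#'
#' The gyration tensor G = (1/N) sum_i (p_i - pbar)(p_i - pbar)' of the
#' uniformly sampled centerline points quantifies the second moments of the
#' shape. Its eigenvectors e1 >= e2 >= e3 (by eigenvalue) define a co-moving
#' frame: e1 is the elongation axis, (e1, e2) span the instantaneous beat
#' plane, and e3 is the beat-plane normal. The square roots r_i =
#' sqrt(lambda_i) are axis lengths; the non-planarity ratio is
#' Gamma = r3 / r2.
#'
#' Eigenvector sign convention for a single shape: e1 has positive dot
#' product with the proximal-to-distal chord, e2 with the mean lateral
#' offset of the shape from that chord, and e3 = e1 x e2 (right-handed).
#' For frame-to-frame continuity across a recording use
#' [gyration_frames()].
#'
#' @param shape [flagellar_shape] or an n x 3 matrix of points.
#' @return object of class `gyration_frame`: list with `e1`, `e2`, `e3`,
#'   `lambda` (length 3, non-increasing), `r` (sqrt of lambda), `Gamma`
#'   (NA with a warning for a straight line, where lambda2 = 0), `G`.
#' @export
gyration_tensor <- function(shape) {
  p <- if (inherits(shape, "flagellar_shape")) shape$points else as.matrix(shape)
  if (nrow(p) < 2) stop("gyration tensor needs at least 2 points")
  pc <- sweep(p, 2, colMeans(p))
  G <- crossprod(pc) / nrow(pc)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  V <- eg$vectors
  chord <- p[nrow(p), ] - p[1, ]
  if (sum(V[, 1] * chord) < 0) V[, 1] <- -V[, 1]
  # lateral reference: offset of the shape midpoint perpendicular to e1
  mid <- pc[round(nrow(pc) / 2), ]
  lat <- mid - sum(mid * V[, 1]) * V[, 1]
  if (sum(V[, 2] * lat) < 0) V[, 2] <- -V[, 2]
  V[, 3] <- cross3(V[, 1], V[, 2])
  r <- sqrt(lam)
  Gamma <- if (lam[2] <= .Machine$double.eps * lam[1]) {
    warning("lambda2 = 0 (straight shape): non-planarity undefined")
    NA_real_
  } else r[3] / r[2]
  structure(list(e1 = V[, 1], e2 = V[, 2], e3 = V[, 3], lambda = lam,
                 r = r, Gamma = Gamma, G = G),
            class = "gyration_frame")
}

#' Non-planarity ratio of a gyration frame
#'
#' Gamma = r3 / r2 in [0, 1]; 0 for planar shapes, 1 for shapes whose
#' out-of-plane extent equals the beat amplitude.
#'
#' @param frame [gyration_tensor()] result.
#' @return numeric scalar (NA for straight shapes).
#' @export
nonplanarity <- function(frame) frame$Gamma

#' Co-moving gyration frames for every frame of a recording
#'
#' Computes [gyration_tensor()] per frame and enforces temporal continuity:
#' each eigenvector is flipped to have positive dot product with its
#' predecessor, and when lambda2 and lambda3 are nearly degenerate the
#' previous frame's (e2, e3) orientation is carried over. e3 is always
#' recomputed as e1 x e2, keeping the frame right-handed.
#'
#' @param rec [beat_recording]
#' @param degeneracy_tol relative |lambda2 - lambda3| below which (e2, e3)
#'   are treated as degenerate.
#' @return list of `gyration_frame` objects, one per frame.
#' @export
gyration_frames <- function(rec, degeneracy_tol = 1e-6) {
  out <- vector("list", n_frames(rec))
  prev <- NULL
  for (i in seq_len(n_frames(rec))) {
    f <- gyration_tensor(rec$frames[[i]])
    if (!is.null(prev)) {
      if (sum(f$e1 * prev$e1) < 0) f$e1 <- -f$e1
      degen <- (f$lambda[2] - f$lambda[3]) < degeneracy_tol * f$lambda[2]
      if (degen) {
        # carry previous orientation, re-orthogonalized against new e1
        e2 <- prev$e2 - sum(prev$e2 * f$e1) * f$e1
        f$e2 <- unitize(e2)
      } else if (sum(f$e2 * prev$e2) < 0) {
        f$e2 <- -f$e2
      }
      f$e3 <- cross3(f$e1, f$e2)
    }
    out[[i]] <- f
    prev <- f
  }
  out
}

#' Project a recording into its co-moving beat plane
#'
#' Per frame, centerline points relative to the head center are projected
#' onto the (e1, e2) plane of the gyration frame, then rotated in-plane so
#' the projected head long axis lies along the positive horizontal axis.
#' This removes translation, rolling, and yawing: a periodic beat becomes a
#' periodic sequence of 2D shapes.
#'
#' @param rec [beat_recording] with head pose.
#' @param frames optional precomputed [gyration_frames()].
#' @return list with `shapes` (list of n x 2 matrices, um) and `times`.
#' @export
comoving_projection <- function(rec, frames = gyration_frames(rec)) {
  shapes <- vector("list", n_frames(rec))
  for (i in seq_len(n_frames(rec))) {
    f <- frames[[i]]
    p <- sweep(rec$frames[[i]]$points, 2, rec$head_center[i, ])
    xy <- cbind(p %*% f$e1, p %*% f$e2)
    h <- c(sum(rec$head_axis[i, ] * f$e1), sum(rec$head_axis[i, ] * f$e2))
    if (vnorm(h) < 1e-3) {
      stop("head axis nearly orthogonal to the beat plane: degenerate alignment")
    }
    h <- h / vnorm(h)
    R <- matrix(c(h[1], -h[2], h[2], h[1]), 2, 2) # rotates h onto +x
    shapes[[i]] <- xy %*% R
  }
  list(shapes = shapes, times = rec$times)
}

#' Mean flagellar curvature from the time-averaged projected shape
#'
#' Averages the co-moving projected shapes point-wise over one beat period
#' and fits a circle (Taubin) to the averaged shape. The inverse radius is
#' the mean flagellar curvature, reported in 1/mm as printed in
#' experimental work.
#'
#' @param proj result of [comoving_projection()].
#' @param T_beat beat period (s); frames within the first full period are
#'   averaged.
#' @param straight_tol if the fitted radius exceeds `straight_tol` times
#'   the shape length the shape is treated as straight and 0 is returned
#'   with attribute `straight = TRUE`.
#' @return curvature in 1/mm.
#' @export
mean_projected_curvature <- function(proj, T_beat, straight_tol = 100) {
  dt <- stats::median(diff(proj$times))
  n_per <- floor(T_beat / dt)
  if (n_per < 2 || n_per > length(proj$shapes)) {
    stop("projection must cover at least one full beat period")
  }
  avg <- Reduce(`+`, proj$shapes[seq_len(n_per)]) / n_per
  fit <- taubin_circle_fit(avg)
  len <- sum(sqrt(rowSums(diff(avg)^2)))
  if (!is.finite(fit$radius) || fit$radius > straight_tol * len) {
    return(structure(0, straight = TRUE))
  }
  1000 / fit$radius
}

#' Rolling versus wobbling analysis of the beat-plane normal
#'
#' The roll angle is accumulated from the signed rotation of e3 about e1
#' between consecutive frames (projections of e3 onto the plane normal to
#' e1; right-hand rule about e1, so a positive rate is a beat plane turning
#' clockwise when viewed from the head toward the distal tip). The cell is
#' classified as "rolling" when the roll rate keeps one sign for more than
#' `rolling_frac` of the samples, else "wobbling".
#'
#' @param rec [beat_recording]
#' @param frames optional precomputed [gyration_frames()].
#' @param rolling_frac same-sign fraction defining rolling.
#' @return list with `times`, `roll_angle` (rad, unwrapped), `roll_rate`
#'   (rad/s, centered differences), `mean_rate`, `classification`.
#' @export
rolling_analysis <- function(rec, frames = gyration_frames(rec),
                             rolling_frac = 0.9) {
  nf <- length(frames)
  if (nf < 2) stop("rolling analysis needs at least 2 frames")
  dt <- frame_dt(rec)
  ang <- numeric(nf)
  for (i in 2:nf) {
    e1 <- frames[[i - 1]]$e1
    if (abs(sum(frames[[i - 1]]$e3 * e1)) > 0.99) {
      stop("e1 and e3 nearly parallel: degenerate frame")
    }
    a <- frames[[i - 1]]$e3 - sum(frames[[i - 1]]$e3 * e1) * e1
    b <- frames[[i]]$e3 - sum(frames[[i]]$e3 * e1) * e1
    ang[i] <- ang[i - 1] + signed_angle(unitize(a), unitize(b), e1)
  }
  rate <- rep(NA_real_, nf)
  rate[2:(nf - 1)] <- (ang[3:nf] - ang[1:(nf - 2)]) / (2 * dt)
  rr <- rate[!is.na(rate)]
  frac_pos <- mean(rr > 0)
  frac_neg <- mean(rr < 0)
  classification <- if (max(frac_pos, frac_neg) > rolling_frac &&
                        abs(ang[nf]) > 1e-8) "rolling" else "wobbling"
  list(times = rec$times, roll_angle = ang, roll_rate = rate,
       mean_rate = mean(rr), classification = classification)
}
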