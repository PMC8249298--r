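#' Taubin algebraic circle fit
#'
#' Chernov's Newton form of Taubin's fit: minimizes the gradient-weighted
#' algebraic distance, which is nearly unbiased for partial arcs and noisy
#' data. Exact for points lying on a circle; returns an infinite radius
#' (flag `collinear`) for collinear input.
#'
#' @param points_2d n x 2 matrix, n >= 3.
#' @return list with `center` (length 2), `radius`, `collinear`.
#' @export
taubin_circle_fit <- function(points_2d) {
  xy <- as.matrix(points_2d)
  if (nrow(xy) < 3) stop("circle fit needs at least 3 points")
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  X <- xy[, 1] - cx; Y <- xy[, 2] - cy
  Z <- X^2 + Y^2
  Mxx <- mean(X^2); Myy <- mean(Y^2); Mxy <- mean(X * Y)
  Mxz <- mean(X * Z); Myz <- mean(Y * Z); Mzz <- mean(Z^2)
  Mz <- Mxx + Myy
  Cov_xy <- Mxx * Myy - Mxy^2
  Var_z <- Mzz - Mz^2
  A3 <- 4 * Mz
  A2 <- -3 * Mz^2 - Mzz
  A1 <- Var_z * Mz + 4 * Cov_xy * Mz - Mxz^2 - Myz^2
  A0 <- Mxz^2 * Myy + Myz^2 * Mxx - Var_z * Cov_xy - 2 * Mxz * Myz * Mxy
  A22 <- 2 * A2; A33 <- 3 * A3
  xn <- 0; yn <- 1e+20
  for (iter in 1:99) {
    yo <- yn
    yn <- A0 + xn * (A1 + xn * (A2 + xn * A3))
    if (abs(yn) > abs(yo)) { xn <- 0; break }
    Dy <- A1 + xn * (A22 + xn * A33)
    xo <- xn
    xn <- xo - yn / Dy
    if (!is.finite(xn)) { xn <- 0; break }
    if (xn != 0 && abs((xn - xo) / xn) < 1e-12) break
  }
  DET <- xn^2 - xn * Mz + Cov_xy
  if (!is.finite(DET) || abs(DET) < 1e-14 * max(Mz^2, 1e-300)) {
    return(list(center = c(NA_real_, NA_real_), radius = Inf,
                collinear = TRUE))
  }
  Xc <- (Mxz * (Myy - xn) - Myz * Mxy) / DET / 2
  Yc <- (Myz * (Mxx - xn) - Mxz * Mxy) / DET / 2
  list(center = c(Xc + cx, Yc + cy), radius = sqrt(Xc^2 + Yc^2 + Mz),
       collinear = FALSE)
}

#' Least-squares tangent and osculating plane of a point window
#'
#' The tangent is the principal direction of the windowed points; the plane
#' normal (the binormal direction) is the direction perpendicular to the
#' tangent that minimizes the squared out-of-plane residuals. Degenerate
#' (collinear) windows get `degenerate = TRUE` and an arbitrary normal.
#'
#' @param window_points m x 3 matrix, m >= 5.
#' @return list with `tangent`, `plane_normal` (unit 3-vectors),
#'   `degenerate`.
#' @export
fit_osculating_plane <- function(window_points) {
  Q <- as.matrix(window_points)
  if (nrow(Q) < 5) stop("window must contain at least 5 points")
  Qc <- sweep(Q, 2, colMeans(Q))
  C <- crossprod(Qc) / nrow(Qc)
  if (sum(diag(C)) < 1e-24) stop("all window points coincide")
  eg <- eigen(C, symmetric = TRUE)
  tangent <- eg$vectors[, 1]
  if (sum(tangent * (Q[nrow(Q), ] - Q[1, ])) < 0) tangent <- -tangent
  degenerate <- eg$values[2] < 1e-12 * eg$values[1]
  list(tangent = tangent, plane_normal = eg$vectors[, 3],
       degenerate = degenerate)
}

# one sequential sweep of regularized window fits along the curve.
# Returns tangents, binormals (plane normals), |kappa| and the degenerate
# mask. The prior pulls each plane normal toward the previous one with
# weight `reg_weight` relative to the in-plane window variance, making the
# angular penalty commensurate with the plane-fit residual it would induce.
frenet_pass <- function(P, ds, half_window, reg_weight, reverse = FALSE) {
  n <- nrow(P)
  Tm <- matrix(NA_real_, n, 3)
  Bm <- matrix(NA_real_, n, 3)
  kap <- rep(NA_real_, n)
  degen <- rep(FALSE, n)
  idx <- if (reverse) rev(seq_len(n)) else seq_len(n)
  prevb <- NULL
  for (i in idx) {
    j0 <- i - half_window; j1 <- i + half_window
    if (j0 < 1 || j1 > n) next
    Q <- P[j0:j1, , drop = FALSE]
    Qc <- sweep(Q, 2, colMeans(Q))
    C <- crossprod(Qc) / nrow(Qc)
    eg <- eigen(C, symmetric = TRUE)
    tg <- eg$vectors[, 1]
    if (sum(tg * (P[min(i + 1, n), ] - P[max(i - 1, 1), ])) < 0) tg <- -tg
    if (eg$values[2] < 1e-12 * eg$values[1]) {
      # collinear window: kappa = 0, plane undefined; carry previous normal
      Tm[i, ] <- tg
      kap[i] <- 0
      degen[i] <- TRUE
      if (!is.null(prevb)) {
        bproj <- prevb - sum(prevb * tg) * tg
        if (vnorm(bproj) > 1e-9) {
          Bm[i, ] <- unitize(bproj)
          prevb <- Bm[i, ]
        }
      }
      next
    }
    Bas <- perp_basis(tg)
    C2 <- t(Bas) %*% C %*% Bas
    M <- C2
    sc <- max(eigen(C2, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.null(prevb)) {
      p2 <- as.vector(t(Bas) %*% prevb)
      np <- vnorm(p2)
      if (np > 1e-6) {
        p2 <- p2 / np
        M <- C2 + reg_weight * sc * (diag(2) - p2 %o% p2)
      }
    }
    e2 <- eigen(M, symmetric = TRUE)
    bn <- as.vector(Bas %*% e2$vectors[, 2])
    if (!is.null(prevb) && sum(bn * prevb) < 0) bn <- -bn
    nn <- cross3(bn, tg)
    fit <- taubin_circle_fit(cbind(Qc %*% tg, Qc %*% nn))
    kap[i] <- if (is.finite(fit$radius)) 1 / fit$radius else 0
    Tm[i, ] <- tg
    Bm[i, ] <- bn
    prevb <- bn
  }
  list(tangent = Tm, binormal = Bm, kappa = kap, degenerate = degen)
}

#' Robust Frenet-Serret frames, curvature and torsion of a noisy curve
#'
#' Implements the sliding-window osculating-plane/osculating-circle
#' estimator: for each sample a window of length `window_length` centered
#' at it is fit with a least-squares line (tangent) and plane, with a
#' continuity prior of weight `regularization_weight` on the angular change
#' of the plane normal between adjacent windows. The fit is run once
#' forward and once backward along the curve and the two plane-normal
#' fields are averaged, which cancels the lag a single causal sweep
#' introduces. The unsigned curvature is the inverse radius of a Taubin
#' circle fit to the window points projected into the osculating plane;
#' curvature is then signed by the rotation sense of the continuous frame
#' about the binormal. Torsion is the rotation rate of the binormal about
#' the tangent, averaged over a baseline of two window lengths (see
#' [torsion_from_plane_rotation()]).
#'
#' Samples within `window_length/2` of either end are masked invalid, and
#' torsion is masked where |kappa| is below `curvature_floor` (the normal
#' direction is ill-conditioned there).
#'
#' @param shape [flagellar_shape] (length must be >= 2 * window_length).
#' @param window_length sliding-window length (um).
#' @param regularization_weight continuity-prior weight.
#' @param curvature_floor |kappa| below which torsion is masked (1/um).
#' @return object of class `frenet_profile`: list with `s`, `tangent`,
#'   `normal`, `binormal` (n x 3), `kappa` (signed, 1/um), `tau` (1/um),
#'   `valid`, `tau_valid` logical masks.
#' @export
frenet_frames <- function(shape, window_length = 5,
                          regularization_weight = 0.1,
                          curvature_floor = 0.005) {
  P <- shape$points
  ds <- shape$ds
  if (arc_length(shape) < 2 * window_length) {
    stop("shape must be at least twice the window length")
  }
  hw <- max(2L, round(window_length / 2 / ds))
  fw <- frenet_pass(P, ds, hw, regularization_weight, reverse = FALSE)
  bw <- frenet_pass(P, ds, hw, regularization_weight, reverse = TRUE)
  n <- nrow(P)
  Bm <- fw$binormal
  for (i in seq_len(n)) {
    if (!is.na(fw$binormal[i, 1]) && !is.na(bw$binormal[i, 1])) {
      gb <- bw$binormal[i, ]
      if (sum(gb * fw$binormal[i, ]) < 0) gb <- -gb
      Bm[i, ] <- unitize(fw$binormal[i, ] + gb)
    }
  }
  Tm <- fw$tangent
  kap <- rep(NA_real_, n)
  Nm <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (is.na(Tm[i, 1])) next
    if (fw$degenerate[i]) { kap[i] <- 0; next }
    if (is.na(Bm[i, 1])) next
    tg <- Tm[i, ]
    bn <- unitize(Bm[i, ] - sum(Bm[i, ] * tg) * tg)
    Bm[i, ] <- bn
    nn <- cross3(bn, tg)
    Nm[i, ] <- nn
    j0 <- i - hw; j1 <- i + hw
    mu <- colMeans(P[j0:j1, , drop = FALSE])
    Qc <- sweep(P[j0:j1, , drop = FALSE], 2, mu)
    fit <- taubin_circle_fit(cbind(Qc %*% tg, Qc %*% nn))
    if (is.finite(fit$radius)) {
      # positive kappa: the frame rotates positively about b, i.e. the
      # circle center lies on the +normal side of the curve point
      ctr_side <- sign(fit$center[2] - sum((P[i, ] - mu) * nn))
      kap[i] <- ctr_side / fit$radius
    } else {
      kap[i] <- 0
    }
  }
  valid <- !is.na(kap)
  prof <- structure(
    list(s = shape$s, tangent = Tm, normal = Nm, binormal = Bm,
         kappa = kap, tau = rep(NA_real_, n), valid = valid,
         tau_valid = rep(FALSE, n), ds = ds, window_length = window_length),
    class = "frenet_profile")
  prof <- torsion_from_plane_rotation(prof, curvature_floor = curvature_floor)
  prof
}

#' Torsion from the rotation of the osculating plane along the curve
#'
#' Torsion at arclength s is the signed rate of rotation of the binormal
#' vector about the tangent vector per unit arclength. Per-step rotation
#' rates (centered differences of consecutive binormals) are averaged over
#' a baseline of two window lengths: normals of overlapping windows are
#' strongly correlated, so rates over shorter baselines carry little
#' information. Torsion is masked where |kappa| < `curvature_floor`.
#'
#' @param profile `frenet_profile` from [frenet_frames()].
#' @param curvature_floor mask threshold on |kappa| (1/um).
#' @return the profile with `tau` and `tau_valid` filled in.
#' @export
torsion_from_plane_rotation <- function(profile, curvature_floor = 0.005) {
  Bm <- profile$binormal
  Tm <- profile$tangent
  n <- nrow(Bm)
  ds <- profile$ds
  rate <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - 1 < 1 || i + 1 > n) next
    if (is.na(Bm[i - 1, 1]) || is.na(Bm[i + 1, 1]) || is.na(Tm[i, 1])) next
    rate[i] <- signed_angle(Bm[i - 1, ], Bm[i + 1, ], Tm[i, ]) / (2 * ds)
  }
  hw <- max(2L, round(profile$window_length / 2 / ds))
  tau <- running_mean(rate, 4L * hw + 1L)
  tau_valid <- !is.na(tau) & profile$valid &
    !is.na(profile$kappa) & abs(profile$kappa) >= curvature_floor
  tau[!tau_valid] <- NA_real_
  profile$tau <- tau
  profile$tau_valid <- tau_valid
  profile
}

#' Fix the global sign gauge of a curvature profile
#'
#' kappa(s, t) and -kappa(s, t) are equivalent descriptions of the same
#' shapes (flipping (n, b) to (-n, -b) flips kappa and leaves tau
#' unchanged). This helper applies the package's gauge convention: the
#' chosen sign makes `mean(kappa)` over the supplied profile(s)
#' non-negative.
#'
#' @param profile `frenet_profile`.
#' @return the profile, possibly with (normal, binormal, kappa) flipped.
#' @export
signed_curvature <- function(profile) {
  m <- mean(profile$kappa[profile$valid], na.rm = TRUE)
  if (!is.na(m) && m < 0) profile <- flip_gauge(profile)
  profile
}

flip_gauge <- function(profile) {
  profile$normal <- -profile$normal
  profile$binormal <- -profile$binormal
  profile$kappa <- -profile$kappa
  profile
}

#' Curvature and torsion kymographs of a beat recording
#'
#' Runs [frenet_frames()] on every frame and stacks the signed curvature
#' and torsion profiles on the (arclength x time) grid. The curvature sign
#' gauge is made temporally continuous (each frame is flipped to correlate
#' positively with its predecessor) and the global gauge is fixed so the
#' spatio-temporal mean of kappa over the first beat period is
#' non-negative.
#'
#' @param rec [beat_recording] (uniform time grid, identical arclength
#'   grids across frames).
#' @param window_length,regularization_weight,curvature_floor passed to
#'   [frenet_frames()].
#' @param T_beat optional beat period used for the global gauge; defaults
#'   to the full record.
#' @return object of class `kymograph`: list with `kappa`, `tau` (n_s x
#'   n_t matrices, 1/um), `valid`, `tau_valid`, `s`, `t`, `ds`, `dt`.
#' @export
compute_kymographs <- function(rec, window_length = 5,
                               regularization_weight = 0.1,
                               curvature_floor = 0.005, T_beat = NULL) {
  nf <- n_frames(rec)
  ns <- nrow(rec$frames[[1]]$points)
  for (f in rec$frames) {
    if (nrow(f$points) != ns) {
      stop("frames have inconsistent arclength grids")
    }
  }
  K <- matrix(NA_real_, ns, nf)
  Tau <- matrix(NA_real_, ns, nf)
  V <- matrix(FALSE, ns, nf)
  TV <- matrix(FALSE, ns, nf)
  prev_k <- NULL
  for (i in seq_len(nf)) {
    pr <- frenet_frames(rec$frames[[i]], window_length,
                        regularization_weight, curvature_floor)
    if (!is.null(prev_k)) {
      ok <- pr$valid & !is.na(prev_k)
      if (sum(pr$kappa[ok] * prev_k[ok], na.rm = TRUE) < 0) {
        pr <- flip_gauge(pr)
      }
    }
    K[, i] <- pr$kappa
    Tau[, i] <- pr$tau
    V[, i] <- pr$valid
    TV[, i] <- pr$tau_valid
    prev_k <- pr$kappa
  }
  dt <- frame_dt(rec)
  n_gauge <- if (is.null(T_beat)) nf else max(2L, min(nf, floor(T_beat / dt)))
  if (mean(K[, seq_len(n_gauge)][V[, seq_len(n_gauge)]], na.rm = TRUE) < 0) {
    K <- -K
  }
  structure(list(kappa = K, tau = Tau, valid = V, tau_valid = TV,
                 s = rec$frames[[1]]$s, t = rec$times,
                 ds = rec$frames[[1]]$ds, dt = dt),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d arclength x %d time samples (%.1f um x %.3f s)\n",
              nrow(x$kappa), ncol(x$kappa), max(x$s), diff(range(x$t))))
  invisible(x)
}
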