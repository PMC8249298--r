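#' Resistive-force-theory configuration
#'
#' Local anisotropic drag for a slender filament in Stokes flow: force per
#' unit length f = -[xi_par t t' + xi_perp (I - t t')] v. Only the ratio
#' xi_perp / xi_par matters for the force-free swimming kinematics;
#' xi_par sets the (arbitrary) force unit.
#'
#' @param xi_ratio drag anisotropy xi_perp / xi_par (> 1); 1.81 is the
#'   slender-body value for a typical flagellar aspect ratio.
#' @param xi_par tangential drag coefficient (arbitrary units).
#' @param head_drag optional isotropic point drag at the proximal end (same
#'   units as `xi_par * length`); 0 disables the head.
#' @return object of class `rft_config`.
#' @export
rft_config <- function(xi_ratio = 1.81, xi_par = 1, head_drag = 0) {
  stopifnot(xi_ratio > 1, xi_par > 0, head_drag >= 0)
  structure(list(xi_ratio = xi_ratio, xi_par = xi_par,
                 head_drag = head_drag),
            class = "rft_config")
}

#' Simulate swimming from a prescribed beat pattern
#'
#' Converts a body-frame beat recording into a lab-frame swimming
#' trajectory with resistive-force theory. Per time step, the local
#' deformation velocity comes from consecutive body-frame shapes; the
#' unknown rigid-body translation V and rotation Omega solve the 6x6
#' linear system expressing that the total drag force and torque vanish
#' (inertia-free Stokes swimming). Orientation is advanced with the
#' rotation exponential of Omega dt and re-orthonormalized; position with
#' the midpoint orientation. The returned object carries the lab-frame
#' head trajectory, the lab-frame shapes (for gyration/rolling analysis),
#' and per-step force/torque residuals.
#'
#' @param beat [beat_recording] in the body frame (shapes relative to a
#'   material frame anchored at the proximal end), uniform time grid
#'   covering the wanted duration; the time step must resolve the beat.
#' @param cfg [rft_config]
#' @param R0 initial body-to-lab rotation (3 x 3).
#' @param x0 initial body origin in the lab (um).
#' @return object of class `rft_simulation`: list with `times`,
#'   `head_positions` (lab, um), `head_axis` (lab), `lab_rec`
#'   ([beat_recording] in the lab frame), `V_body`, `Omega_body`
#'   (per-step rigid velocities), `residuals` (relative force/torque
#'   residual per step).
#' @export
simulate_swimming <- function(beat, cfg = rft_config(), R0 = diag(3),
                              x0 = c(0, 0, 0)) {
  if (!is_orthonormal(R0, 1e-9)) stop("R0 must be orthonormal")
  nf <- n_frames(beat)
  if (nf < 3) stop("beat recording too short")
  dt <- frame_dt(beat)
  ds <- beat$frames[[1]]$ds
  np <- nrow(beat$frames[[1]]$points)
  w <- rep(ds, np); w[1] <- w[np] <- ds / 2 # trapezoid weights
  xi_par <- cfg$xi_par
  xi_perp <- cfg$xi_ratio * xi_par

  Rk <- R0
  xk <- as.numeric(x0)
  times <- beat$times
  head_pos <- matrix(NA_real_, nf, 3)
  head_ax <- matrix(NA_real_, nf, 3)
  lab_frames <- vector("list", nf)
  V_body <- matrix(NA_real_, nf - 1, 3)
  O_body <- matrix(NA_real_, nf - 1, 3)
  resid <- rep(NA_real_, nf - 1)

  record_state <- function(k, Rk, xk) {
    p_lab <- t(Rk %*% t(beat$frames[[k]]$points)) +
      matrix(xk, np, 3, byrow = TRUE)
    lab_frames[[k]] <<- structure(
      list(points = p_lab, s = beat$frames[[k]]$s, ds = ds),
      class = "flagellar_shape")
    head_pos[k, ] <<- as.numeric(Rk %*% beat$head_center[k, ]) + xk
    head_ax[k, ] <<- as.numeric(Rk %*% beat$head_axis[k, ])
  }
  record_state(1, Rk, xk)

  skew <- function(r) matrix(c(0, r[3], -r[2],
                               -r[3], 0, r[1],
                               r[2], -r[1], 0), 3, 3)
  for (k in seq_len(nf - 1)) {
    P0 <- beat$frames[[k]]$points
    P1 <- beat$frames[[k + 1]]$points
    Pm <- (P0 + P1) / 2
    U <- (P1 - P0) / dt
    # midpoint tangents
    Tg <- rbind(Pm[2, ] - Pm[1, ],
                Pm[3:np, ] - Pm[1:(np - 2), ],
                Pm[np, ] - Pm[np - 1, ])
    Tg <- Tg / sqrt(rowSums(Tg^2))
    A <- matrix(0, 6, 6)
    rhs <- numeric(6)
    scale <- 0
    for (i in seq_len(np)) {
      tg <- Tg[i, ]
      Xi <- w[i] * (xi_par * (tg %o% tg) + xi_perp * (diag(3) - tg %o% tg))
      S <- skew(Pm[i, ])
      A[1:3, 1:3] <- A[1:3, 1:3] + Xi
      A[1:3, 4:6] <- A[1:3, 4:6] - Xi %*% S
      A[4:6, 1:3] <- A[4:6, 1:3] + S %*% Xi
      A[4:6, 4:6] <- A[4:6, 4:6] - S %*% Xi %*% S
      fu <- Xi %*% U[i, ]
      rhs[1:3] <- rhs[1:3] - fu
      rhs[4:6] <- rhs[4:6] - S %*% fu
      scale <- scale + vnorm(fu)
    }
    if (cfg$head_drag > 0) {
      rh <- (beat$head_center[k, ] + beat$head_center[k + 1, ]) / 2
      uh <- (beat$head_center[k + 1, ] - beat$head_center[k, ]) / dt
      Xi <- cfg$head_drag * diag(3)
      S <- skew(rh)
      A[1:3, 1:3] <- A[1:3, 1:3] + Xi
      A[1:3, 4:6] <- A[1:3, 4:6] - Xi %*% S
      A[4:6, 1:3] <- A[4:6, 1:3] + S %*% Xi
      A[4:6, 4:6] <- A[4:6, 4:6] - S %*% Xi %*% S
      fu <- Xi %*% uh
      rhs[1:3] <- rhs[1:3] - fu
      rhs[4:6] <- rhs[4:6] - S %*% fu
      scale <- scale + vnorm(fu)
    }
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      stop("singular resistance matrix: degenerate shape")
    })
    V <- sol[1:3]; Om <- sol[4:6]
    res <- A %*% sol - rhs
    resid[k] <- vnorm(res) / max(scale, .Machine$double.xmin)
    V_body[k, ] <- V
    O_body[k, ] <- Om
    Rmid <- Rk %*% rotation_exp(Om * dt / 2)
    xk <- xk + as.numeric(Rmid %*% V) * dt
    Rk <- Rk %*% rotation_exp(Om * dt)
    sv <- svd(Rk)
    Rk <- sv$u %*% t(sv$v)
    record_state(k + 1, Rk, xk)
  }
  lab_rec <- beat_recording(lab_frames, times, head_pos, head_ax,
                            truth = beat$truth)
  structure(list(times = times, head_positions = head_pos,
                 head_axis = head_ax, lab_rec = lab_rec,
                 V_body = V_body, Omega_body = O_body, residuals = resid),
            class = "rft_simulation")
}

#' @export
print.rft_simulation <- function(x, ...) {
  cat(sprintf("<rft_simulation> %d steps, %.3f s, net displacement %.2f um\n",
              length(x$times) - 1, diff(range(x$times)),
              vnorm(x$head_positions[nrow(x$head_positions), ] -
                    x$head_positions[1, ])))
  invisible(x)
}

#' Classify a simulated swimming path
#'
#' Discriminates the three stereotypical averaged paths from the gyration
#' spectrum of the averaged path: a nearly one-dimensional path (lateral
#' extent below 10% of the elongation) with monotonic rolling of the beat
#' plane is a "twisted_ribbon"; a curved path that stays planar
#' (non-planarity of the path below 0.1, total yaw turn above pi/4) is a
#' "circle"; a curved non-planar path is a "helix". Anything straddling
#' the thresholds is "unclassified" (diagnostics returned).
#'
#' @param sim [simulate_swimming()] result covering >= 5 beat periods.
#' @param T_beat beat period (s).
#' @return list with `class` and diagnostics (`straightness` = lateral/
#'   axial extent ratio, `Gamma_path` = path non-planarity, `r` circle-fit
#'   radius in the principal plane, `Omega_yaw`, `roll`).
#' @export
classify_path <- function(sim, T_beat) {
  traj <- trajectory(sim$times, sim$head_positions,
                     head_angle = head_orientation_angle(sim$head_axis))
  ap <- averaged_path(traj, T_beat)
  pc <- sweep(ap$positions, 2, colMeans(ap$positions))
  eg <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  aspect <- sqrt(lam[2] / lam[1])
  Gamma_path <- sqrt(lam[3] / max(lam[2], .Machine$double.xmin))
  duration <- diff(range(ap$times))
  roll <- rolling_analysis(sim$lab_rec)
  fy <- fit_circle_and_yaw(ap)
  q <- cbind(pc %*% eg$vectors[, 1], pc %*% eg$vectors[, 2])
  fit <- taubin_circle_fit(q)
  cls <- if (aspect < 0.1) {
    if (roll$classification == "rolling") "twisted_ribbon" else "unclassified"
  } else if (Gamma_path < 0.1) {
    if (abs(fy$Omega_yaw) * duration > pi / 4) "circle" else "unclassified"
  } else {
    "helix"
  }
  list(class = cls, straightness = aspect, Gamma_path = Gamma_path,
       r = fit$radius, Omega_yaw = fy$Omega_yaw, roll = roll)
}
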