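# Analytic curve builders and independent closed-form oracles used across
# the test files.

# parametric circular helix of radius a and pitch 2*pi*b, sampled at
# uniform arclength; curvature a/(a^2+b^2), torsion b/(a^2+b^2)
helix_points <- function(a, b, L, ds = 0.5) {
  c0 <- sqrt(a^2 + b^2)
  s <- seq(0, L, by = ds)
  cbind(a * cos(s / c0), a * sin(s / c0), b * s / c0)
}

helix_kappa <- function(a, b) a / (a^2 + b^2)
helix_tau <- function(a, b) b / (a^2 + b^2)

# initial Frenet frame of the parametric helix at s = 0
helix_frame0 <- function(a, b) {
  c0 <- sqrt(a^2 + b^2)
  tg <- c(0, a / c0, b / c0)
  nn <- c(-1, 0, 0)
  cbind(tg, nn, cross3_t(tg, nn))
}

cross3_t <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# full planar circle in the xy-plane, n points, endpoint not duplicated
circle_points <- function(R, n = 200, z = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(R * cos(th), R * sin(th), z)
}

# planar circular arc of given arclength starting at the origin along +x
arc_points <- function(R, L, ds = 0.5) {
  s <- seq(0, L, by = ds)
  cbind(R * sin(s / R), R * (1 - cos(s / R)), 0)
}

# circumscribed circle of a triangle (closed-form oracle)
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]
  cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# rotation matrix about a unit axis
rot_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# two planar arcs of equal arclength joined with a dihedral twist about
# the shared tangent at the junction
two_plane_curve <- function(seg_len = 22.5, R = 20, twist = pi / 4,
                            ds = 0.25) {
  s <- seq(0, seg_len, by = ds)
  arc1 <- cbind(R * sin(s / R), R * (1 - cos(s / R)), 0)
  n1 <- length(s)
  tangent_end <- c(cos(s[n1] / R), sin(s[n1] / R), 0)
  arc2 <- cbind(R * sin(s / R), R * (1 - cos(s / R)), 0)
  # move arc2 so it starts at the end of arc1 with matching tangent, then
  # twist its plane about the shared tangent
  tan0 <- c(1, 0, 0)
  ang <- atan2(tangent_end[2], tangent_end[1])
  Ralign <- rot_about(c(0, 0, 1), ang)
  Rtwist <- rot_about(tangent_end, twist)
  arc2 <- t(Rtwist %*% Ralign %*% t(arc2))
  arc2 <- sweep(arc2, 2, -arc1[n1, ], `-`)
  rbind(arc1, arc2[-1, , drop = FALSE])
}

# recording of a rigid shape whose orientation follows a supplied rotation
# angle series about a fixed axis (for rolling/wobbling tests)
rotating_arc_recording <- function(angles, dt = 1e-3, axis = NULL) {
  base <- arc_points(20, 30, ds = 0.5)
  if (is.null(axis)) axis <- gyration_tensor(base)$e1
  frames <- lapply(angles, function(a) {
    p <- t(rot_about(axis, a) %*% t(base))
    structure(list(points = p, s = seq(0, 30, by = 0.5), ds = 0.5),
              class = "flagellar_shape")
  })
  nf <- length(frames)
  hc <- t(vapply(frames, function(f) f$points[1, ], numeric(3)))
  ha <- t(vapply(frames, function(f) {
    v <- f$points[1, ] - f$points[2, ]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  beat_recording(frames, (seq_len(nf) - 1) * dt, hc, ha)
}

# small twisted-plane recording shared by several tests
twisted_plane_recording <- function(duration = 0.1, frame_rate = 500,
                                    tau0 = 0.1, noise_sd = 0) {
  params <- beat_params(K0 = 0, K1 = 0.08, lambda_w = 45, T_beat = 1 / 30,
                        tau0 = tau0, torsion_mode = "pulse_at_low_curvature",
                        duration = duration, frame_rate = frame_rate,
                        noise_sd = noise_sd)
  make_twisted_plane_beat(params)
}

# manual (n, b) -> (-n, -b) gauge flip of a frenet profile
flip_gauge_for_test <- function(pr) {
  pr$normal <- -pr$normal
  pr$binormal <- -pr$binormal
  pr$kappa <- -pr$kappa
  pr
}
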