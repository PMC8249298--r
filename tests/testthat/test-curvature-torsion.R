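test_that("Taubin circle fit is exact on circles and matches the circumcircle oracle", {
  th <- seq(0.2, 4, length.out = 25)
  xy <- cbind(3 + 7 * cos(th), -2 + 7 * sin(th))
  fit <- taubin_circle_fit(xy)
  expect_equal(fit$center, c(3, -2), tolerance = 1e-9)
  expect_equal(fit$radius, 7, tolerance = 1e-9)

  # three points: the circumscribed circle of the triangle (closed form)
  tri <- rbind(c(0, 0), c(4, 1), c(1, 5))
  fit3 <- taubin_circle_fit(tri)
  oracle <- circumcircle(tri[1, ], tri[2, ], tri[3, ])
  expect_equal(fit3$center, oracle$center, tolerance = 1e-8)
  expect_equal(fit3$radius, oracle$radius, tolerance = 1e-8)

  # collinear points: infinite radius, flagged
  fitc <- taubin_circle_fit(cbind(1:10, 2 * (1:10)))
  expect_true(fitc$collinear)
  expect_identical(fitc$radius, Inf)
})

test_that("Taubin fit recovers the radius of noisy circles (Monte Carlo)", {
  R <- 10
  set.seed(101)
  ok <- vapply(1:200, function(i) {
    th <- stats::runif(50, 0, 2 * pi)
    xy <- cbind(R * cos(th), R * sin(th)) +
      matrix(stats::rnorm(100, 0, R / 100), ncol = 2)
    abs(taubin_circle_fit(xy)$radius - R) / R < 0.02
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("osculating-plane fit recovers tangents and plane normals", {
  # planar arc: plane normal is the arc's plane normal
  w <- arc_points(10, 4, ds = 0.25)
  fit <- fit_osculating_plane(w)
  expect_lt(abs(abs(sum(fit$plane_normal * c(0, 0, 1))) - 1), 1e-6)
  expect_false(fit$degenerate)

  # collinear points: tangent along the line, flagged degenerate
  line <- cbind(seq(0, 3, by = 0.25), 0, 0)
  fitl <- fit_osculating_plane(line)
  expect_lt(abs(abs(fitl$tangent[1]) - 1), 1e-9)
  expect_true(fitl$degenerate)
  expect_error(fit_osculating_plane(matrix(1, 6, 3)), "coincide")

  # 5-um helix window: tangent within 2 degrees of the analytic tangent
  a <- 5; b <- 2; c0 <- sqrt(a^2 + b^2)
  p <- helix_points(a, b, 45, ds = 0.25)
  s <- seq(0, 45, by = 0.25)
  i <- 61 # window center
  win <- p[(i - 10):(i + 10), ]
  fith <- fit_osculating_plane(win)
  tg_true <- c(-a * sin(s[i] / c0), a * cos(s[i] / c0), b) / c0
  ang <- acos(min(1, abs(sum(fith$tangent * tg_true))))
  expect_lt(ang, 2 * pi / 180)
})

test_that("frenet_frames handles straight lines, circles and helices", {
  line <- flagellar_shape(cbind(seq(0, 30, by = 0.5), 0, 0),
                          resample = FALSE)
  pl <- frenet_frames(line)
  expect_true(all(pl$kappa[pl$valid] == 0))
  expect_true(any(pl$valid))
  expect_false(any(pl$tau_valid))
  # end margins masked
  expect_false(pl$valid[1])
  expect_false(pl$valid[length(pl$valid)])
  expect_error(frenet_frames(flagellar_shape(cbind(seq(0, 6, by = 0.5), 0, 0),
                                             resample = FALSE)),
               "twice the window")

  R <- 20
  circ <- flagellar_shape(arc_points(R, 35, ds = 0.5), resample = FALSE)
  pc <- frenet_frames(circ)
  expect_lt(max(abs(abs(pc$kappa[pc$valid]) - 1 / R)) / (1 / R), 0.01)
  expect_lt(max(abs(pc$tau[pc$tau_valid])), 1e-3)

  a <- 5; b <- 2
  hx <- flagellar_shape(helix_points(a, b, 45), resample = FALSE)
  ph <- frenet_frames(hx)
  mid <- 25:65
  expect_lt(stats::median(abs(abs(ph$kappa[mid]) - helix_kappa(a, b))) /
            helix_kappa(a, b), 0.05)
  expect_lt(stats::median(abs(ph$tau[mid] - helix_tau(a, b))) /
            helix_tau(a, b), 0.05)
  # b = t x n where valid
  i <- 40
  expect_lt(max(abs(cross3_t(ph$tangent[i, ], ph$normal[i, ]) -
                    ph$binormal[i, ])), 1e-6)
})

test_that("parameter recovery on the helix grid: <5% noiseless, <15% with 0.05 um noise", {
  # window adapted to the osculating radius for tight helices; median
  # relative error over the grid
  errs <- c()
  for (a in c(1, 2, 5, 10)) for (b in c(1, 2, 5, 10)) {
    kt <- helix_kappa(a, b); tt <- helix_tau(a, b)
    win <- min(5, 0.8 / kt)
    ds <- min(0.5, win / 10)
    sh <- flagellar_shape(helix_points(a, b, 45, ds = ds), resample = FALSE)
    pr <- frenet_frames(sh, window_length = win)
    n <- length(pr$s)
    mid <- round(0.25 * n):round(0.75 * n)
    errs <- rbind(errs, c(
      stats::median(abs(abs(pr$kappa[mid]) - kt) / kt, na.rm = TRUE),
      stats::median(abs(pr$tau[mid] - tt) / tt, na.rm = TRUE)))
  }
  expect_lt(stats::median(errs[, 1]), 0.05)
  expect_lt(stats::median(errs[, 2]), 0.05)

  # with tracking noise at the reference helix (a = 5, b = 2)
  a <- 5; b <- 2
  kt <- helix_kappa(a, b); tt <- helix_tau(a, b)
  set.seed(11)
  noisy <- vapply(1:8, function(i) {
    p <- helix_points(a, b, 45) + matrix(stats::rnorm(273, 0, 0.05), ncol = 3)
    sh <- flagellar_shape(p, ds = 0.5)
    pr <- frenet_frames(sh)
    n <- length(pr$s)
    mid <- round(0.25 * n):round(0.75 * n)
    c(stats::median(abs(abs(pr$kappa[mid]) - kt) / kt, na.rm = TRUE),
      stats::median(abs(pr$tau[mid] - tt) / tt, na.rm = TRUE))
  }, numeric(2))
  expect_lt(mean(noisy[1, ]), 0.15)
  expect_lt(mean(noisy[2, ]), 0.15)
})

test_that("curvature and torsion are rigid-motion invariant and gauge-consistent", {
  p <- helix_points(4, 2, 45, ds = 0.5)
  sh <- flagellar_shape(p, resample = FALSE)
  pr <- frenet_frames(sh)
  Rm <- rot_about(c(1, 0.4, -0.2), 2.1)
  sh2 <- sh
  sh2$points <- t(Rm %*% t(p)) + matrix(c(3, 1, -8), nrow(p), 3, byrow = TRUE)
  pr2 <- frenet_frames(sh2)
  ok <- pr$valid & pr2$valid
  expect_lt(max(abs(abs(pr$kappa[ok]) - abs(pr2$kappa[ok]))), 1e-6)
  okt <- pr$tau_valid & pr2$tau_valid
  expect_lt(max(abs(pr$tau[okt] - pr2$tau[okt])), 1e-6)

  # global (n, b) flip: kappa sign flips, tau bitwise identical
  flipped <- pr
  flipped$normal <- -pr$normal
  flipped$binormal <- -pr$binormal
  flipped$kappa <- -pr$kappa
  flipped$tau[] <- NA_real_
  flipped <- torsion_from_plane_rotation(flipped)
  expect_lt(max(abs(flipped$tau[okt] - pr$tau[okt])), 1e-12)

  # signed_curvature gauge: spatio-temporal mean becomes non-negative
  neg <- flip_gauge_for_test(pr)
  fixed <- signed_curvature(neg)
  expect_gte(mean(fixed$kappa[fixed$valid]), 0)
})

test_that("signed curvature follows the frame-rotation convention on a circle", {
  # counter-clockwise planar circle traversed proximal to distal with the
  # continuous frame's binormal along +z: kappa > 0 throughout
  sh <- flagellar_shape(arc_points(15, 35, ds = 0.5), resample = FALSE)
  pr <- signed_curvature(frenet_frames(sh))
  expect_true(all(pr$kappa[pr$valid] > 0))
  # with that gauge the binormal is +z everywhere valid
  bz <- pr$binormal[pr$valid, 3]
  expect_true(all(abs(abs(bz) - 1) < 1e-6))
  # the tangent rotates towards the normal (t' = kappa*n with kappa > 0)
  i <- 30
  dtds <- (pr$tangent[i + 1, ] - pr$tangent[i - 1, ]) / (2 * sh$ds)
  expect_gt(sum(dtds * pr$normal[i, ]), 0)
})

test_that("torsion pulse of the twisted-plane shape is localized at the curvature minimum", {
  rec <- twisted_plane_recording(duration = 0.02, frame_rate = 600)
  i <- 5
  pr <- frenet_frames(rec$frames[[i]])
  ctr <- rec$truth$pulse_center(rec$times[i])
  # only test frames whose pulse is away from the masked ends
  if (ctr > 12 && ctr < 33) {
    tmin <- which.min(pr$tau)
    expect_lt(pr$tau[tmin], -0.005)
    expect_lt(abs(pr$s[tmin] - ctr), 5)
  }
  # the pulse is the only strongly negative region
  expect_lt(sum(pr$tau < -0.01, na.rm = TRUE) * rec$frames[[i]]$ds, 20)
})

test_that("kymographs are periodic, gauge-fixed and carry the wave speed", {
  rec <- make_planar_asymmetric_beat(
    beat_params(K0 = 0.01, K1 = 0.08, lambda_w = 40, T_beat = 1 / 25,
                duration = 2 / 25, frame_rate = 500))
  kym <- compute_kymographs(rec, T_beat = 1 / 25)
  expect_gte(mean(kym$kappa[kym$valid]), 0)
  # periodicity: columns one period apart agree
  per <- 20 # frames per period
  ok <- kym$valid[, 1] & kym$valid[, 1 + per]
  expect_lt(max(abs(kym$kappa[ok, 1] - kym$kappa[ok, 1 + per])), 1e-6)

  # wavefront: the kappa zero-crossing locus moves at lambda_w / T
  zc <- rep(NA_real_, ncol(kym$kappa))
  for (j in seq_len(ncol(kym$kappa))) {
    col <- kym$kappa[, j]
    col[!kym$valid[, j]] <- NA
    i <- which(col[-length(col)] > 0 & col[-1] <= 0)
    if (length(i)) {
      i <- i[1]
      frac <- col[i] / (col[i] - col[i + 1])
      zc[j] <- kym$s[i] + frac * kym$ds
    }
  }
  # use the longest stretch following one crossing (no wrap-around jumps)
  good <- which(!is.na(zc))
  brk <- good[c(FALSE, abs(diff(zc[good])) > 4)]
  runs <- split(good, cumsum(good %in% brk))
  run <- runs[[which.max(lengths(runs))]]
  fitv <- stats::coef(stats::lm(zc[run] ~ kym$t[run]))[2]
  expect_equal(unname(fitv), 40 * 25, tolerance = 0.1)

  # static shape: identical kymograph columns
  recs <- make_planar_asymmetric_beat(
    beat_params(K0 = 0.04, K1 = 0, duration = 0.02, frame_rate = 600))
  kys <- compute_kymographs(recs)
  expect_lt(max(abs(kys$kappa[kys$valid[, 1], 1] -
                    kys$kappa[kys$valid[, 1], 5])), 1e-9)
})

test_that("two-segment non-planarity finds the torsion point of twisted-plane shapes", {
  # planar curve: Gamma_ts = 0
  sh <- flagellar_shape(arc_points(20, 40, ds = 0.5), resample = FALSE)
  ts <- two_segment_nonplanarity(sh)
  expect_equal(ts$Gamma_ts, 0, tolerance = 1e-9)
  expect_true(all(ts$scan$Gbar >= ts$Gamma_ts - 1e-15))

  # two planar 22.5-um arcs joined with a 45-degree dihedral twist
  curve <- two_plane_curve(seg_len = 22.5, R = 20, twist = pi / 4, ds = 0.25)
  sh2 <- flagellar_shape(curve, ds = 0.25, resample = FALSE)
  ts2 <- two_segment_nonplanarity(sh2)
  expect_lt(ts2$Gamma_ts, 0.02)
  expect_lt(abs(ts2$s_ts - 22.5), 2)
  # Gamma_ts is dramatically smaller than the whole-shape Gamma
  expect_lt(ts2$Gamma_ts, 0.2 * gyration_tensor(sh2)$Gamma)

  # 3-turn helix: no planar split exists; frozen brute-force oracle 0.775
  L3 <- 3 * 2 * pi * sqrt(2)
  sh3 <- flagellar_shape(helix_points(1, 1, L3, ds = L3 / 400),
                         resample = FALSE)
  ts3 <- two_segment_nonplanarity(sh3, min_segment = 3)
  expect_gt(ts3$Gamma_ts, 0.5)
  expect_equal(ts3$Gamma_ts, 0.775, tolerance = 0.05)
})
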