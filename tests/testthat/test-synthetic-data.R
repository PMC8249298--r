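test_that("Frenet-Serret construction reproduces straight lines, circles and helices", {
  # zero curvature and torsion: straight segment along the initial tangent
  sh <- shape_from_curvature_torsion(function(s) 0 * s, function(s) 0 * s,
                                     L = 30, ds = 0.5)
  expect_equal(sh$points, cbind(sh$s, 0, 0), tolerance = 1e-9)

  # constant curvature 1/R over L = 2*pi*R: closed planar circle
  R <- 5
  L <- 2 * pi * R
  shc <- shape_from_curvature_torsion(function(s) rep(1 / R, length(s)),
                                      function(s) 0 * s,
                                      L = L, ds = L / 640)
  gap <- sqrt(sum((shc$points[nrow(shc$points), ] - shc$points[1, ])^2))
  expect_lt(gap, 1e-3 * R)
  expect_lt(max(abs(shc$points[, 3])), 1e-9)

  # constant curvature+torsion: circular helix, compared point-wise with
  # the closed-form parametric helix
  a <- 5; b <- 2
  shh <- shape_from_curvature_torsion(
    function(s) rep(helix_kappa(a, b), length(s)),
    function(s) rep(helix_tau(a, b), length(s)),
    L = 45, ds = 0.25,
    initial_frame = helix_frame0(a, b), origin = c(a, 0, 0))
  ref <- helix_points(a, b, 45, ds = 0.25)
  expect_lt(max(sqrt(rowSums((shh$points - ref)^2))), 1e-3)
})

test_that("a non-orthonormal initial frame is rejected", {
  F0 <- diag(3); F0[1, 2] <- 0.5
  expect_error(
    shape_from_curvature_torsion(function(s) 0 * s, function(s) 0 * s,
                                 L = 30, ds = 0.5, initial_frame = F0),
    "orthonormal")
})

test_that("planar asymmetric beat is planar with time-mean curvature K0", {
  params <- beat_params(K0 = 0.03, K1 = 0.08, lambda_w = 40,
                        T_beat = 1 / 40, duration = 1 / 40, frame_rate = 800)
  rec <- make_planar_asymmetric_beat(params)
  lam3 <- vapply(rec$frames,
                 function(f) gyration_tensor(f)$lambda[3], numeric(1))
  expect_lt(max(lam3), 1e-12)
  # time-mean of the ground-truth curvature over one full period is K0
  # (frame_rate * T_beat = 20 frames per period, sampled phases cancel)
  s_grid <- seq(0, 45, by = 0.5)
  t_grid <- (0:19) / 800
  km <- rowMeans(vapply(t_grid, function(t) rec$truth$kappa(s_grid, t),
                        numeric(length(s_grid))))
  expect_equal(km, rep(0.03, length(s_grid)), tolerance = 1e-12)
})

test_that("K1 = 0 gives a static circular arc of radius 1/K0", {
  R <- 25
  params <- beat_params(K0 = 1 / R, K1 = 0, lambda_w = 40, T_beat = 1 / 30,
                        duration = 0.01, frame_rate = 1000)
  rec <- make_planar_asymmetric_beat(params)
  p <- rec$frames[[1]]$points
  fit <- taubin_circle_fit(p[, 1:2])
  expect_equal(fit$radius, R, tolerance = 1e-6)
})

test_that("symmetric beat has exact mirror symmetry and planar frames when tau0 = 0", {
  params <- beat_params(K0 = 0, K1 = 0.08, lambda_w = 40, T_beat = 1 / 30,
                        tau0 = 0, torsion_mode = "constant",
                        duration = 0.05, frame_rate = 600)
  rec <- make_symmetric_torsion_beat(params)
  s <- seq(0, 45, by = 0.5)
  phases <- seq(0, params$T_beat, length.out = 13)
  for (t in phases) {
    expect_lt(max(abs(rec$truth$kappa(s, t) +
                      rec$truth$kappa(s, t + params$T_beat / 2))), 1e-9)
  }
  lam3 <- vapply(rec$frames,
                 function(f) gyration_tensor(f)$lambda[3], numeric(1))
  expect_lt(max(lam3), 1e-12)
  expect_error(
    make_symmetric_torsion_beat(
      beat_params(K0 = 0.01, torsion_mode = "constant")),
    "K0")
})

test_that("twisted-plane beat: non-positive torsion pulse rides the descending curvature zero", {
  rec <- twisted_plane_recording(duration = 0.05, frame_rate = 600)
  params <- rec$truth$params
  s <- seq(0, params$L, by = params$ds)
  for (t in rec$times[seq(1, length(rec$times), by = 7)]) {
    tau <- rec$truth$tau(s, t)
    expect_true(all(tau <= 1e-12))
    ctr <- rec$truth$pulse_center(t)
    # pulse minimum sits at the descending zero crossing of kappa
    expect_lt(abs(s[which.min(tau)] - ctr), params$ds + 1e-9)
    kap <- rec$truth$kappa(s, t)
    expect_lt(abs(kap[which.min(abs(s - ctr))]), 0.05 * params$K1)
    # the |kappa| minimum nearest the pulse is within L/10 of its center
    expect_lt(min(abs(s[abs(kap) < 0.05 * params$K1] - ctr)), params$L / 10)
  }
  # tau0 = 0 degenerates to planar frames
  rec0 <- twisted_plane_recording(duration = 0.02, frame_rate = 600,
                                  tau0 = 0)
  g <- gyration_tensor(rec0$frames[[5]])
  expect_lt(g$lambda[3], 1e-12)
  expect_equal(g$Gamma, 0)
})

test_that("tracking noise is seeded, optional, and preserves uniform spacing", {
  rec <- twisted_plane_recording(duration = 0.02, frame_rate = 600)
  same <- add_tracking_noise(rec, 0, 7)
  expect_identical(same, rec)
  n1 <- add_tracking_noise(rec, 0.05, 7)
  n2 <- add_tracking_noise(rec, 0.05, 7)
  expect_identical(n1$frames, n2$frames)
  n3 <- add_tracking_noise(rec, 0.05, 8)
  expect_false(identical(n1$frames[[1]]$points, n3$frames[[1]]$points))
  seg <- sqrt(rowSums(diff(n1$frames[[1]]$points)^2))
  expect_lt(max(abs(seg - n1$frames[[1]]$ds)), 1e-6)
})

test_that("rendered filament volumes integrate to the Gaussian-blob mass", {
  P <- cbind(seq(0, 20, by = 0.5), 0, 0)
  sh <- flagellar_shape(P, resample = FALSE)
  vol <- render_filament_volume(sh, voxel = 0.25, psf_sd = 0.5)
  expected <- nrow(sh$points) * (2 * pi)^1.5 * 0.5^3 / 0.25^3
  expect_equal(sum(vol$data), expected, tolerance = 0.05)
  # brightest voxel lies on the filament axis (within one psf_sd)
  idx <- arrayInd(which.max(vol$data), dim(vol$data))
  pos <- vol$origin + (as.numeric(idx) - 1) * vol$voxel
  expect_lt(sqrt(pos[2]^2 + pos[3]^2), 0.5)
  # intensity ridge follows the straight axis at every x-slab
  for (i in seq(5, dim(vol$data)[1] - 5, by = 10)) {
    sl <- vol$data[i, , ]
    ij <- arrayInd(which.max(sl), dim(sl))
    ridge <- vol$origin[2:3] + (as.numeric(ij) - 1) * vol$voxel
    expect_lt(sqrt(sum(ridge^2)), 0.5)
  }
  expect_error(render_filament_volume(sh, voxel = 1, psf_sd = 0.5), "voxel")
})

test_that("generators are deterministic under a fixed seed", {
  p <- beat_params(K0 = 0.03, duration = 0.02, frame_rate = 600,
                   noise_sd = 0.05, rng_seed = 42)
  r1 <- make_planar_asymmetric_beat(p)
  r2 <- make_planar_asymmetric_beat(p)
  expect_identical(r1$frames, r2$frames)
})
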