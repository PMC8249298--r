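#' Build a space curve from prescribed curvature and torsion
#'
#' Integrates the Frenet-Serret equations t' = kappa n, n' = -kappa t +
#' tau b, b' = -tau n from arclength 0 to `L`, returning points at uniform
#' arclength spacing `ds`. This is the forward construction inverse to the
#' curvature/torsion estimator and serves as its ground-truth oracle: a
#' beat pattern is fully specified by kappa(s) and tau(s) up to a rigid
#' motion fixed by `origin` and `initial_frame`.
#'
#' @param kappa_profile function of arclength s returning curvature (1/um).
#' @param tau_profile function of arclength s returning torsion (1/um).
#' @param L total arclength (um).
#' @param ds output spacing (um); must satisfy ds <= L/20.
#' @param initial_frame 3 x 3 matrix with columns (tangent, normal,
#'   binormal) at s = 0; must be orthonormal.
#' @param origin curve start point (um).
#' @return [flagellar_shape] with points exactly on the integrated curve at
#'   uniform arclength spacing.
#' @export
shape_from_curvature_torsion <- function(kappa_profile, tau_profile, L,
                                         ds = 0.5,
                                         initial_frame = diag(3),
                                         origin = c(0, 0, 0)) {
  if (ds > L / 20) stop("ds must be <= L/20")
  if (!is_orthonormal(initial_frame)) {
    stop("initial_frame must be orthonormal")
  }
  deriv <- function(s, y, parms) {
    tg <- y[4:6]; nn <- y[7:9]; bb <- y[10:12]
    k <- kappa_profile(s); tu <- tau_profile(s)
    list(c(tg, k * nn, -k * tg + tu * bb, -tu * nn))
  }
  y0 <- c(origin, initial_frame[, 1], initial_frame[, 2], initial_frame[, 3])
  s_out <- seq(0, L, by = ds)
  sol <- deSolve::ode(y = y0, times = s_out, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-11)
  pts <- unname(sol[, 2:4])
  structure(list(points = pts, s = s_out, ds = ds),
            class = "flagellar_shape")
}

#' Beat recording from arbitrary curvature/torsion wave functions
#'
#' General constructor behind the named beat generators: every frame is
#' built with [shape_from_curvature_torsion()] from the supplied
#' kappa(s, t) and tau(s, t), in the body frame anchored at the proximal
#' end (fixed initial Frenet frame). Useful for beat classes not covered
#' by the named generators, e.g. an asymmetric beat with constant torsion
#' (helical swimming).
#'
#' @param params [beat_params] (supplies L, ds, frame grid, noise).
#' @param kappa_st function of (s, t) returning curvature (1/um).
#' @param tau_st function of (s, t) returning torsion (1/um).
#' @return [beat_recording] with `$truth` carrying the wave functions.
#' @export
make_custom_beat <- function(params, kappa_st, tau_st) {
  build_wave_recording(params, kappa_st, tau_st)
}

# shared machinery: sample a traveling-wave beat into a beat_recording
build_wave_recording <- function(params, kappa_st, tau_st) {
  tt <- seq(0, params$duration, by = 1 / params$frame_rate)
  frames <- vector("list", length(tt))
  head_center <- matrix(0, length(tt), 3)
  head_axis <- matrix(0, length(tt), 3)
  for (i in seq_along(tt)) {
    sh <- shape_from_curvature_torsion(
      function(s) kappa_st(s, tt[i]),
      function(s) tau_st(s, tt[i]),
      L = params$L, ds = params$ds)
    frames[[i]] <- sh
    head_center[i, ] <- sh$points[1, ]
    # head long axis points forward, away from the flagellum
    head_axis[i, ] <- -unitize(sh$points[2, ] - sh$points[1, ])
  }
  rec <- beat_recording(frames, tt, head_center, head_axis,
                        truth = list(kappa = kappa_st, tau = tau_st,
                                     params = params))
  if (params$noise_sd > 0) {
    rec <- add_tracking_noise(rec, params$noise_sd, params$rng_seed)
  }
  rec
}

#' Planar asymmetric traveling-wave beat (sea-urchin-like)
#'
#' kappa(s, t) = K0 + K1 sin(2 pi s / lambda_w - 2 pi t / T), tau = 0.
#' A positive mean curvature `K0` makes the beat asymmetric; every frame is
#' planar before noise.
#'
#' @param params [beat_params] with `torsion_mode = "none"`.
#' @return [beat_recording]; ground-truth kappa/tau functions are attached
#'   in `$truth`.
#' @export
make_planar_asymmetric_beat <- function(params) {
  if (params$torsion_mode != "none") {
    stop("planar beat requires torsion_mode = 'none'")
  }
  kap <- function(s, t) {
    params$K0 + params$K1 * sin(2 * pi * s / params$lambda_w -
                                2 * pi * t / params$T_beat)
  }
  build_wave_recording(params, kap, function(s, t) 0 * s)
}

#' Symmetric sinusoidal beat with constant torsion
#'
#' kappa(s, t) = K1 sin(2 pi s / lambda_w - 2 pi t / T), tau = tau0. The
#' curvature satisfies the mirror symmetry kappa(s, t) = -kappa(s, t + T/2)
#' exactly; under resistive-force theory this beat class swims along a
#' straight averaged path with a continuously rotating beat plane (twisted
#' ribbon).
#'
#' @param params [beat_params] with `K0 = 0` and
#'   `torsion_mode = "constant"`.
#' @return [beat_recording]
#' @export
make_symmetric_torsion_beat <- function(params) {
  if (params$torsion_mode != "constant") {
    stop("symmetric torsion beat requires torsion_mode = 'constant'")
  }
  if (params$K0 != 0) stop("symmetric beat requires K0 = 0")
  kap <- function(s, t) {
    params$K1 * sin(2 * pi * s / params$lambda_w - 2 * pi * t / params$T_beat)
  }
  tau <- function(s, t) rep(params$tau0, length(s))
  build_wave_recording(params, kap, tau)
}

# arclength of the descending zero crossing of the curvature wave at time t
# (phase = pi mod 2*pi), folded into [0, L)
descending_zero <- function(params, t) {
  lam <- params$lambda_w
  base <- lam * (0.5 + t / params$T_beat)
  base %% lam
}

#' Twisted-plane beat with a traveling torsion pulse (human-like)
#'
#' A symmetric traveling curvature wave whose wavelength is comparable to
#' the flagellar length, plus a localized negative torsion pulse (Gaussian
#' in arclength) centered on the descending zero-crossing of the curvature
#' wave and traveling with it. Torsion is therefore everywhere non-positive
#' (homochiral) and peaks where curvature is low, so each instantaneous
#' shape is approximately two flat segments joined with a twist.
#'
#' @param params [beat_params] with
#'   `torsion_mode = "pulse_at_low_curvature"`; `tau0` is the pulse
#'   amplitude (the pulse is `-tau0` at its center) and the pulse s.d. is
#'   `L/20` (full width about L/10).
#' @return [beat_recording]; `$truth$pulse_center(t)` gives the pulse
#'   arclength position.
#' @export
make_twisted_plane_beat <- function(params) {
  if (params$torsion_mode != "pulse_at_low_curvature") {
    stop("twisted-plane beat requires torsion_mode = 'pulse_at_low_curvature'")
  }
  if (params$lambda_w < 0.5 * params$L || params$lambda_w > 2 * params$L) {
    stop("twisted-plane beat assumes lambda_w comparable to L")
  }
  kap <- function(s, t) {
    params$K0 + params$K1 * sin(2 * pi * s / params$lambda_w -
                                2 * pi * t / params$T_beat)
  }
  sig <- params$L / 20
  tau <- function(s, t) {
    c0 <- descending_zero(params, t)
    # periodic images keep the pulse smooth while it wraps across the ends
    -params$tau0 * (exp(-(s - c0)^2 / (2 * sig^2)) +
                    exp(-(s - c0 - params$lambda_w)^2 / (2 * sig^2)) +
                    exp(-(s - c0 + params$lambda_w)^2 / (2 * sig^2)))
  }
  rec <- build_wave_recording(params, kap, tau)
  rec$truth$pulse_center <- function(t) descending_zero(params, t)
  rec
}

#' Add isotropic Gaussian tracking noise to a recording
#'
#' Each centerline point is displaced by i.i.d. isotropic Gaussian noise
#' and each frame is then re-resampled to uniform spacing, emulating the
#' point-wise error of holographic centerline tracking. Deterministic for a
#' fixed seed. Head pose is left untouched.
#'
#' @param rec [beat_recording]
#' @param noise_sd displacement s.d. per coordinate (um).
#' @param rng_seed integer seed.
#' @return [beat_recording]
#' @export
add_tracking_noise <- function(rec, noise_sd, rng_seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(rec)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(rng_seed))
  for (i in seq_along(rec$frames)) {
    p <- rec$frames[[i]]$points
    p <- p + matrix(stats::rnorm(length(p), 0, noise_sd), ncol = 3)
    rec$frames[[i]] <- flagellar_shape(p, ds = rec$frames[[i]]$ds,
                                       resample = TRUE)
  }
  rec
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a flagellar shape into a synthetic intensity volume
#'
#' Places an isotropic Gaussian blob (s.d. `psf_sd`) at every centerline
#' point, emulating a refocused stack of a fluorescent/phase filament, with
#' optional Gaussian background noise (clamped at zero so intensities stay
#' non-negative) and an optional brighter head blob at the proximal end.
#'
#' @param shape [flagellar_shape]
#' @param voxel voxel edge length (um); must be <= `psf_sd`.
#' @param psf_sd blob s.d. (um).
#' @param background_sd s.d. of additive Gaussian background noise.
#' @param head_amp amplitude of an extra blob at s = 0 relative to the
#'   filament blob amplitude (0 disables it).
#' @param margin empty border around the shape (um); at least `3 * psf_sd`.
#' @param rng_seed seed for the background noise.
#' @return object of class `intensity_volume`: list with `data` (3D array),
#'   `voxel`, `origin` (um position of the center of voxel [1,1,1]).
#' @export
render_filament_volume <- function(shape, voxel = 0.25, psf_sd = 0.5,
                                   background_sd = 0, head_amp = 0,
                                   margin = NULL, rng_seed = 1L) {
  if (voxel > psf_sd) stop("voxel must be <= psf_sd")
  if (is.null(margin)) margin <- 3 * psf_sd
  if (margin < 3 * psf_sd) stop("margin must be >= 3 * psf_sd")
  p <- shape$points
  lo <- apply(p, 2, min) - margin
  hi <- apply(p, 2, max) + margin
  dims <- pmax(ceiling((hi - lo) / voxel) + 1L, 5L)
  vol <- array(0, dim = dims)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1) * voxel)
  r <- ceiling(4 * psf_sd / voxel)
  amp <- c(rep(1, nrow(p)))
  if (head_amp > 0) amp[1] <- amp[1] + head_amp
  for (i in seq_len(nrow(p))) {
    ic <- pmin(pmax(round((p[i, ] - lo) / voxel) + 1, 1), dims)
    i1 <- pmax(ic - r, 1); i2 <- pmin(ic + r, dims)
    gx <- exp(-(ax[[1]][i1[1]:i2[1]] - p[i, 1])^2 / (2 * psf_sd^2))
    gy <- exp(-(ax[[2]][i1[2]:i2[2]] - p[i, 2])^2 / (2 * psf_sd^2))
    gz <- exp(-(ax[[3]][i1[3]:i2[3]] - p[i, 3])^2 / (2 * psf_sd^2))
    vol[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <-
      vol[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] +
      amp[i] * (gx %o% gy %o% gz)
  }
  if (background_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(rng_seed))
    vol <- pmax(vol + array(stats::rnorm(length(vol), 0, background_sd),
                            dim = dims), 0)
  }
  structure(list(data = vol, voxel = voxel, origin = lo),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s voxels @ %.3g um, origin (%.1f, %.1f, %.1f)\n",
              paste(dim(x$data), collapse = " x "), x$voxel,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}
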