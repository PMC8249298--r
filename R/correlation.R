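# Correlation statistics of curvature and torsion waves.

# normalized lagged correlation <x(t) y(t+dt)> with pairwise deletion of
# missing entries; means and standard deviations are taken over the same
# overlapping pairs, so |result| <= 1 holds exactly (Cauchy-Schwarz) and
# the estimate agrees with the global-moment normalization for long
# stationary records
lagged_corr <- function(x, y, lag) {
  n <- length(x)
  if (lag >= 0) {
    xi <- x[seq_len(n - lag)]
    yi <- y[seq_len(n - lag) + lag]
  } else {
    xi <- x[(1 - lag):n]
    yi <- y[seq_len(n + lag)]
  }
  ok <- !is.na(xi) & !is.na(yi)
  if (sum(ok) < 3) return(NA_real_)
  xi <- xi[ok]; yi <- yi[ok]
  sx <- sqrt(mean(xi^2) - mean(xi)^2)
  sy <- sqrt(mean(yi^2) - mean(yi)^2)
  if (sx <= 0 || sy <= 0) return(NA_real_)
  (mean(xi * yi) - mean(xi) * mean(yi)) / (sx * sy)
}

#' Autocorrelation of the curvature wave and beat period
#'
#' For each arclength sample in `s_band`, computes the normalized
#' autocorrelation A(s, dt) = (<kappa(s,t) kappa(s,t+dt)> - <kappa>^2) /
#' sigma_kappa^2 of the curvature time series (pairwise deletion of masked
#' entries), then averages A over the band. The beat period T is the lag
#' of the first local maximum of A at positive lag.
#'
#' @param kym [compute_kymographs()] result.
#' @param s_band length-2 arclength range (um); defaults to the middle
#'   fifth of the flagellum.
#' @param max_lag largest lag scanned (s); defaults to half the record.
#' @return list with `lags` (s), `A`, `T_beat` (s).
#' @export
curvature_autocorrelation <- function(kym, s_band = NULL, max_lag = NULL) {
  if (is.null(s_band)) {
    L <- max(kym$s)
    s_band <- c(0.4 * L, 0.6 * L)
  }
  rows <- which(kym$s >= s_band[1] & kym$s <= s_band[2])
  rows <- rows[rowSums(kym$valid[rows, , drop = FALSE]) >= 3]
  if (length(rows) == 0) stop("no valid samples in s_band")
  nt <- ncol(kym$kappa)
  max_k <- if (is.null(max_lag)) floor((nt - 1) / 2) else
    min(nt - 3, round(max_lag / kym$dt))
  lags <- 0:max_k
  A <- matrix(NA_real_, length(rows), length(lags))
  for (r in seq_along(rows)) {
    x <- kym$kappa[rows[r], ]
    x[!kym$valid[rows[r], ]] <- NA
    if (stats::var(x, na.rm = TRUE) <= 0) next
    A[r, ] <- vapply(lags, function(k) lagged_corr(x, x, k), numeric(1))
  }
  Abar <- colMeans(A, na.rm = TRUE)
  T_beat <- NA_real_
  for (k in 2:(length(Abar) - 1)) {
    if (!any(is.na(Abar[(k - 1):(k + 1)])) &&
        Abar[k] >= Abar[k - 1] && Abar[k] > Abar[k + 1] && Abar[k] > 0) {
      T_beat <- lags[k] * kym$dt
      break
    }
  }
  if (is.na(T_beat)) stop("beat period undetermined: no local maximum in A")
  list(lags = lags * kym$dt, A = Abar, T_beat = T_beat)
}

#' Cross-correlation between |curvature| and torsion waves
#'
#' Computes C(s, dt) = (<|kappa(s,t)| tau(s,t+dt)> - <|kappa|><tau>) /
#' (sigma_|kappa| sigma_tau) with pairwise deletion of masked entries,
#' averaged over the arclength band, over lags up to `lag_factor` beat
#' periods on both sides. The phase shift between torsion and curvature
#' waves is the lag of the extremum of |C| nearest dt = 0 (excluding an
#' interior extremum at exactly 0), expressed as a fraction of the beat
#' period from [curvature_autocorrelation()].
#'
#' @param kym [compute_kymographs()] result.
#' @param s_band length-2 arclength range (um); default 29.5-30.5 um.
#' @param lag_factor lag range scanned, in beat periods.
#' @return list with `lags` (s), `C`, `T_beat` (s), `phase_lag` (s),
#'   `phase_shift` (fraction of T).
#' @export
curvature_torsion_crosscorrelation <- function(kym,
                                               s_band = c(29.5, 30.5),
                                               lag_factor = 1.5) {
  ac <- curvature_autocorrelation(kym)
  T_beat <- ac$T_beat
  rows <- which(kym$s >= s_band[1] & kym$s <= s_band[2])
  rows <- rows[rowSums(kym$tau_valid[rows, , drop = FALSE]) >= 3]
  if (length(rows) == 0) stop("no valid (s, t) entries in s_band")
  nt <- ncol(kym$kappa)
  max_k <- min(nt - 3, round(lag_factor * T_beat / kym$dt))
  lags <- -max_k:max_k
  C <- matrix(NA_real_, length(rows), length(lags))
  for (r in seq_along(rows)) {
    x <- abs(kym$kappa[rows[r], ])
    x[!kym$valid[rows[r], ]] <- NA
    y <- kym$tau[rows[r], ]
    y[!kym$tau_valid[rows[r], ]] <- NA
    sx <- stats::sd(x, na.rm = TRUE)
    sy <- stats::sd(y, na.rm = TRUE)
    if (!is.finite(sx) || !is.finite(sy) || sx <= 0 || sy <= 0) {
      stop("zero variance in |kappa| or tau: correlation undefined")
    }
    C[r, ] <- vapply(lags, function(k) lagged_corr(x, y, k), numeric(1))
  }
  Cbar <- colMeans(C, na.rm = TRUE)
  phase_lag <- phase_extremum(lags * kym$dt, Cbar, T_beat)
  list(lags = lags * kym$dt, C = Cbar, T_beat = T_beat,
       phase_lag = phase_lag, phase_shift = abs(phase_lag) / T_beat)
}

# lag of the local extremum of |C| nearest zero, excluding the central
# (zero-lag) extremum: for wave signals extrema of |C| are at least a
# quarter period apart, so anything closer than T/8 to zero is treated as
# the central one
phase_extremum <- function(lags, C, T_beat) {
  a <- abs(C)
  n <- length(a)
  ext <- integer(0)
  for (k in 2:(n - 1)) {
    if (!any(is.na(a[(k - 1):(k + 1)])) &&
        a[k] >= a[k - 1] && a[k] >= a[k + 1]) {
      ext <- c(ext, k)
    }
  }
  ext <- ext[abs(lags[ext]) >= T_beat / 8]
  if (length(ext) == 0) stop("no interior extremum of |C| found")
  lags[ext[which.min(abs(lags[ext]))]]
}
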