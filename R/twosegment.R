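#' Two-segment non-planarity and torsion point
#'
#' Splits the flagellar shape at arclength s into two segments, computes
#' the non-planarity ratio Gamma of each from its gyration tensor, and
#' forms the length-weighted mean
#'   Gbar(s) = s * Gamma1 / L + (L - s) * Gamma2 / L.
#' The two-segment non-planarity is Gamma_ts = min over s of Gbar(s), and
#' the minimizing split s_ts is the torsion point: a shape made of two
#' nearly flat pieces joined with a twist has Gamma_ts close to zero with
#' s_ts at the junction. The scan runs over the resampled grid in
#' [min_segment, L - min_segment]; a straight segment (lambda2 = 0) gets
#' Gamma = 0 (it is perfectly planar) and is flagged. Ties are broken
#' toward the split nearest L/2.
#'
#' @param shape [flagellar_shape]
#' @param min_segment smallest allowed segment length (um); one plane-fit
#'   window by default.
#' @return object of class `two_segment_result`: list with `Gamma_ts`,
#'   `s_ts`, `scan` (data.frame s, Gbar, Gamma1, Gamma2), `Gamma1`,
#'   `Gamma2` at the optimum, `straight_flag`.
#' @export
two_segment_nonplanarity <- function(shape, min_segment = 5) {
  L <- arc_length(shape)
  if (L < 2 * min_segment) stop("shape shorter than 2 * min_segment")
  s <- shape$s
  idx <- which(s >= min_segment & s <= L - min_segment)
  seg_gamma <- function(pts) {
    if (nrow(pts) < 3) return(c(0, TRUE))
    f <- suppressWarnings(gyration_tensor(pts))
    if (is.na(f$Gamma)) c(0, TRUE) else c(f$Gamma, FALSE)
  }
  G1 <- numeric(length(idx)); G2 <- numeric(length(idx))
  flag <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    g1 <- seg_gamma(shape$points[1:i, , drop = FALSE])
    g2 <- seg_gamma(shape$points[i:nrow(shape$points), , drop = FALSE])
    G1[k] <- g1[1]; G2[k] <- g2[1]
    flag[k] <- g1[2] > 0 || g2[2] > 0
  }
  Gbar <- s[idx] * G1 / L + (L - s[idx]) * G2 / L
  best <- which(Gbar <= min(Gbar) + 1e-15)
  if (length(best) > 1) best <- best[which.min(abs(s[idx][best] - L / 2))]
  structure(list(Gamma_ts = Gbar[best], s_ts = s[idx][best],
                 scan = data.frame(s = s[idx], Gbar = Gbar,
                                   Gamma1 = G1, Gamma2 = G2),
                 Gamma1 = G1[best], Gamma2 = G2[best],
                 straight_flag = any(flag)),
            class = "two_segment_result")
}

#' @export
print.two_segment_result <- function(x, ...) {
  cat(sprintf("<two_segment_result> Gamma_ts = %.4f at s_ts = %.2f um\n",
              x$Gamma_ts, x$s_ts))
  invisible(x)
}
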