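# Small internal geometry helpers shared across modules.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' @noRd
#' Rodrigues rotation matrix for rotation vector w (angle = |w|, axis = w/|w|).
rotation_exp <- function(w) {
  th <- vnorm(w)
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# unwrap a phase series (radians), removing 2*pi jumps
unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

# centered running mean; returns NA at the trimmed ends
running_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

# signed angle from a to b about unit axis u (right-hand rule)
signed_angle <- function(a, b, u) {
  atan2(sum(cross3(a, b) * u), sum(a * b))
}

# orthonormal basis (u, v) of the plane perpendicular to unit vector t,
# with u x v = t
perp_basis <- function(t) {
  seed <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(seed - sum(seed * t) * t)
  v <- cross3(t, u)
  cbind(u, v)
}

is_orthonormal <- function(M, tol = 1e-6) {
  all(abs(crossprod(M) - diag(ncol(M))) < tol)
}
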