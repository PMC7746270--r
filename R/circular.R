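#' Wrap angles into [-180, 180)
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped to the half-open interval [-180, 180).
#' @export
wrap_deg <- function(x) ((x + 180) %% 360) - 180

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean of angles in degrees
#'
#' Argument of the resultant vector, optionally weighted. Returns NA for an
#' empty input or a (numerically) zero resultant.
#'
#' @param x Angles in degrees.
#' @param w Optional nonnegative weights, recycled to `length(x)`.
#' @return Mean direction in degrees in [-180, 180), or NA.
#' @export
circ_mean_deg <- function(x, w = NULL) {
  if (length(x) == 0L) return(NA_real_)
  r <- deg2rad(x)
  if (is.null(w)) w <- rep(1, length(x))
  s <- sum(w * sin(r))
  c_ <- sum(w * cos(r))
  if (sqrt(s^2 + c_^2) < 1e-12 * max(sum(abs(w)), 1)) return(NA_real_)
  wrap_deg(rad2deg(atan2(s, c_)))
}

#' Circular root-mean-square of angular errors
#'
#' Errors are wrapped to [-180, 180) before squaring, so a response 350°
#' away from the target counts as a 10° error.
#'
#' @param errors Angular errors in degrees.
#' @return RMS error in degrees.
#' @export
circ_rmse_deg <- function(errors) {
  if (length(errors) == 0L) return(NA_real_)
  sqrt(mean(wrap_deg(errors)^2))
}

# circular (wrapped) distance |a - b| in degrees, in [0, 180]
circ_dist_deg <- function(a, b) abs(wrap_deg(a - b))

# width (degrees) -> von Mises concentration, kappa = 1/sigma_rad^2
kappa_from_sigma_deg <- function(sigma_deg) {
  if (any(sigma_deg <= 0)) stop("sigma must be positive (degrees)")
  1 / deg2rad(sigma_deg)^2
}

#' von Mises density on angles measured in degrees
#'
#' Density of the circular normal distribution with mean direction `mu` and
#' width `sigma`, both in degrees. The width maps to the concentration as
#' kappa = 1/sigma_rad^2 (the Gaussian-approximation convention), and the
#' returned values are densities per radian, so the density integrates to 1
#' over the circle in radian measure.
#'
#' @param angle Angle(s) in degrees at which to evaluate.
#' @param mu Mean direction in degrees.
#' @param sigma Width in degrees (> 0).
#' @return Density values (per radian), same shape as `angle - mu`.
#' @export
vm_density <- function(angle, mu = 0, sigma = 20) {
  kappa <- kappa_from_sigma_deg(sigma)
  x <- deg2rad(angle - mu)
  # exponentially scaled Bessel keeps large kappa (narrow widths) finite
  exp(kappa * (cos(x) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution (degrees)
#'
#' Best-Fisher rejection sampler; exact for any concentration. Uses the
#' global RNG stream.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param sigma Width in degrees (> 0); kappa = 1/sigma_rad^2.
#' @return `n` angles in degrees in [-180, 180).
#' @export
rvm_deg <- function(n, mu = 0, sigma = 20) {
  if (n == 0L) return(numeric(0))
  kappa <- kappa_from_sigma_deg(sigma)
  if (kappa < 1e-8) return(wrap_deg(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    ccap <- kappa * (r - f)
    ok <- (ccap * (2 - ccap) - u2 > 0) | (log(ccap / u2) + 1 - ccap >= 0)
    k <- sum(ok)
    if (k > 0L) {
      theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_deg(mu + rad2deg(out))
}

#' Uniform angular grid over the circle
#'
#' @param step Grid spacing in degrees; must divide 360.
#' @return Vector of angles covering [-180, 180) half-open.
#' @export
angle_grid <- function(step = 1) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9)
    stop("grid step must be a positive divisor of 360")
  seq(-180, 180 - step, by = step)
}

# circulant index matrix: M[i, j] = position of wrap(grid_i - grid_j) in the
# grid vector; the grid starts at -180, so index 0 sits at position n/2 + 1
circulant_idx <- function(n) {
  i <- seq_len(n)
  ((outer(i, i, `-`) + n / 2) %% n) + 1L
}
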