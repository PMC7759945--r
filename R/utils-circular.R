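## Shared circular helpers. Internal convention: a clock time t (hours,
## 0-24) maps to the angle theta = 2*pi*t/24 on [0, 2*pi); midnight = 0.

#' Convert clock hours to angles on the 24-h circle
#'
#' @param hours numeric vector of clock times in decimal hours (0--24).
#' @return angles in radians on `[0, 2*pi)`.
#' @seealso [radians_to_hours()]
#' @export
#' @examples
#' hours_to_radians(c(0, 6, 12, 18))
hours_to_radians <- function(hours) {
  (hours %% 24) * pi / 12
}

#' Convert angles on the 24-h circle to clock hours
#'
#' @param theta numeric vector of angles in radians.
#' @return decimal hours on `[0, 24)`.
#' @export
radians_to_hours <- function(theta) {
  (theta %% (2 * pi)) * 12 / pi
}

## wrap into [0, 2*pi)
wrap_angle <- function(theta) theta %% (2 * pi)

## circular absolute deviation between two angles, in [0, pi]
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

## von Mises density, numerically stable for large kappa
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

## Best & Fisher rejection sampler for the von Mises distribution
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nacc <- sum(ok)
    if (nacc > 0) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nacc)] <- th
      got <- got + nacc
    }
  }
  wrap_angle(out + mu)
}

## mean resultant length
resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}

## circular mean direction on [0, 2*pi)
circ_mean <- function(theta) {
  wrap_angle(atan2(mean(sin(theta)), mean(cos(theta))))
}

## Maximum-likelihood von Mises concentration from the mean resultant
## length, via the standard series inversion of A1(kappa) = I1/I0
## (Fisher 1993); adequate well beyond the precision bandwidth
## selection needs.
a1inv <- function(R) {
  if (R < 0) R <- 0
  if (R >= 1) return(Inf)
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

## trapezoidal integral of periodic values on an equally spaced circular
## grid (the wrap-around makes the trapezoid rule a plain Riemann sum)
circ_trapz <- function(values, n_grid = length(values)) {
  sum(values) * 2 * pi / n_grid
}

## linear interpolation of a periodic function tabulated on the standard
## equally spaced grid
interp_circular <- function(grid, values, at) {
  g <- length(grid)
  step <- 2 * pi / g
  at <- wrap_angle(at)
  i0 <- floor(at / step)
  frac <- at / step - i0
  i0 <- as.integer(i0 %% g)
  i1 <- as.integer((i0 + 1L) %% g)
  values[i0 + 1L] * (1 - frac) + values[i1 + 1L] * frac
}

## equally spaced grid of G angles on [0, 2*pi)
density_grid <- function(n_grid = 128L) {
  seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
}

## round-half-up to `digits`, the convention used for reported percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
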