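#' Von Mises density (degrees)
#'
#' Density of the von Mises distribution with mean direction `mu_deg` and
#' concentration `kappa`, evaluated per radian at compass angles in
#' degrees. Uses exponentially scaled Bessel terms for numerical stability
#' at large `kappa`.
#'
#' @param theta_deg angles in degrees.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration, >= 0 (0 is the circular uniform).
#' @return density values per radian.
#' @export
dvonmises <- function(theta_deg, mu_deg, kappa) {
  stopifnot(kappa >= 0)
  d <- .deg2rad(theta_deg - mu_deg)
  exp(kappa * (cos(d) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution (degrees)
#'
#' Draws headings from the von Mises distribution by the Best-Fisher
#' wrapped-Cauchy rejection scheme; `kappa = 0` falls back to exact
#' uniform draws on the circle. Consumes the current PRNG stream (callers
#' seed via their own `seed` arguments).
#'
#' @param n number of draws.
#' @param mu_deg mean direction in compass degrees.
#' @param kappa concentration, >= 0.
#' @return numeric vector of `n` angles in \[0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(length(n) == 1, n >= 0, kappa >= 0)
  n <- as.integer(n)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(normalize_deg(stats::runif(n, 0, 360)))
  mu <- .deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(keep)) {
      ang <- mu + sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
      take <- sum(keep)
      out[(filled + 1L):(filled + take)] <- ang
      filled <- filled + take
    }
  }
  normalize_deg(.rad2deg(out))
}
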