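#' Mean vector of a circular sample
#'
#' Computes the mean resultant length `r` and mean direction `mu` of a set
#' of headings by vector summation of unit vectors (weighted, if the sample
#' carries weights). `r` ranges from 0 (uniform spread / perfect
#' cancellation) to 1 (all angles identical); in orientation work `r` is
#' often called "directedness". When `r` is numerically zero the
#' mean direction is undefined and reported as `NA`.
#'
#' @param sample an [angle_sample()] or a numeric vector of degrees.
#' @return an object of class `directional_summary`: list with `n` (sample
#'   size), `mu_deg` (mean direction in compass degrees, `NA` when
#'   undefined), `r` (mean resultant length), and `mu_defined` (logical).
#' @examples
#' mean_vector(c(0, 90))   # mu = 45, r = sqrt(0.5)
#' mean_vector(c(0, 90, 180, 270))  # r = 0, mu undefined
#' @export
mean_vector <- function(sample) {
  s <- as_angle_sample(sample)
  th <- .deg2rad(s$angles)
  w <- s$weights / sum(s$weights)
  e <- sum(w * sin(th))  # East component
  nn <- sum(w * cos(th)) # North component
  r <- sqrt(e^2 + nn^2)
  r <- min(r, 1)  # guard rounding just above 1 for degenerate samples
  defined <- r > 1e-12
  mu <- if (defined) normalize_deg(.rad2deg(atan2(e, nn))) else NA_real_
  structure(
    list(n = length(s$angles), mu_deg = mu, r = r, mu_defined = defined),
    class = "directional_summary"
  )
}

#' @export
print.directional_summary <- function(x, ...) {
  mu <- if (x$mu_defined) sprintf("%.1f deg", x$mu_deg) else "undefined"
  cat(sprintf("Mean vector: n = %d, r = %.4f, mu = %s\n", x$n, x$r, mu))
  invisible(x)
}

#' Rayleigh statistic Z = n r^2
#'
#' The Rayleigh test statistic for circular uniformity, computed from a
#' sample size and a mean resultant length. Large `Z` indicates departure
#' from uniformity (a directed sample).
#'
#' @param n sample size (>= 1).
#' @param r mean resultant length in \[0, 1\].
#' @return the statistic `Z = n * r^2`.
#' @examples
#' rayleigh_z(26, 0.301)
#' @export
rayleigh_z <- function(n, r) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1)
    stop("r must be a single value in [0, 1]", call. = FALSE)
  n * r^2
}

#' Rayleigh p-value (series approximation)
#'
#' Approximate p-value of the Rayleigh uniformity test, using the standard
#' series expansion in 1/n:
#' \deqn{p = e^{-Z}\left[1 + \frac{2Z - Z^2}{4n}
#'       - \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\right]}
#' clipped into \[0, 1\].
#'
#' @param z Rayleigh statistic, >= 0.
#' @param n sample size, >= 1.
#' @return approximate p-value in \[0, 1\].
#' @examples
#' rayleigh_p(rayleigh_z(26, 0.301), 26)
#' @export
rayleigh_p <- function(z, n) {
  if (!is.numeric(z) || length(z) != 1 || is.na(z) || z < 0)
    stop("z must be a single value >= 0", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    stop("n must be a single value >= 1", call. = FALSE)
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  min(max(p, 0), 1)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that a sample of headings is uniformly
#' distributed on the circle, against a unimodal directed alternative.
#' Composes [mean_vector()], [rayleigh_z()] and [rayleigh_p()].
#'
#' @param sample an [angle_sample()] or numeric vector of degrees. Weights,
#'   if present, are ignored for `n` but enter `r` through the weighted
#'   mean vector.
#' @return object of class `rayleigh_result`: list with `n`, `r`, `mu_deg`,
#'   `z`, `p`.
#' @examples
#' rayleigh_test(c(10, 20, 15, 350, 5, 12))
#' @export
rayleigh_test <- function(sample) {
  mv <- mean_vector(sample)
  z <- rayleigh_z(mv$n, mv$r)
  structure(
    list(n = mv$n, r = mv$r, mu_deg = mv$mu_deg, z = z, p = rayleigh_p(z, mv$n)),
    class = "rayleigh_result"
  )
}

#' @export
print.rayleigh_result <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, r = %.3f, Z = %.2f, p = %.3f\n",
              x$n, x$r, x$z, x$p))
  invisible(x)
}

#' Von Mises kernel density estimate on the circle
#'
#' Kernel density estimate of a circular sample using von Mises kernels of
#' concentration `bandwidth` (the convention of `density.circular`-style
#' estimators: larger bandwidth = narrower kernel):
#' \deqn{\hat f(\theta) = \frac{1}{n}\sum_i
#'   \frac{e^{\kappa\cos(\theta-\theta_i)}}{2\pi I_0(\kappa)}}
#' The density is per radian and integrates to 1 over the circle.
#' Computation uses exponentially scaled Bessel terms so large
#' concentrations (e.g. 200) do not overflow.
#'
#' @param sample an [angle_sample()] or numeric vector of degrees.
#' @param bandwidth von Mises kernel concentration, > 0. Default 40, the
#'   value conventionally used for worm-heading rose plots.
#' @param grid_size number of evenly spaced evaluation angles on \[0, 360),
#'   >= 16. Default 512.
#' @return object of class `circular_density`: list with `grid_deg`,
#'   `density` (per radian), `bandwidth`, `n`.
#' @examples
#' kde <- vonmises_kde(c(80, 90, 100, 95), bandwidth = 40)
#' @export
vonmises_kde <- function(sample, bandwidth = 40, grid_size = 512) {
  s <- as_angle_sample(sample)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || is.na(bandwidth) ||
      bandwidth <= 0)
    stop("bandwidth must be a single positive concentration", call. = FALSE)
  if (!is.numeric(grid_size) || length(grid_size) != 1 || grid_size < 16)
    stop("grid_size must be >= 16", call. = FALSE)
  grid_deg <- seq(0, 360, length.out = grid_size + 1)[seq_len(grid_size)]
  th <- .deg2rad(grid_deg)
  ti <- .deg2rad(s$angles)
  w <- s$weights / sum(s$weights)
  # exp(k*cos(d)) / (2*pi*I0(k)) = exp(k*(cos(d)-1)) / (2*pi*I0(k)*exp(-k))
  i0s <- besselI(bandwidth, 0, expon.scaled = TRUE)
  dens <- vapply(th, function(t0) {
    sum(w * exp(bandwidth * (cos(t0 - ti) - 1))) / (2 * pi * i0s)
  }, numeric(1))
  structure(
    list(grid_deg = grid_deg, density = dens, bandwidth = bandwidth,
         n = length(s$angles)),
    class = "circular_density"
  )
}

#' @export
print.circular_density <- function(x, ...) {
  cat(sprintf(
    "Von Mises KDE: n = %d, bandwidth = %g, %d grid points, peak %.4f/rad\n",
    x$n, x$bandwidth, length(x$grid_deg), max(x$density)))
  invisible(x)
}

#' Integrate a circular density over the full circle
#'
#' Trapezoidal integral (in radians, with periodic closure) of a
#' [vonmises_kde()] result; equals 1 for a proper density.
#'
#' @param density a `circular_density` object.
#' @return the integral, a scalar.
#' @export
circular_integral <- function(density) {
  stopifnot(inherits(density, "circular_density"))
  th <- .deg2rad(density$grid_deg)
  d <- density$density
  # close the circle: append first point at theta + 2*pi
  th <- c(th, th[1] + 2 * pi)
  d <- c(d, d[1])
  sum(diff(th) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Bootstrap confidence interval for the mean resultant length
#'
#' Percentile bootstrap CI for the directedness `r` of a circular sample:
#' resamples the angles with replacement `n_reps` times, computes `r` for
#' each resample, sorts the `n_reps` values ascending, and reads off the
#' ranks `ceiling(n_reps * (1 - conf_level) / 2)` and
#' `floor(n_reps * (1 + conf_level) / 2)` (1-based). With the defaults
#' (100,000 replicates, 95%) these are ranks 2,500 and 97,500.
#'
#' @param sample an [angle_sample()] or numeric vector of degrees; >= 2
#'   angles. Weights are ignored (each angle is one resampling unit).
#' @param n_reps number of bootstrap resamples, >= 1,000. Default 100,000.
#' @param conf_level confidence level in (0, 1). Default 0.95.
#' @param seed integer PRNG seed; the same seed reproduces the interval
#'   bit-for-bit. Default 1.
#' @return object of class `bootstrap_ci`: list with `lower`, `upper`,
#'   `n_reps`, `conf_level`, `seed`, `observed_r`.
#' @examples
#' bootstrap_r_ci(c(0, 45, 90, 300), n_reps = 2000, seed = 7)
#' @export
bootstrap_r_ci <- function(sample, n_reps = 1e5, conf_level = 0.95, seed = 1) {
  s <- as_angle_sample(sample)
  n <- length(s$angles)
  if (n < 2) stop("bootstrap CI undefined for fewer than 2 angles", call. = FALSE)
  if (!is.numeric(n_reps) || length(n_reps) != 1 || n_reps < 1000)
    stop("n_reps must be >= 1000", call. = FALSE)
  if (conf_level <= 0 || conf_level >= 1)
    stop("conf_level must be in (0, 1)", call. = FALSE)
  th <- .deg2rad(s$angles)
  sines <- sin(th); cosines <- cos(th)
  rs <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n_reps)
    e <- rowMeans(matrix(sines[idx], nrow = n_reps))
    nn <- rowMeans(matrix(cosines[idx], nrow = n_reps))
    sqrt(e^2 + nn^2)
  })
  rs <- sort(rs)
  lo_rank <- ceiling(n_reps * (1 - conf_level) / 2)
  hi_rank <- floor(n_reps * (1 + conf_level) / 2)
  structure(
    list(lower = rs[lo_rank], upper = rs[hi_rank], n_reps = as.integer(n_reps),
         conf_level = conf_level, seed = as.integer(seed),
         observed_r = mean_vector(s)$r),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("Bootstrap %g%% CI for r: [%.3f, %.3f] (%d resamples, seed %d)\n",
              100 * x$conf_level, x$lower, x$upper, x$n_reps, x$seed))
  invisible(x)
}

#' Does a bootstrap CI contain a reference directedness?
#'
#' The directedness comparison of the orientation assay: a magnetic
#' condition is called significantly more directed than the reference
#' (zero-field) group, at p < 0.05 for a 95% interval, when the reference
#' `r` falls below the lower confidence limit of the magnetic group's
#' bootstrapped `r`.
#'
#' @param ci a [bootstrap_r_ci()] result.
#' @param r_ref reference mean resultant length in \[0, 1\].
#' @return list with `contained` (logical), `r_ref`, and `verdict`, one of
#'   `"not significantly more directed"`, `"significantly more directed
#'   (p < 0.05)"` (reference below the interval), or `"less directed than
#'   reference"` (reference above the interval).
#' @export
ci_contains <- function(ci, r_ref) {
  stopifnot(inherits(ci, "bootstrap_ci"))
  if (!is.numeric(r_ref) || length(r_ref) != 1 || is.na(r_ref) ||
      r_ref < 0 || r_ref > 1)
    stop("r_ref must be a single value in [0, 1]", call. = FALSE)
  contained <- ci$lower <= r_ref && r_ref <= ci$upper
  verdict <- if (contained) {
    "not significantly more directed"
  } else if (r_ref < ci$lower) {
    "significantly more directed (p < 0.05)"
  } else {
    "less directed than reference"
  }
  list(contained = contained, r_ref = r_ref, verdict = verdict)
}
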