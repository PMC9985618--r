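# Truncated-Poisson draws (>= 1), via the inverse-CDF restricted to x >= 1.
.rtpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
}

#' Configuration for the hierarchical horizontal-field simulator
#'
#' The generative model mirrors the two statistical commitments of the
#' orientation assay: worms on a plate are non-independent (a shared
#' plate-level mean direction) and any directional preference sits at a
#' fixed compass bearing. Per plate `j`: a mean direction
#' `mu_j ~ vonMises(mu_population_deg, kappa_between)` (uniform when
#' `kappa_between = 0`, the null), then worm headings
#' `theta_ij ~ vonMises(mu_j, kappa_within)` (uniform when
#' `kappa_within = 0`).
#'
#' @param n_plates_per_condition plates per condition.
#' @param worms_per_plate mean of the truncated (>= 1) Poisson worm count
#'   per plate. Default 100, a typical 10-microliter worm aliquot.
#' @param mu_population_deg population preferred direction, degrees.
#'   Default 305, the bearing relative to the field lines reported for
#'   starved worms by the original magnetotaxis study.
#' @param kappa_between concentration of plate means around
#'   `mu_population_deg`; 0 = null (no population preference).
#' @param kappa_within concentration of worm headings around their plate
#'   mean; 0 = worms uniform. Default 1.
#' @param frac_filter_violations fraction of plates (per condition) whose
#'   metadata is made to violate exactly one randomly chosen inclusion
#'   rule. Default 0.
#' @param conditions subset of `"zero"`, `"field1"`, `"field2"` to
#'   generate. Default all three.
#' @param seed integer PRNG seed.
#' @return list of class `field_sim_config`.
#' @export
field_sim_config <- function(n_plates_per_condition, worms_per_plate = 100,
                             mu_population_deg = 305, kappa_between = 0,
                             kappa_within = 1, frac_filter_violations = 0,
                             conditions = FIELD_CONDITIONS, seed = 1) {
  stopifnot(n_plates_per_condition >= 1, worms_per_plate > 0,
            kappa_between >= 0, kappa_within >= 0,
            frac_filter_violations >= 0, frac_filter_violations <= 1,
            all(conditions %in% FIELD_CONDITIONS), length(conditions) >= 1)
  structure(
    list(n_plates_per_condition = as.integer(n_plates_per_condition),
         worms_per_plate = worms_per_plate,
         mu_population_deg = normalize_deg(mu_population_deg),
         kappa_between = kappa_between, kappa_within = kappa_within,
         frac_filter_violations = frac_filter_violations,
         conditions = conditions, seed = as.integer(seed)),
    class = "field_sim_config"
  )
}

# Metadata drawn uniformly inside the filter-pass region.
.passing_env <- function() {
  ts <- stats::runif(1, 21.5, 23)
  env_metadata(humidity_pct = stats::runif(1, 30, 49),
               temp_start_c = ts,
               temp_end_c = ts + stats::runif(1, -1.4, 1.4),
               duration_min = stats::runif(1, 56, 64))
}

# Metadata violating exactly one rule; all other rules stay satisfied.
# Returns the env plus, for the min_worms rule, a reduced worm count.
.violating_env <- function(rule) {
  env <- .passing_env()
  n_override <- NA_integer_
  if (rule == "min_worms") {
    n_override <- sample(5:29, 1)
  } else if (rule == "humidity") {
    env$humidity_pct <- stats::runif(1, 50, 90)
  } else if (rule == "max_temp") {
    ts <- stats::runif(1, 25.5, 28)
    env$temp_start_c <- ts
    env$temp_end_c <- ts + stats::runif(1, -1.4, 1.4)
  } else if (rule == "temp_delta") {
    ts <- stats::runif(1, 20, 22)
    env$temp_start_c <- ts
    env$temp_end_c <- ts + sample(c(-1, 1), 1) * stats::runif(1, 2, 2.8)
  } else if (rule == "duration") {
    env$duration_min <- if (stats::runif(1) < 0.5)
      stats::runif(1, 30, 54) else stats::runif(1, 66, 120)
  }
  list(env = env, n_override = n_override)
}

#' Simulate horizontal-field assay plates
#'
#' Draws plates from the hierarchical von Mises model of
#' [field_sim_config()], attaches environmental metadata sampled inside
#' the filter-pass region except for the designated violation fraction
#' (those plates violate exactly one randomly chosen rule), and returns
#' [field_plate()] objects that flow through the real readers, filters and
#' pipeline. Reproducible given the config seed.
#'
#' @param config a [field_sim_config()].
#' @return list of [field_plate()] objects; plate ids encode condition and
#'   index (e.g. `"zero_03"`).
#' @export
simulate_field_plates <- function(config) {
  stopifnot(inherits(config, "field_sim_config"))
  with_seed(config$seed, {
    plates <- list()
    for (cond in config$conditions) {
      np <- config$n_plates_per_condition
      n_viol <- round(config$frac_filter_violations * np)
      viol_idx <- if (n_viol > 0) sample.int(np, n_viol) else integer(0)
      for (j in seq_len(np)) {
        mu_j <- if (config$kappa_between == 0) stats::runif(1, 0, 360) else
          rvonmises(1, config$mu_population_deg, config$kappa_between)
        n_worms <- .rtpois(1, config$worms_per_plate)
        if (j %in% viol_idx) {
          v <- .violating_env(sample(FILTER_RULES, 1))
          env <- v$env
          if (!is.na(v$n_override)) n_worms <- v$n_override
        } else {
          env <- .passing_env()
        }
        headings <- if (config$kappa_within == 0)
          stats::runif(n_worms, 0, 360) else
            rvonmises(n_worms, mu_j, config$kappa_within)
        plates[[length(plates) + 1L]] <- field_plate(
          sprintf("%s_%02d", cond, j), cond, angle_sample(headings), env)
      }
    }
    plates
  })
}

#' Configuration for the two-target count simulator
#'
#' Emulates the magnet/chemotaxis plate assay: per plate a worm count
#' `N ~ truncated Poisson(lambda)` splits into target and control circles
#' by a beta-binomial draw, allowing intra-plate correlation
#' (overdispersion relative to a binomial split).
#'
#' @param n_plates number of plates.
#' @param worms_reaching_circles Poisson mean of worms reaching either
#'   circle per plate. Default 60.
#' @param p_target expected fraction choosing the target circle, in
#'   (0, 1); 0.5 = null (no preference).
#' @param overdispersion_rho intra-plate correlation in \[0, 1); 0 = pure
#'   binomial split.
#' @param condition label for the simulated plates, one of `"magnet"`,
#'   `"control"`, `"diacetyl"`. Default `"magnet"`.
#' @param seed integer PRNG seed.
#' @return list of class `magnet_sim_config`.
#' @export
magnet_sim_config <- function(n_plates, worms_reaching_circles = 60,
                              p_target = 0.5, overdispersion_rho = 0,
                              condition = "magnet", seed = 1) {
  stopifnot(n_plates >= 1, worms_reaching_circles > 0,
            p_target > 0, p_target < 1,
            overdispersion_rho >= 0, overdispersion_rho < 1)
  condition <- match.arg(condition, MAGNET_CONDITIONS)
  structure(
    list(n_plates = as.integer(n_plates),
         worms_reaching_circles = worms_reaching_circles,
         p_target = p_target, overdispersion_rho = overdispersion_rho,
         condition = condition, seed = as.integer(seed)),
    class = "magnet_sim_config"
  )
}

#' Simulate two-target assay plates
#'
#' @param config a [magnet_sim_config()].
#' @return list of [magnet_plate()] objects.
#' @export
simulate_magnet_plates <- function(config) {
  stopifnot(inherits(config, "magnet_sim_config"))
  with_seed(config$seed, {
    n <- config$n_plates
    sizes <- .rtpois(n, config$worms_reaching_circles)
    rho <- config$overdispersion_rho
    p <- if (rho == 0) rep(config$p_target, n) else {
      a <- config$p_target * (1 - rho) / rho
      b <- (1 - config$p_target) * (1 - rho) / rho
      stats::rbeta(n, a, b)
    }
    t_counts <- stats::rbinom(n, sizes, p)
    lapply(seq_len(n), function(i)
      magnet_plate(sprintf("%s_%03d", config$condition, i), config$condition,
                   t_counts[i], sizes[i] - t_counts[i]))
  })
}

#' Simulate exit angles from a biased correlated random walk
#'
#' A mechanistic generator for the plate geometry of the orientation
#' assay: each worm starts at the plate center with a uniform random
#' heading, updates its heading each step by a wrapped-normal turn and a
#' vector blend toward `target_deg` with weight `bias_weight`, and records
#' its compass exit angle where the path first crosses `plate_radius`.
#' `bias_weight = 0` is an unbiased correlated random walk whose exit
#' angles are statistically uniform; `bias_weight = 1` with vanishing turn
#' spread is ballistic toward the target.
#'
#' @param n_worms number of worms.
#' @param bias_weight blend weight toward the target in \[0, 1\].
#' @param target_deg target compass bearing, degrees.
#' @param step_deg_sd wrapped-normal turning-angle SD per step, degrees.
#'   Default 30.
#' @param plate_radius plate radius in step lengths. Default 45
#'   (a 9 cm-diameter scoring rim walked in ~1 mm steps).
#' @param seed integer PRNG seed.
#' @param max_steps cap on steps per worm; worms still inside the plate
#'   after `max_steps` are dropped with a warning. Default 10000.
#' @return an [angle_sample()] of exit angles (degrees).
#' @export
simulate_biased_walk <- function(n_worms, bias_weight, target_deg,
                                 step_deg_sd = 30, plate_radius = 45,
                                 seed = 1, max_steps = 10000) {
  stopifnot(n_worms >= 1, bias_weight >= 0, bias_weight <= 1,
            step_deg_sd >= 0, plate_radius > 0, max_steps >= 1)
  tgt <- .deg2rad(normalize_deg(target_deg))
  sd_rad <- .deg2rad(step_deg_sd)
  w <- bias_weight
  exits <- with_seed(seed, {
    h <- stats::runif(n_worms, 0, 2 * pi)
    x <- numeric(n_worms); y <- numeric(n_worms)
    exit <- rep(NA_real_, n_worms)
    active <- seq_len(n_worms)
    for (step in seq_len(max_steps)) {
      turn <- stats::rnorm(length(active), 0, sd_rad)
      hr <- h[active] + turn
      e <- (1 - w) * sin(hr) + w * sin(tgt)
      nn <- (1 - w) * cos(hr) + w * cos(tgt)
      h[active] <- atan2(e, nn)
      x[active] <- x[active] + sin(h[active])
      y[active] <- y[active] + cos(h[active])
      out <- x[active]^2 + y[active]^2 >= plate_radius^2
      if (any(out)) {
        done <- active[out]
        exit[done] <- atan2(x[done], y[done])
        active <- active[!out]
      }
      if (length(active) == 0) break
    }
    if (length(active) > 0)
      warning(sprintf("%d worm(s) did not reach the rim within %d steps; dropped",
                      length(active), max_steps))
    if (all(is.na(exit)))
      stop("no worm reached the rim; increase max_steps or shrink plate_radius",
           call. = FALSE)
    exit[!is.na(exit)]
  })
  angle_sample(normalize_deg(.rad2deg(exits)))
}
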