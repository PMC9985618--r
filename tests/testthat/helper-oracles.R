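# Independent oracles and hand-built fixtures shared across test files.
# These deliberately avoid the package's own code paths where they are
# used to check them.

# Mean resultant length by direct complex summation (oracle for r).
oracle_r <- function(deg) {
  z <- exp(1i * deg * pi / 180)
  Mod(mean(z))
}

# Exhaustive bootstrap distribution of r for a tiny sample: every one of
# the n^n equally likely resamples, enumerated via expand.grid.
exhaustive_boot_r <- function(deg) {
  n <- length(deg)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  apply(idx, 1, function(ii) oracle_r(deg[ii]))
}

# Quantile of the exhaustive distribution under the sorted-rank rule used
# for a Monte-Carlo CI: smallest value whose CDF reaches p (type-1).
exhaustive_quantile <- function(vals, p) {
  unname(stats::quantile(vals, p, type = 1))
}

# Exhaustive null distribution of the Mann-Whitney U statistic by direct
# pair counting over every allocation of the pooled values to group 1.
oracle_u_distribution <- function(pooled, n1) {
  combos <- utils::combn(length(pooled), n1)
  apply(combos, 2, function(ii) {
    x <- pooled[ii]; y <- pooled[-ii]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
}

# Eight-plate filter fixture with hand-set metadata covering every rule
# and its boundary: 29 worms, humidity exactly 50.0%, max temperature
# exactly 25.0 C, drift exactly 2.0 C, durations 55 and 65 min.
make_filter_fixture <- function() {
  mk <- function(id, cond, n_worms, hum, t0, t1, dur) {
    field_plate(id, cond,
                angle_sample(seq(0, 359, length.out = n_worms)),
                env_metadata(hum, t0, t1, dur))
  }
  list(
    kept = list(
      mk("ok_a", "zero",   30, 49.9, 23.0, 24.8, 60),
      mk("ok_b", "field1", 45, 35.0, 21.0, 21.5, 55),
      mk("ok_c", "field2", 60, 40.0, 24.0, 25.0, 65)
    ),
    excluded = list(
      few_worms = mk("few_worms", "zero",  29, 40.0, 22.0, 22.5, 60),
      humid     = mk("humid",     "zero",  30, 50.0, 22.0, 22.5, 60),
      hot       = mk("hot",       "field1", 31, 40.0, 24.5, 25.1, 60),
      drift     = mk("drift",     "field1", 40, 40.0, 21.0, 23.0, 60),
      multi     = mk("multi",     "field2", 25, 55.0, 26.0, 28.0, 54)
    ),
    expected_rules = list(
      few_worms = "min_worms",
      humid     = "humidity",
      hot       = "max_temp",
      drift     = "temp_delta",
      multi     = c("min_worms", "humidity", "max_temp", "temp_delta",
                    "duration")
    )
  )
}

extdata <- function(f) system.file("extdata", f, package = "magtaxis")
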