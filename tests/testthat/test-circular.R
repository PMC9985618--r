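test_that("angle samples normalize and validate their inputs", {
  expect_equal(angle_sample(c(370, -15, 360))$angles, c(10, 345, 0))
  expect_error(angle_sample(numeric(0)), "empty")
  expect_error(angle_sample(c(0, NA)), "NA")
  expect_error(angle_sample(c(0, 90), weights = c(1, -1)), "nonnegative")
  expect_error(angle_sample(c(0, 90), weights = c(0, 0)), "positive sum")
  expect_error(angle_sample(c(0, 90), weights = 1), "same length")
})

test_that("mean vector reproduces closed-form cases", {
  mv <- mean_vector(c(0, 90))
  expect_equal(mv$mu_deg, 45)
  expect_equal(mv$r, sqrt(0.5))
  expect_equal(mv$n, 2)

  mv <- mean_vector(c(30, 30, 30))
  expect_equal(mv$mu_deg, 30)
  expect_equal(mv$r, 1)

  mv <- mean_vector(c(0, 90, 180, 270))
  expect_equal(mv$r, 0, tolerance = 1e-12)
  expect_false(mv$mu_defined)
  expect_true(is.na(mv$mu_deg))
})

test_that("weighted mean vector matches replication of angles", {
  w <- mean_vector(angle_sample(c(10, 200, 355), weights = c(3, 1, 2)))
  rep_ <- mean_vector(c(rep(10, 3), 200, rep(355, 2)))
  expect_equal(w$r, rep_$r)
  expect_equal(w$mu_deg, rep_$mu_deg)
})

test_that("r is rotation invariant and mu rotates along", {
  set.seed(41)
  for (i in 1:20) {
    ang <- runif(15, 0, 360)
    delta <- runif(1, -720, 720)
    a <- mean_vector(ang)
    b <- mean_vector(ang + delta)
    expect_equal(b$r, a$r, tolerance = 1e-12)
    diff <- (b$mu_deg - a$mu_deg - delta) %% 360
    expect_lt(min(diff, 360 - diff), 1e-8)
  }
})

test_that("rayleigh_z is n r^2 with validation", {
  expect_equal(rayleigh_z(26, 0.301), 26 * 0.301^2)
  expect_equal(rayleigh_z(5, 0), 0)
  expect_error(rayleigh_z(0, 0.5), "n must")
  expect_error(rayleigh_z(10, 1.2), "r must")
})

test_that("rayleigh_p matches the series, limits and monotonicity", {
  expect_equal(rayleigh_p(0, 10), 1)
  # hand-evaluated series at Z = 2, n = 20
  z <- 2; n <- 20
  manual <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                         (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  expect_equal(rayleigh_p(z, n), manual)
  # monotone decreasing in Z for fixed n over [0, 0.9 n]
  for (n in c(8, 26, 100)) {
    zs <- seq(0, 0.9 * n, length.out = 200)
    ps <- vapply(zs, rayleigh_p, numeric(1), n = n)
    expect_true(all(diff(ps) <= 1e-12))
  }
  expect_error(rayleigh_p(-1, 10), "z must")
})

test_that("rayleigh test composes consistently and handles degenerate samples", {
  rt <- rayleigh_test(rep(77, 10))
  expect_equal(rt$r, 1)
  expect_equal(rt$z, 10)
  expect_equal(rt$p, rayleigh_p(10, 10))

  rt <- rayleigh_test(c(0, 120, 240))
  expect_lt(rt$r, 1e-12)
  expect_equal(rt$p, 1, tolerance = 1e-10)

  set.seed(13)
  ang <- runif(40, 0, 360)
  rt <- rayleigh_test(ang)
  expect_equal(rt$r, oracle_r(ang), tolerance = 1e-12)
  expect_equal(rt$z, rt$n * rt$r^2, tolerance = 1e-12)
})

test_that("analytic Rayleigh p calibrates against uniform simulation", {
  # empirical rejection at alpha = 0.05 within +-1% of 5%, n in {10, 26, 100}
  set.seed(271)
  for (n in c(10, 26, 100)) {
    th <- matrix(runif(20000 * n, 0, 2 * pi), nrow = 20000)
    r <- sqrt(rowMeans(sin(th))^2 + rowMeans(cos(th))^2)
    p <- vapply(n * r^2, rayleigh_p, numeric(1), n = n)
    expect_gt(mean(p < 0.05), 0.04)
    expect_lt(mean(p < 0.05), 0.06)
  }
})

test_that("von Mises KDE integrates to one and matches the closed form", {
  for (bw in c(0.1, 1, 40, 200)) {
    for (n in c(1, 5, 100)) {
      set.seed(n * 7 + round(bw * 10))
      kde <- vonmises_kde(runif(n, 0, 360), bandwidth = bw, grid_size = 256)
      expect_equal(circular_integral(kde), 1, tolerance = 1e-6)
      expect_true(all(kde$density >= 0))
    }
  }
  # single-point sample equals the von Mises density exactly
  kde <- vonmises_kde(123.4, bandwidth = 40, grid_size = 128)
  expect_equal(kde$density, dvonmises(kde$grid_deg, 123.4, 40),
               tolerance = 1e-12)
  expect_equal(kde$grid_deg[which.max(kde$density)],
               kde$grid_deg[which.min(abs(kde$grid_deg - 123.4))])
  # vanishing bandwidth approaches the circular uniform density
  kde0 <- vonmises_kde(c(10, 200), bandwidth = 1e-8)
  expect_equal(kde0$density, rep(1 / (2 * pi), length(kde0$grid_deg)),
               tolerance = 1e-6)
  expect_error(vonmises_kde(c(1, 2), bandwidth = 0), "bandwidth")
  expect_error(vonmises_kde(c(1, 2), grid_size = 4), "grid_size")
})

test_that("bootstrap CI is reproducible, ordered and degenerate-exact", {
  ang <- c(0, 45, 90, 300, 200)
  a <- bootstrap_r_ci(ang, n_reps = 2000, seed = 7)
  b <- bootstrap_r_ci(ang, n_reps = 2000, seed = 7)
  expect_identical(a$lower, b$lower)
  expect_identical(a$upper, b$upper)
  expect_lte(a$lower, a$upper)
  expect_gte(a$lower, 0)
  expect_lte(a$upper, 1)

  same <- bootstrap_r_ci(rep(42, 5), n_reps = 1000, seed = 1)
  expect_equal(same$lower, 1)
  expect_equal(same$upper, 1)

  expect_error(bootstrap_r_ci(10), "fewer than 2")
  expect_error(bootstrap_r_ci(c(1, 2), n_reps = 10), "n_reps")
})

test_that("bootstrap CI endpoints converge to exhaustive enumeration", {
  for (ang in list(c(0, 90), c(0, 90, 180), c(10, 100, 250, 340))) {
    vals <- exhaustive_boot_r(ang)
    ci <- bootstrap_r_ci(ang, n_reps = 1e5, seed = 17)
    expect_equal(ci$lower, exhaustive_quantile(vals, 0.025), tolerance = 0.02)
    expect_equal(ci$upper, exhaustive_quantile(vals, 0.975), tolerance = 0.02)
    # Monte-Carlo endpoints never leave the exhaustive support
    expect_gte(ci$lower, min(vals) - 1e-12)
    expect_lte(ci$upper, max(vals) + 1e-12)
  }
})

test_that("containment verdicts follow the directedness comparison rule", {
  ci <- structure(list(lower = 0.128, upper = 0.547, n_reps = 1e5L,
                       conf_level = 0.95, seed = 1L, observed_r = 0.304),
                  class = "bootstrap_ci")
  v <- ci_contains(ci, 0.301)
  expect_true(v$contained)
  expect_equal(v$verdict, "not significantly more directed")

  ci$lower <- 0.40; ci$upper <- 0.60
  v <- ci_contains(ci, 0.301)
  expect_false(v$contained)
  expect_equal(v$verdict, "significantly more directed (p < 0.05)")

  v <- ci_contains(ci, 0.9)
  expect_equal(v$verdict, "less directed than reference")
  expect_error(ci_contains(ci, 1.5), "r_ref")
})

test_that("von Mises sampler hits its distributional targets", {
  set.seed(91)
  x <- rvonmises(4000, 305, 2)
  mv <- mean_vector(x)
  # A(2) = I1(2)/I0(2) ~ 0.6978; sampling error ~ 0.01 at n = 4000
  expect_equal(mv$r, besselI(2, 1) / besselI(2, 0), tolerance = 0.03)
  dmu <- abs(((mv$mu_deg - 305) + 180) %% 360 - 180)
  expect_lt(dmu, 5)
  expect_true(all(x >= 0 & x < 360))
  u <- rvonmises(1000, 0, 0)
  expect_gt(rayleigh_test(u)$p, 0.01)
})
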