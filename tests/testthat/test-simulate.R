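test_that("field simulator is seed-reproducible and respects degenerate limits", {
  cfg <- field_sim_config(3, worms_per_plate = 40, kappa_between = 1,
                          kappa_within = 2, seed = 5)
  a <- simulate_field_plates(cfg)
  b <- simulate_field_plates(cfg)
  expect_identical(a, b)
  expect_length(a, 9)  # 3 plates x 3 conditions

  # huge concentrations collapse every heading onto the population direction
  tight <- simulate_field_plates(field_sim_config(
    2, worms_per_plate = 30, mu_population_deg = 305,
    kappa_between = 1e6, kappa_within = 1e6, conditions = "zero", seed = 9))
  for (p in tight) {
    d <- abs(((p$headings$angles - 305) + 180) %% 360 - 180)
    expect_lt(max(d), 0.5)
  }
})

test_that("simulated metadata passes the filters except designated violators", {
  clean <- simulate_field_plates(field_sim_config(
    10, worms_per_plate = 60, frac_filter_violations = 0,
    conditions = "zero", seed = 21))
  res <- filter_plates(clean)
  expect_length(res$kept, 10)

  half <- simulate_field_plates(field_sim_config(
    10, worms_per_plate = 60, frac_filter_violations = 0.5,
    conditions = "zero", seed = 22))
  res <- filter_plates(half)
  expect_length(res$kept, 5)
  # injected violators break exactly one rule each
  expect_equal(as.integer(table(res$exclusions$plate_id)), rep(1L, 5))
})

test_that("magnet simulator matches its binomial targets", {
  cfg <- magnet_sim_config(10000, worms_reaching_circles = 60,
                           p_target = 0.5, overdispersion_rho = 0, seed = 31)
  plates <- simulate_magnet_plates(cfg)
  pis <- vapply(plates, `[[`, numeric(1), "pi")
  expect_lt(abs(mean(pis)), 0.01)  # law of large numbers at the null

  near1 <- simulate_magnet_plates(magnet_sim_config(
    50, p_target = 1 - 1e-6, seed = 32))
  expect_true(all(vapply(near1, `[[`, numeric(1), "pi") > 0.99))

  expect_identical(simulate_magnet_plates(cfg)[[1]],
                   simulate_magnet_plates(cfg)[[1]])

  # overdispersion inflates the between-plate PI variance
  od <- simulate_magnet_plates(magnet_sim_config(
    4000, p_target = 0.5, overdispersion_rho = 0.2, seed = 33))
  expect_gt(var(vapply(od, `[[`, numeric(1), "pi")), var(pis) * 2)
})

test_that("plate-level directedness increases with within-plate concentration", {
  set.seed(55)
  grid <- c(0, 0.5, 1, 2, 4)
  mean_r <- vapply(grid, function(kw) {
    mean(replicate(200, mean_vector(
      if (kw == 0) runif(60, 0, 360) else rvonmises(60, 100, kw))$r))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("null simulators give uniform second-order p-values", {
  set.seed(101)
  ps <- replicate(600, {
    plates <- simulate_field_plates(field_sim_config(
      12, worms_per_plate = 40, kappa_between = 0, kappa_within = 1,
      conditions = "zero", seed = sample.int(2^30, 1)))
    mus <- vapply(plates, function(p) mean_vector(p$headings)$mu_deg,
                  numeric(1))
    rayleigh_test(mus)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  set.seed(102)
  pm <- replicate(500, {
    a <- simulate_magnet_plates(magnet_sim_config(
      23, p_target = 0.5, seed = sample.int(2^30, 1)))
    b <- simulate_magnet_plates(magnet_sim_config(
      22, p_target = 0.5, condition = "control", seed = sample.int(2^30, 1)))
    magnet_assay_analysis(c(a, b))$comparisons$magnet_vs_control$p
  })
  expect_gt(suppressWarnings(ks.test(pm, "punif"))$p.value, 0.01)
})

test_that("biased walk covers ballistic, uniform and reproducible regimes", {
  ball <- simulate_biased_walk(50, bias_weight = 1, target_deg = 210,
                               step_deg_sd = 1e-9, seed = 61)
  expect_length(ball, 50)
  d <- abs(((ball$angles - 210) + 180) %% 360 - 180)
  expect_lt(max(d), 1.5)  # discrete steps overshoot the rim slightly

  expect_identical(
    simulate_biased_walk(20, 0.3, 90, seed = 62),
    simulate_biased_walk(20, 0.3, 90, seed = 62))

  # unbiased walks give statistically uniform exit angles
  nonsig <- vapply(1:100, function(i) {
    ex <- simulate_biased_walk(1000, bias_weight = 0, target_deg = 0,
                               step_deg_sd = 30, seed = 7000 + i)
    rayleigh_test(ex)$p > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.93)

  # a strong bias is detected
  biased <- simulate_biased_walk(200, bias_weight = 0.5, target_deg = 135,
                                 seed = 63)
  rt <- rayleigh_test(biased)
  expect_lt(rt$p, 1e-6)
  dmu <- abs(((rt$mu_deg - 135) + 180) %% 360 - 180)
  expect_lt(dmu, 15)

  # walks that cannot terminate in time are dropped with a warning
  expect_warning(
    out <- simulate_biased_walk(30, 0, 0, step_deg_sd = 180,
                                plate_radius = 6, seed = 64, max_steps = 40),
    "did not reach")
  expect_lt(length(out), 30)
  expect_error(
    suppressWarnings(simulate_biased_walk(5, 0, 0, step_deg_sd = 180,
                                          plate_radius = 500, seed = 64,
                                          max_steps = 50)),
    "no worm reached")
})
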