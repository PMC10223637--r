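test_that("sampling respects medians, GSDs, determinism and bounds", {
  nominal <- list(v_milk = 0.5, cl = 5)

  # GSD = 1 (or absent) leaves everyone at nominal
  s0 <- sample_population(population_spec(n = 20, seed = 1,
                                          gsd_map = c(v_milk = 1)), nominal)
  expect_true(all(s0$v_milk == 0.5) && all(s0$cl == 5))

  # identical seed, identical draws
  sp <- population_spec(n = 100, seed = 42)
  expect_identical(sample_population(sp, nominal),
                   sample_population(sp, nominal))

  # law of large numbers: recovered geometric statistics within 1%
  big <- sample_population(population_spec(n = 2e4, seed = 7), nominal)
  gsd_hat <- exp(sd(log(big$v_milk)))
  expect_equal(gsd_hat, 1.16, tolerance = 0.01)
  expect_equal(median(big$v_milk), 0.5, tolerance = 0.01)

  # truncation bounds honoured
  sb <- sample_population(
    population_spec(n = 5000, seed = 3, gsd_map = c(v_milk = 1.5),
                    bounds = list(v_milk = c(0.3, 0.9))), nominal)
  expect_true(all(sb$v_milk >= 0.3 & sb$v_milk <= 0.9))

  expect_error(sample_population(population_spec(gsd_map = c(nope = 1.2)),
                                 nominal), "nominal parameter set")
})

test_that("population bands are monotone and collapse without variability", {
  cfg <- load_fixture_drug("caffeine")
  m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
  reg <- regimen(100, 8, 3)

  pop <- population_simulate(population_spec(n = 40, seed = 11), m, reg,
                             t_end = 24, dt_out = 0.5)
  b <- pop$bands
  expect_true(all(b$plasma_p5 <= b$plasma_p50 + 1e-12) &&
              all(b$plasma_p50 <= b$plasma_p95 + 1e-12))
  expect_true(all(b$milk_p5 <= b$milk_p50 + 1e-12) &&
              all(b$milk_p50 <= b$milk_p95 + 1e-12))

  # milk-volume-only variability: milk bands widen while plasma is nearly
  # untouched (milk volume feeds back on plasma only through the small
  # reuptake flux, so the plasma spread is second-order)
  plasma_spread <- max(b$plasma_p95 - b$plasma_p5) / max(b$plasma_p50)
  milk_spread <- max(b$milk_p95 - b$milk_p5) / max(b$milk_p50)
  expect_lt(plasma_spread, 0.01)
  expect_gt(milk_spread, 0.1)
  expect_gt(milk_spread / plasma_spread, 10)

  # n = 1 without variability reproduces the deterministic run
  one <- population_simulate(population_spec(n = 1, seed = 2,
                                             gsd_map = c(v_milk = 1)),
                             m, reg, t_end = 24, dt_out = 0.5)
  det <- simulate_regimen(m, reg, t_end = 24, dt_out = 0.5)
  expect_equal(one$bands$milk_p50, det$c_milk, tolerance = 1e-12)
  expect_equal(one$bands$plasma_p50, det$c_plasma, tolerance = 1e-12)
})

test_that("population runs are seed-reproducible and median-preserving", {
  cfg <- load_fixture_drug("zidovudine")
  m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
  reg <- regimen(300, 12, 2)
  sp <- population_spec(n = 30, seed = 99)
  p1 <- population_simulate(sp, m, reg, t_end = 24, dt_out = 1)
  p2 <- population_simulate(sp, m, reg, t_end = 24, dt_out = 1)
  expect_identical(p1$bands, p2$bands)

  # the log-normal median equals the nominal value, so the p50 band tracks
  # the deterministic profile (Monte-Carlo error at modest n)
  p3 <- population_simulate(population_spec(n = 400, seed = 5), m, reg,
                            t_end = 24, dt_out = 1)
  det <- simulate_regimen(m, reg, t_end = 24, dt_out = 1)
  sel <- det$c_milk > 0.05 * max(det$c_milk)
  relerr <- abs(p3$bands$milk_p50[sel] - det$c_milk[sel]) / det$c_milk[sel]
  expect_lt(median(relerr), 0.05)
})

test_that("about 90% of individual milk AUCs fall inside the 5-95 AUC band", {
  cfg <- load_fixture_drug("caffeine")
  m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
  pop <- population_simulate(population_spec(n = 500, seed = 21), m,
                             regimen(100, 8, 2), t_end = 16, dt_out = 1)
  auc <- pop$individual_metrics$auc_milk
  qs <- quantile(auc, c(0.05, 0.95), type = 7)
  frac <- mean(auc >= qs[1] & auc <= qs[2])
  expect_gt(frac, 0.86)
  expect_lt(frac, 0.94)
})
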