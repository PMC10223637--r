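# frozen expected values computed by direct evaluation of the regression
# formulas (independent of the package code paths)

test_that("compute_clsec matches direct evaluation", {
  expect_equal(compute_clsec(0, 100, 0), 663.7431, tolerance = 1e-6)
  expect_equal(compute_clsec(58.44, 194.2, 0), 824.015, tolerance = 1e-6)
  expect_equal(compute_clsec(58.44, 194.2, -0.07), 846.0872, tolerance = 1e-6)
})

test_that("compute_clre reproduces the published reuptake clearances", {
  expect_equal(compute_clre(0, 0), 620.869, tolerance = 1e-6)
  # the seven drugs whose published values are consistent with their
  # tabulated LogP/HBD, to 0.1%
  consistent <- list(
    list(logp = 0.87, hbd = 4, clre = 263.47),   # amoxicillin
    list(logp = -0.07, hbd = 0, clre = 603.21),  # caffeine
    list(logp = -0.60, hbd = 1, clre = 357.77),  # levetiracetam
    list(logp = -1.43, hbd = 3, clre = 138.37),  # metformin
    list(logp = 1.93, hbd = 1, clre = 1015.01),  # nevirapine
    list(logp = 2.75, hbd = 1, clre = 1423.15),  # valproic acid
    list(logp = 0.05, hbd = 2, clre = 345.10))   # zidovudine
  for (d in consistent)
    expect_equal(compute_clre(d$logp, d$hbd), d$clre, tolerance = 1e-3)
})

test_that("compute_pmilk, compute_fu_skim, compute_fu_milk_total match direct evaluation", {
  expect_equal(compute_pmilk(0), 0.1318257, tolerance = 1e-6)
  expect_equal(compute_pmilk(-0.07), 0.1070779, tolerance = 1e-6)
  expect_equal(compute_pmilk(1.93), 40.7099, tolerance = 1e-6)

  expect_equal(compute_fu_skim(1.0), 0.962971, tolerance = 1e-6)
  expect_equal(compute_fu_skim(0.023), 0.827548, tolerance = 1e-6)
  expect_lt(compute_fu_skim(1e-10), 1e-3)  # vanishes with plasma binding

  expect_equal(compute_fu_milk_total(1, 0), 1.04712, tolerance = 1e-5)
  expect_equal(compute_fu_milk_total(0.9568, 0.1071), 0.9970704, tolerance = 1e-6)
  expect_equal(compute_fu_milk_total(0.827, 490.9), 0.04301949, tolerance = 1e-6)
  expect_error(compute_fu_milk_total(0, 1), "fu_skim")
})

test_that("steady-state M/P closed form reproduces published ratios", {
  expect_equal(mp_ratio_steady_state(0.85, 46.90, 1.0055, 263.47), 0.15,
               tolerance = 0.01)
  expect_equal(mp_ratio_steady_state(0.90, 445.38, 1.0055, 357.77), 1.11,
               tolerance = 0.01)
  expect_equal(mp_ratio_steady_state(0.5, 100, 0.5, 100), 1.0)
})

test_that("derive_milk_transfer chains the full pipeline", {
  # effective-input fixtures reproduce the published clearances end to end
  met <- load_fixture_drug("metformin", effective = TRUE)$drug
  tr <- derive_milk_transfer(met)
  expect_equal(tr$clre, 138.37, tolerance = 1e-3)
  expect_equal(tr$clsec, 21.73, tolerance = 1e-3)
  expect_equal(tr$mp_ss, 0.16, tolerance = 0.03)

  tdf <- load_fixture_drug("tenofovir", effective = TRUE)$drug
  expect_equal(derive_milk_transfer(tdf)$clre, 129.00, tolerance = 1e-3)

  # neutral probe: composition of the intercept-only cases
  probe <- drug_physchem("probe", mw = 100, logp = 0, hbd = 0, hba = 0,
                         psa = 0, fu_plasma = 1)
  tr <- derive_milk_transfer(probe)
  expect_equal(tr$clre, 620.869, tolerance = 1e-6)
  expect_equal(tr$mp_ss, (1 * tr$clsec) / (tr$fu_milk_total * tr$clre),
               tolerance = 1e-12)
})

test_that("monotonicity properties of the transfer regressions", {
  logps <- seq(-3, 6, by = 0.5)
  expect_true(all(diff(vapply(logps, compute_clre, numeric(1), hbd = 2)) > 0))
  expect_true(all(diff(vapply(0:6, function(h) compute_clre(1, h), numeric(1))) < 0))
  psas <- seq(0, 200, by = 20)
  expect_true(all(diff(vapply(psas, compute_clsec, numeric(1),
                              mw = 300, logd74 = 1)) < 0))
  mws <- seq(100, 600, by = 50)
  expect_true(all(diff(vapply(mws, function(m) compute_clsec(50, m, 1),
                              numeric(1))) > 0))
  lds <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(vapply(lds, function(l) compute_clsec(50, 300, l),
                              numeric(1))) < 0))
  fus <- seq(0.01, 1, by = 0.05)
  expect_true(all(diff(vapply(fus, compute_fu_skim, numeric(1))) > 0))
  pms <- c(0, 0.1, 1, 10, 100, 1000)
  expect_true(all(diff(vapply(pms, function(p) compute_fu_milk_total(0.9, p),
                              numeric(1))) < 0))
})

test_that("milk_transfer_table emits one row per drug with all quantities", {
  drugs <- lapply(c("caffeine", "nevirapine"), function(n)
    load_fixture_drug(n)$drug)
  tab <- milk_transfer_table(drugs)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("name", "logd74", "logd72", "clsec_ml_h", "clre_ml_h",
                      "pmilk", "fu_skim", "fu_milk_total", "mp_ss"))
  expect_equal(tab$clre_ml_h[tab$name == "caffeine"], 603.21, tolerance = 1e-3)
})
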