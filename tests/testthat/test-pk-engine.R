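test_that("model structure follows the compartment layout", {
  drug <- drug_physchem("probe", mw = 200, logp = 0, fu_plasma = 0.85,
                        psa = 50)
  tr <- flat_transfer(clsec = 100, fu_plasma = 0.85)

  m_iv <- build_model(drug, maternal_pk_params(cl = 5, vc = 20), tr)
  expect_equal(n_states(m_iv), 2)  # central + milk

  pk_oral2 <- maternal_pk_params(cl = 5, vc = 20, ka = 1,
                                 peripherals = list(list(v = 50, q = 10),
                                                    list(v = 30, q = 5)))
  m <- build_model(drug, pk_oral2, tr)
  expect_equal(n_states(m), 2 + 2 + 1)  # + 2 peripherals + depot

  m_br <- build_model(drug, pk_oral2, tr, include_breast = TRUE)
  expect_equal(n_states(m_br), 6)

  # milk inflow term is Cplasma * fu_plasma * CLsec (amounts: entry * Vc)
  expect_equal(m$A["milk", "central"] * 20, 0.85 * 100 / 1000)
  # milk has no efflux other than reuptake
  expect_equal(m$A["milk", "milk"], -1 * (200 / 1000) / 0.5)

  expect_error(simulate_regimen(m_iv, regimen(100, 8, 3, route = "oral")),
               "absorption compartment")
})

test_that("IV bolus without milk transfer matches the mono-exponential closed form", {
  m <- one_cpt_model(cl = 5, vc = 20, clsec = 0, clre = 0)
  sim <- simulate_regimen(m, regimen(100, 24, 1, route = "iv_bolus"),
                          t_end = 24, dt_out = 0.25)
  k <- 5 / 20
  expect_equal(sim$c_plasma, (100 / 20) * exp(-k * sim$times), tolerance = 1e-10)
  expect_true(all(sim$c_milk == 0))  # decoupled milk stays empty
})

test_that("zero-dose regimen produces all-zero trajectories", {
  m <- one_cpt_model(ka = 1, clsec = 100, clre = 200)
  sim <- simulate_regimen(m, regimen(0, 8, 3, route = "oral"), t_end = 24)
  expect_true(all(sim$c_plasma == 0) && all(sim$c_milk == 0))
})

test_that("engine trajectories match an independent RK4 oracle", {
  cfg <- load_fixture_drug("caffeine")
  m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
  boluses <- list(list(time = 0, state = 1, amount = 100),
                  list(time = 8, state = 1, amount = 100))
  orc <- rk4_simulate(m$A, boluses, t_end = 16, dt = 0.002, record_every = 500)
  sim <- simulate_regimen(m, regimen(100, 8, 2, route = "oral"), t_end = 16,
                          dt_out = 1)
  idx <- match(orc$times, sim$times)
  expect_false(anyNA(idx))
  for (s in seq_len(n_states(m))) {
    scale <- max(orc$X[, s], 1e-9)
    expect_lt(max(abs(sim$amounts[idx, s] - orc$X[, s])) / scale, 1e-6)
  }
})

test_that("mass balance and non-negativity hold across random models and routes", {
  set.seed(202)
  spec <- synthetic_drug_spec(seed = 303)
  drugs <- generate_synthetic_drugs(spec, 8)
  routes <- c("oral", "iv_bolus", "iv_infusion")
  for (i in seq_along(drugs)) {
    m <- build_model(drugs[[i]], random_pk(), derive_milk_transfer(drugs[[i]]))
    route <- routes[(i %% 3) + 1]
    reg <- regimen(200, 12, 3, route = route,
                   duration = if (route == "iv_infusion") 1.5 else 0)
    sim <- simulate_regimen(m, reg, t_end = 48, dt_out = 0.5)
    expect_lt(mass_balance_error(sim), 1e-4)
    expect_true(all(sim$amounts >= 0))
  }
})

test_that("steady state: accumulation ratio matches superposition closed form", {
  # 1-compartment IV bolus (milk decoupled): R = 1 / (1 - exp(-k * tau))
  m <- one_cpt_model(cl = 2, vc = 20)
  tau <- 12
  k <- 2 / 20
  ss <- simulate_to_steady_state(m, dose = 100, tau = tau, route = "iv_bolus",
                                 rel_tol = 1e-5)
  expect_true(attr(ss, "converged"))
  expect_equal(attr(ss, "accumulation_ratio"), 1 / (1 - exp(-k * tau)),
               tolerance = 1e-3)

  # tau much longer than 5 half-lives: no accumulation, fast convergence
  m2 <- one_cpt_model(cl = 10, vc = 10)  # t1/2 0.7 h
  ss2 <- simulate_to_steady_state(m2, dose = 100, tau = 24, route = "iv_bolus")
  expect_lte(attr(ss2, "n_cycles"), 3)
  expect_equal(attr(ss2, "accumulation_ratio"), 1, tolerance = 1e-3)
})

test_that("linearity: doubling the dose doubles Cmax and AUC at steady state", {
  cfg <- load_fixture_drug("levetiracetam")
  m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
  ss1 <- simulate_to_steady_state(m, dose = 750, tau = 12)
  ss2 <- simulate_to_steady_state(m, dose = 1500, tau = 12)
  expect_equal(max(ss2$c_plasma) / max(ss1$c_plasma), 2, tolerance = 1e-9)
  expect_equal(attr(ss2, "auc_plasma") / attr(ss1, "auc_plasma"), 2,
               tolerance = 1e-9)
  expect_equal(attr(ss2, "auc_milk") / attr(ss1, "auc_milk"), 2,
               tolerance = 1e-9)
})

test_that("milk peak lags the plasma peak under oral dosing", {
  for (nm in c("caffeine", "nevirapine", "zidovudine")) {
    cfg <- load_fixture_drug(nm)
    m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
    ss <- simulate_to_steady_state(m, dose = 100, tau = 12)
    t_plasma <- ss$times[which.max(ss$c_plasma)]
    t_milk <- ss$times[which.max(ss$c_milk)]
    expect_gte(t_milk, t_plasma)
  }
})

test_that("simulated steady-state M/P matches the closed form (single case)", {
  cfg <- load_fixture_drug("caffeine")
  tr <- derive_milk_transfer(cfg$drug)
  m <- build_model(cfg$drug, cfg$pk, tr)
  ss <- simulate_to_steady_state(m, dose = 100, tau = 8)
  mp_sim <- attr(ss, "auc_milk") / attr(ss, "auc_plasma")
  expect_equal(mp_sim, tr$mp_ss, tolerance = 0.01)
})

test_that("direct periodic steady state agrees with cycle iteration", {
  cfg <- load_fixture_drug("levetiracetam")
  m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
  iter <- simulate_to_steady_state(m, 1500, 12, rel_tol = 1e-6)
  direct <- steady_state_interval(m, 1500, 12)
  expect_equal(attr(direct, "auc_plasma"), attr(iter, "auc_plasma"),
               tolerance = 1e-4)
  expect_equal(attr(direct, "auc_milk"), attr(iter, "auc_milk"),
               tolerance = 1e-4)
  expect_equal(direct$c_plasma, iter$c_plasma, tolerance = 1e-3)
})

test_that("interval AUC is stable under grid refinement", {
  cfg <- load_fixture_drug("nevirapine")
  m <- build_model(cfg$drug, cfg$pk, derive_milk_transfer(cfg$drug))
  ss1 <- simulate_to_steady_state(m, 200, 12, n_per_interval = 100)
  ss2 <- simulate_to_steady_state(m, 200, 12, n_per_interval = 200)
  expect_equal(attr(ss1, "auc_plasma"), attr(ss2, "auc_plasma"),
               tolerance = 1e-3)
  expect_equal(attr(ss1, "auc_milk"), attr(ss2, "auc_milk"),
               tolerance = 1e-3)
})

test_that("non-convergence within the cycle cap is flagged, partial result returned", {
  m <- one_cpt_model(cl = 0.05, vc = 100, clsec = 1e-6, clre = 1e-6) # t1/2 58 days
  expect_warning(
    ss <- simulate_to_steady_state(m, 100, 12, route = "iv_bolus",
                                   max_cycles = 5),
    "not reached")
  expect_false(attr(ss, "converged"))
  expect_false(ss$ss_flag)
  expect_equal(attr(ss, "n_cycles"), 5)
})

test_that("terminal slope estimation behaves like textbook NCA", {
  t <- seq(0, 24, by = 2)
  c0 <- 10
  conc <- c0 * exp(-0.2 * t)
  expect_equal(nca_terminal_slope(t, conc, 5), 0.2, tolerance = 1e-10)
  # dense sampling so the trapezoid part meets the closed-form integral
  td <- seq(0, 40, by = 0.1)
  expect_equal(nca_auc_inf(td, c0 * exp(-0.2 * td), 4), c0 / 0.2,
               tolerance = 1e-3)
  expect_error(nca_terminal_slope(t, rep(1, length(t))), "not declining")
  expect_error(nca_terminal_slope(t, c0 * exp(0.1 * t)), "not declining")
  expect_error(nca_terminal_slope(c(0, 1, 2), c(1, 0, 0)), "positive concentrations")
})

test_that("infusion route delivers the dose over the stated duration", {
  m <- one_cpt_model(cl = 5, vc = 20, clsec = 1e-6, clre = 1e-6)
  sim <- simulate_regimen(m, regimen(100, 24, 1, route = "iv_infusion",
                                     duration = 2), t_end = 12, dt_out = 0.1)
  # during the infusion the administered amount ramps linearly
  expect_equal(sim$cumulative_dosed[sim$times == 1], 50)
  expect_equal(sim$cumulative_dosed[sim$times == 2], 100)
  expect_lt(mass_balance_error(sim), 1e-10)
  # peak at end of infusion for a 1-compartment model
  expect_equal(sim$times[which.max(sim$c_plasma)], 2)
})
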