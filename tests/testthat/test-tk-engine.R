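test_that("kinetic constants follow their closed forms", {
  expect_equal(elimination_constant(840), log(2) / 840)
  expect_equal(elimination_constant(840), 8.2518e-4, tolerance = 1e-4)
  expect_equal(elimination_constant(1679), 4.1285e-4, tolerance = 1e-4)
  expect_equal(elimination_constant(log(2)), 1.0)
  expect_error(elimination_constant(0), "positive")

  expect_equal(clearance_rate(0.17, 840), 1.4028e-4, tolerance = 1e-4)
  expect_equal(clearance_rate(1, log(2)), 1.0)
  expect_equal(clearance_rate(0.17, 1679), 7.018e-5, tolerance = 1e-4)
  expect_error(clearance_rate(-0.1, 840), "positive")
})

test_that("steady-state, placental and breastmilk relations are the stated products", {
  # 95th-percentile lifetime intake at the breastfed guidance concentration
  expect_equal(steady_state_serum(47e-3 * 0.035e-3, clearance_rate(0.17, 840)),
               0.011727, tolerance = 1e-4)
  expect_equal(steady_state_serum(0, 1), 0)
  expect_error(steady_state_serum(1, 0), "positive")

  expect_equal(birth_serum(2.3, 0.87), 2.001)
  expect_equal(birth_serum(5.2, 0.87), 4.524)
  expect_equal(birth_serum(7.3, 1), 7.3)

  expect_equal(breastmilk_concentration(2.3, 0.052), 0.1196)
  expect_equal(breastmilk_concentration(0.13, 0.052), 0.00676)
  expect_equal(breastmilk_concentration(4, 0), 0)
})

test_that("daily update adds intake before eliminating and halves over a half-life", {
  k <- log(2) / 840
  expect_equal(daily_update(0.1, 0, 0.17, 3.4, k), 0.1 * exp(-k))
  expect_equal(daily_update(0.1, 0, 0.17, 3.4, k), 0.0999175, tolerance = 1e-6)
  # unit mass pulse into a unit distribution volume
  expect_equal(daily_update(0, 0.17 * 3.4, 0.17, 3.4, k), exp(-k))
  # n zero-intake days decay to s * e^-nk; 840 of them halve the serum
  s <- 0.4
  for (i in 1:840) s <- daily_update(s, 0, 0.2, 10, k)
  expect_equal(s, 0.2, tolerance = 1e-12)
  expect_error(daily_update(0.1, 0, 0, 3.4, k), "positive")
})

test_that("zero exposure gives an identically zero system", {
  sim <- simulate_lifetime(rme_breastfed(), 0, n_days = 600)
  expect_equal(max(abs(sim$infant_serum)), 0)
  expect_equal(max(abs(sim$maternal_serum)), 0)
  expect_equal(nrow(sim), 600)
})

test_that("the system is exactly linear in the water concentration", {
  base <- simulate_lifetime(rme_breastfed(), 0.035, n_days = 3000)
  for (mult in c(2, 4, 32)) {
    scaled <- simulate_lifetime(rme_breastfed(), 0.035 * mult, n_days = 3000)
    expect_equal(scaled$infant_serum, mult * base$infant_serum,
                 tolerance = 1e-12)
    expect_equal(scaled$maternal_serum, mult * base$maternal_serum,
                 tolerance = 1e-12)
  }
})

test_that("daily mass balance holds between infant gain and maternal debit", {
  sim <- simulate_lifetime(rme_breastfed(), 0.1, n_days = 800)
  lact <- which(!is.na(sim$milk_conc) & sim$day > 0)
  chem <- attr(sim, "chem")
  lib <- attr(sim, "library")
  bw_m <- lib$maternal_bw[["upper"]]
  k <- chem$k

  # reconstruct each day's maternal update from the reported milk dose; the
  # infant's milk-borne mass gain must be exactly the mass removed from her
  prev_m <- sim$maternal_serum[lact - 1]
  dose_m <- prev_m * chem$clearance * bw_m
  expected_m <- (prev_m + (dose_m - sim$milk_dose_mg[lact]) /
                   (chem$vd * bw_m)) * exp(-k)
  expect_equal(sim$maternal_serum[lact], expected_m, tolerance = 1e-9)

  # and the infant side books the same mass before its own elimination
  prev_i <- sim$infant_serum[lact - 1]
  expected_i <- (prev_i +
                   (sim$milk_dose_mg[lact] + sim$water_dose_mg[lact]) /
                   (sim$vd_eff[lact] * sim$bw_kg[lact])) * exp(-k)
  expect_equal(sim$infant_serum[lact], expected_i, tolerance = 1e-9)

  # milk concentration is the start-of-day maternal serum times the factor
  expect_equal(sim$milk_conc[lact], prev_m * chem$milk_tf, tolerance = 1e-12)
})

test_that("simulated plateau matches the closed-form steady state within 0.5%", {
  lib <- constant_library(water_mL_kg = 42, bw_kg = 70)
  sim <- simulate_lifetime(rme_formula(), 1, library = lib)
  closed <- steady_state_serum(42e-3 * 1e-3, clearance_rate(0.17, 840))
  expect_equal(sim$infant_serum[nrow(sim)], closed, tolerance = 0.005)

  # full age-structured run also plateaus at the adult closed form
  full <- simulate_lifetime(rme_formula(), 1)
  expect_equal(full$infant_serum[nrow(full)],
               adult_steady_state(rme_formula(), 1), tolerance = 0.005)
})

test_that("a breastfed scenario with zero duration reproduces the formula-fed series", {
  b0 <- exposure_scenario("breastfed", tiers = c(intake = "upper"),
                          breastfeeding_months = 0)
  f <- exposure_scenario("formula", tiers = c(intake = "upper"))
  sb <- simulate_lifetime(b0, 0.1, n_days = 2000)
  sf <- simulate_lifetime(f, 0.1, n_days = 2000)
  expect_equal(sb$infant_serum, sf$infant_serum)
  expect_equal(sb$maternal_serum, sf$maternal_serum)
})

test_that("infant serum is monotone in both transfer factors", {
  lib <- default_parameter_library()
  days <- c(30, 183, 365, 1000)
  runs <- lapply(c(0, 0.03, 0.052, 0.12, 0.3), function(tf) {
    l <- lib
    l$milk_tf[["upper"]] <- tf
    sc <- exposure_scenario("breastfed",
                            tiers = c(intake = "upper", duration = "upper",
                                      transfer = "upper"))
    l$placental_tf[["upper"]] <- 0.87
    l$half_life[["upper"]] <- 840
    simulate_lifetime(sc, 0.1, library = l, n_days = 1100)$infant_serum
  })
  for (i in seq_along(runs)[-1]) {
    expect_true(all(runs[[i]] >= runs[[i - 1]] - 1e-15))
  }
  runs_p <- lapply(c(0, 0.5, 0.87, 1.69), function(ptf) {
    l <- lib
    l$placental_tf[["central"]] <- ptf
    simulate_lifetime(rme_breastfed(), 0.1, library = l,
                      n_days = 1100)$infant_serum
  })
  for (i in seq_along(runs_p)[-1]) {
    expect_true(all(runs_p[[i]] >= runs_p[[i - 1]] - 1e-15))
  }
})

test_that("the lactation coupling agrees with an independent row-by-row oracle", {
  n <- 250
  orc <- oracle_lactation(5.2, tier = "upper", n_days = n)
  sc <- exposure_scenario("breastfed", tiers = c(intake = "upper"),
                          breastfeeding_months = 12)
  sim <- simulate_lifetime(sc, 0, n_days = n, maternal_serum_ug_L = 5.2)
  expect_equal(sim$infant_serum, orc$infant, tolerance = 1e-9)
  expect_equal(sim$maternal_serum, orc$maternal, tolerance = 1e-9)
  expect_equal(sim$milk_conc, orc$milk, tolerance = 1e-9)

  # central tier, and initialisation from a measured birth serum
  orc2 <- oracle_lactation(2.3, tier = "central", n_days = n,
                           birth_ug_L = 1.4)
  sc2 <- exposure_scenario("breastfed", tiers = c(intake = "central"),
                           breastfeeding_months = 12)
  sim2 <- simulate_lifetime(sc2, 0, n_days = n, maternal_serum_ug_L = 2.3,
                            infant_birth_serum_ug_L = 1.4)
  expect_equal(sim2$infant_serum, orc2$infant, tolerance = 1e-9)
  expect_equal(sim2$maternal_serum, orc2$maternal, tolerance = 1e-9)
})

test_that("simulator rejects invalid inputs", {
  expect_error(simulate_lifetime(rme_breastfed(), -1), "non-negative")
  expect_error(simulate_lifetime(rme_breastfed(), 1, n_days = 1), "at least")
})
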