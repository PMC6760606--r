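test_that("infant-serum prediction is degree-1 homogeneous in maternal serum", {
  p1 <- predict_infant_serum(1, "upper", 6)
  expect_equal(predict_infant_serum(3.7, "upper", 6), 3.7 * p1,
               tolerance = 1e-10)
  expect_equal(predict_infant_serum(0, "upper", 6), 0)
})

test_that("breastfed accumulation outweighs decay at the published intake rates", {
  for (tier in c("central", "upper")) {
    birth <- 2.3 * 0.87
    at6 <- predict_infant_serum(2.3, tier, 6)
    expect_gt(at6, birth)
  }
})

test_that("maternal serum declines over lactation through milk offloading", {
  sc <- exposure_scenario("breastfed", tiers = c(intake = "upper"),
                          breastfeeding_months = 12)
  sim <- simulate_lifetime(sc, 0, n_days = 400, maternal_serum_ug_L = 5)
  expect_lt(sim$maternal_serum[366], sim$maternal_serum[1])
  expect_lt(milk_decline(sim, 6), 100)
  expect_gt(milk_decline(sim, 6), 0)
})

test_that("prediction from birth serum reduces to pure decay without milk transfer", {
  lib <- default_parameter_library()
  lib$milk_tf[["central"]] <- 0
  k <- log(2) / 840
  d <- round(6 * DAYS_PER_MONTH)
  expect_equal(predict_from_birth_serum(2, "upper", 6, library = lib),
               2 * exp(-k * d), tolerance = 1e-9)
  expect_equal(predict_from_birth_serum(0, "upper", 6), 0)
})

test_that("prediction from birth serum matches the independent oracle", {
  n <- round(7 * DAYS_PER_MONTH) + 2
  orc <- oracle_lactation(2 / 0.87, tier = "upper", n_days = n,
                          birth_ug_L = 2)
  d <- round(6 * DAYS_PER_MONTH)
  expect_equal(predict_from_birth_serum(2, "upper", 6),
               orc$infant[orc$day == d] * 1e3, tolerance = 1e-9)
})

test_that("relative change reports fold differences between two ages", {
  sc <- exposure_scenario("breastfed", tiers = c(intake = "upper"),
                          breastfeeding_months = 0)
  sim <- simulate_lifetime(sc, 0, n_days = 900, maternal_serum_ug_L = 4)
  # no intake after birth: pure decay, halving over one half-life
  expect_equal(relative_change(sim, 0, 840), 0.5, tolerance = 1e-9)
  expect_equal(relative_change(sim, 50, 50 + 840), 0.5, tolerance = 1e-9)
  expect_error(relative_change(sim, 500, 500), "earlier")
  expect_error(relative_change(sim, 100, 5000), "within the horizon")
})

test_that("milk decline requires a lactating simulation", {
  sim <- simulate_lifetime(rme_formula(), 0.1, n_days = 400)
  expect_error(milk_decline(sim, 6), "no lactation")
  lib <- default_parameter_library()
  lib$milk_tf[["central"]] <- 0
  sc <- exposure_scenario("breastfed", breastfeeding_months = 12)
  sim0 <- simulate_lifetime(sc, 0, n_days = 400, maternal_serum_ug_L = 3,
                            library = lib)
  expect_error(milk_decline(sim0, 6), "zero")
})

test_that("regression agreement recovers perfect and affine relationships", {
  tab <- generate_fixture(10, noise_cv = 0, seed = 7)
  preds <- tab$measured_serum
  # an exact fit legitimately trips summary.lm's perfect-fit warning
  r <- suppressWarnings(regression_agreement(tab, preds))
  expect_equal(r$r_squared, 1.0)
  expect_equal(r$mean_relative_bias, 0)

  r2 <- suppressWarnings(regression_agreement(tab, 1.1 * preds))
  expect_equal(r2$r_squared, 1.0)
  expect_equal(r2$mean_relative_bias, 0.1)
  expect_error(regression_agreement(tab[1:2, ], preds[1:2]), "3 pairs")
  expect_error(regression_agreement(tab, preds[-1]), "row count")
})

test_that("fixture generator is seed-deterministic and noise-calibrated", {
  a <- generate_fixture(14, noise_cv = 0.3, seed = 11)
  b <- generate_fixture(14, noise_cv = 0.3, seed = 11)
  expect_identical(a, b)
  c <- generate_fixture(14, noise_cv = 0.3, seed = 12)
  expect_false(identical(a$measured_serum, c$measured_serum))

  # noiseless fixture is exactly the model prediction scaled by maternal serum
  clean <- generate_fixture(6, noise_cv = 0, seed = 3)
  preds <- clean$birth_serum / 0.87 * predict_infant_serum(1, "upper", 6)
  expect_equal(clean$measured_serum, preds, tolerance = 1e-10)
})

test_that("regression on noisy fixtures recovers strong but imperfect agreement", {
  unit <- predict_infant_serum(1, "upper", 6)
  r2s <- vapply(1:40, function(seed) {
    tab <- generate_fixture(14, noise_cv = 0.3, seed = seed)
    preds <- tab$birth_serum / 0.87 * unit
    regression_agreement(tab, preds)$r_squared
  }, numeric(1))
  expect_gt(stats::median(r2s), 0.5)
  expect_lt(stats::median(r2s), 0.99)
  expect_true(all(r2s > 0.2) && all(r2s < 1))
})

test_that("paired serum tables round-trip through CSV and are validated", {
  tab <- generate_fixture(8, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_serum(tab, path)
  back <- read_paired_serum(path)
  expect_equal(back$measured_serum, tab$measured_serum, tolerance = 1e-12)
  expect_s3_class(back, "paired_serum")

  bad <- tab
  names(bad)[2] <- "wrong"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_paired_serum(path2), "missing column")
})
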