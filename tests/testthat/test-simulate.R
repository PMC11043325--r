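test_that("inventory generator honours the configured distribution and is deterministic", {
  cfg0 <- simulation_config(seed = 3, n_reservoirs = 0)
  expect_equal(nrow(simulate_inventory(cfg0)), 0)

  cfg <- simulation_config(seed = 5, n_reservoirs = 300)
  expect_equal(simulate_inventory(cfg), simulate_inventory(cfg))
  sv1 <- suppressWarnings(simulate_surveys(simulate_inventory(cfg), cfg))
  sv2 <- suppressWarnings(simulate_surveys(simulate_inventory(cfg), cfg))
  expect_equal(sv1, sv2)

  # Monte-Carlo bound: mean of ln(volume) within 3 sd / sqrt(n) of the
  # configured mean (ecoregion shifts and injected rows switched off so
  # the draw is the configured distribution itself)
  cfg_mc <- simulation_config(seed = 17, n_reservoirs = 10000,
                              ln_volume_mean = 10, ln_volume_sd = 2,
                              ecoregion_sd = 0, prop_duplicate = 0,
                              prop_natural_lake = 0, prop_missing_area = 0)
  inv <- simulate_inventory(cfg_mc)
  expect_equal(nrow(inv), 10000)
  expect_lt(abs(mean(log(inv$storage_volume_m3)) - 10), 3 * 2 / sqrt(10000))
  expect_true(all(inv$surface_area_ha > 0 | is.na(inv$surface_area_ha)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulation_config(gamma_shape = 0), "gamma_shape")
  expect_error(simulation_config(recovery_constant = 0.5), "recovery_constant")
  expect_error(simulation_config(ln_volume_sd = -1), "standard deviations")
  expect_error(simulation_config(n_reservoirs = -2), "n_reservoirs")
})

test_that("survey densities follow the generator's closed form", {
  # no noise, flat age and year effects: every true density is exp(b0)
  # and every recorded raw density is exp(b0) / recovery constant
  cfg <- zero_noise_config(seed = 21, n_reservoirs = 80)
  inv <- simulate_inventory(cfg)
  sv <- suppressWarnings(simulate_surveys(inv, cfg))
  expect_gt(nrow(sv), 0)
  expect_equal(sv$true_density, rep(150, nrow(sv)))
  expect_equal(sv$raw_density_kg_ha, rep(150 / 1.773056, nrow(sv)))

  # recovery-bias round trip is exact
  cfg2 <- simulation_config(seed = 22, n_reservoirs = 100)
  sv2 <- suppressWarnings(simulate_surveys(simulate_inventory(cfg2), cfg2))
  expect_equal(apply_recovery_correction(sv2$raw_density_kg_ha,
                                         cfg2$recovery_constant),
               sv2$true_density, tolerance = 1e-12)

  # survey_fraction = 0 gives an empty table
  cfg3 <- simulation_config(seed = 23, n_reservoirs = 50, survey_fraction = 0)
  expect_equal(nrow(simulate_surveys(simulate_inventory(cfg3), cfg3)), 0)

  # Gamma CV = 1/sqrt(shape): a huge shape makes densities near-constant
  cfg4 <- zero_noise_config(seed = 24, n_reservoirs = 200,
                            survey_fraction = 1, gamma_shape = 1e6)
  sv4 <- suppressWarnings(simulate_surveys(simulate_inventory(cfg4), cfg4))
  expect_lt(stats::sd(sv4$true_density) / mean(sv4$true_density), 0.01)
})

test_that("ground-truth summary is additive and exact", {
  cfg <- zero_noise_config(seed = 31, n_reservoirs = 10)
  inv <- tibble::tibble(
    reservoir_id = c("A", "B"), name = c("A", "B"), state = c("TX", "TX"),
    latitude = c(31, 32), longitude = c(-95, -96),
    year_completed = c(1993L, 1993L),
    storage_volume_m3 = c(1e6, 2e6), max_discharge_m3s = c(1, 2),
    surface_area_ha = c(100, 200), natural_lake = FALSE,
    true_class = "small_low", true_area_ha = c(100, 200))
  tr <- true_summary(inv, cfg)
  expect_equal(tr$density_kg_ha, rep(150, 2))
  expect_equal(attr(tr, "total_kg"), 300 * 150)

  empty <- inv[0, , drop = FALSE]
  expect_equal(attr(true_summary(empty, cfg), "total_kg"), 0)

  # expectation mode includes the log-normal random-intercept factor
  cfg_u <- zero_noise_config(seed = 31, n_reservoirs = 10)
  cfg_u$random_intercept_sd <- 0.5
  tr_u <- true_summary(inv, cfg_u, expectation = TRUE)
  expect_equal(tr_u$density_kg_ha, rep(150 * exp(0.125), 2))
})

test_that("simulated bundle writes and reloads as plain text", {
  cfg <- simulation_config(seed = 41, n_reservoirs = 60)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, cfg)
  expect_true(all(file.exists(file.path(
    dir, c("inventory.csv", "surveys.csv", "validation.csv", "truth.csv",
           "ecoregions.geojson", "config.yml")))))
  inv <- load_inventory(file.path(dir, "inventory.csv"))
  expect_equal(nrow(inv), nrow(sim$inventory))
  expect_equal(inv$storage_volume_m3, sim$inventory$storage_volume_m3)
  layer <- read_ecoregions(file.path(dir, "ecoregions.geojson"))
  expect_equal(layer$labels, sim$ecoregions$labels)
  expect_equal(layer$rings[[1]], sim$ecoregions$rings[[1]],
               ignore_attr = TRUE)
})
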