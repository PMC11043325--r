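test_that("model preparation applies the exclusion rules with an itemized report", {
  # classes at the minimum-size boundary: 4 rows dropped, 5 rows kept
  tab <- make_model_table(
    density = rep(100, 9), age = rep(10, 9), year = rep(1960L, 9),
    class_label = c(rep("A", 5), rep("B", 4)),
    reservoir_id = sprintf("R%d", 1:9))
  prep <- prepare_model_table(tab, tibble::tibble(
    reservoir_id = tab$reservoir_id, schema_id = 3L,
    class_label = tab$class_label))
  expect_setequal(unique(prep$table$class_label), "A")
  expect_equal(prep$report$small_class, 4L)

  # 12 rows: one zero density, one missing age, one 3-row class -> 7 left
  tab2 <- make_model_table(
    density = c(0, rep(100, 11)),
    age = c(10, NA, rep(10, 10)), year = rep(1960L, 12),
    class_label = c("A", "A", rep("A", 5), rep("C", 3), rep("A", 2)),
    reservoir_id = sprintf("R%d", 1:12))
  prep2 <- prepare_model_table(tab2, tibble::tibble(
    reservoir_id = tab2$reservoir_id, schema_id = 3L,
    class_label = tab2$class_label))
  expect_equal(nrow(prep2$table), 7)
  expect_equal(prep2$report$nonpositive_density, 1L)
  expect_equal(prep2$report$missing_age, 1L)
  expect_equal(prep2$report$small_class, 3L)

  # no exclusions: table passes through unchanged
  prep3 <- prepare_model_table(tab[1:5, ], tibble::tibble(
    reservoir_id = tab$reservoir_id[1:5], schema_id = 3L,
    class_label = tab$class_label[1:5]))
  expect_equal(nrow(prep3$table), 5)
  expect_true(all(unlist(prep3$report) == 0))

  # everything excluded is an estimation error
  tab4 <- tab[1:3, ]
  tab4$corrected_density <- 0
  expect_error(prepare_model_table(tab4, tibble::tibble(
    reservoir_id = tab4$reservoir_id, schema_id = 1L,
    class_label = "all")), "estimation error")
})

test_that("a constant response shrinks to the intercept", {
  set.seed(8)
  n <- 300
  tab <- make_model_table(
    density = 50 * exp(rnorm(n, 0, 0.05)),
    age = sample(1:40, n, TRUE), year = sample(1950:1978, n, TRUE),
    class_label = "all", reservoir_id = rep(sprintf("R%d", 1:20), 15))
  fit <- fit_density_gamm(tab)
  mu <- fitted(fit$gam)
  expect_true(all(abs(mu - 50) / 50 < 0.05))
  # no spurious structure: each smooth contributes (near) nothing to the
  # linear predictor (the thin-plate null space keeps edf >= 1, so the
  # check is on the contributions themselves)
  contrib <- mgcv::predict.gam(fit$gam, type = "terms")
  for (term in c("s(age)", "s(year_sampled)")) {
    expect_lt(stats::sd(contrib[, term]), 0.05)
  }
})

test_that("the fitted age curve recovers a known smooth signal", {
  set.seed(15)
  n <- 500
  age <- runif(n, 0, 60)
  log_mu <- 1 + 0.5 * sin(age / 8)
  y <- rgamma(n, shape = 50, rate = 50 / exp(log_mu))
  tab <- make_model_table(
    density = y, age = age, year = rep(1970L, n),
    class_label = "all", reservoir_id = rep(sprintf("R%d", 1:25), 20))
  fit <- fit_density_gamm(tab)
  eta <- as.numeric(mgcv::predict.gam(
    fit$gam, newdata = data.frame(
      age = age, year_sampled = 1970,
      class_label = factor("all"),
      reservoir_id = factor("R1", levels = levels(fit$gam$model$reservoir_id))),
    type = "link", exclude = "s(reservoir_id)"))
  expect_lt(sqrt(mean((eta - log_mu)^2)), 0.1)
  expect_gte(fit$deviance_explained, 0)
  expect_lte(fit$deviance_explained, 1)
})

test_that("the linear-terms limit matches a hand-rolled Gamma-GLM IRLS oracle", {
  set.seed(23)
  n <- 200
  age <- runif(n, 0, 50)
  year <- runif(n, 1950, 1978)
  eta <- 3 + 0.02 * age - 0.01 * (year - 1960)
  y <- rgamma(n, shape = 30, rate = 30 / exp(eta))
  tab <- make_model_table(density = y, age = age, year = year,
                          class_label = "all", reservoir_id = "R1")
  fit <- fit_density_gamm(tab, smooth = FALSE)
  beta_gam <- unname(coef(fit$gam)[c("(Intercept)", "age", "year_sampled")])
  X <- cbind(1, age, year)
  beta_oracle <- irls_gamma_log(X, y)
  expect_equal(beta_gam, beta_oracle, tolerance = 1e-4)

  # prediction is the hand-computed exp(linear predictor)
  pred <- predict_density(fit, "all", reservoir_id = "R1", year = 1970)
  age_1970 <- 1970 - tab$year_completed[1]
  expect_equal(pred,
               exp(sum(beta_gam * c(1, age_1970, 1970))), tolerance = 1e-8)
  expect_gt(pred, 0)
})

test_that("predictions behave as an intercept-only model when nothing varies", {
  tab <- make_model_table(density = rep(50, 8), age = rep(5, 8),
                          year = rep(1960L, 8), class_label = "all",
                          reservoir_id = "R1")
  fit <- fit_density_gamm(tab)
  expect_equal(predict_density(fit, "all", year = 1993), 50, tolerance = 1e-6)
  expect_equal(predict_density(fit, "all", year = 1955), 50, tolerance = 1e-6)
  expect_error(predict_density(fit, "nope"), "lookup error")
  expect_error(predict_density(fit, "all", reservoir_id = "R99"),
               "lookup error")
})

test_that("class means average per-reservoir predictions and omit dropped classes", {
  tab <- make_model_table(
    density = c(rep(40, 10), rep(60, 10), rep(90, 3)),
    age = rep(5, 23), year = rep(1960L, 23),
    class_label = c(rep("A", 20), rep("B", 3)),
    reservoir_id = c(rep("R1", 10), rep("R2", 10), rep("R3", 3)))
  prep <- prepare_model_table(tab, tibble::tibble(
    reservoir_id = tab$reservoir_id, schema_id = 3L,
    class_label = tab$class_label))
  fit <- fit_density_gamm(prep$table)
  cm <- class_mean_density(fit, year = 1960)
  expect_named(cm, "A")          # class B dropped below min_class_n
  expect_equal(unname(cm[["A"]]), 50, tolerance = 1e-2)
  expect_equal(global_mean_density(fit, year = 1960), 50, tolerance = 1e-2)
})

test_that("class mean densities and the intercept sd are recovered on the stated synthetic design", {
  # 200 sampled reservoirs x 5 surveys each = 1,000 surveys, Gamma shape
  # 20, four balanced classes (uncorrelated covariates make the quadrant
  # classes equal-sized)
  cfg <- simulation_config(seed = 27, n_reservoirs = 200, survey_fraction = 1,
                           surveys_per_reservoir = 5, gamma_shape = 20,
                           vol_discharge_cor = 0,
                           prop_duplicate = 0, prop_natural_lake = 0,
                           prop_missing_area = 0, prop_missing_coords = 0)
  inv <- simulate_inventory(cfg)
  sv <- suppressWarnings(simulate_surveys(inv, cfg))
  linked <- link_surveys(sv, inv, constant = cfg$recovery_constant)
  assignments <- tibble::tibble(reservoir_id = inv$reservoir_id,
                                schema_id = 3L,
                                class_label = inv$true_class)
  prep <- prepare_model_table(linked$linked, assignments)
  fit <- fit_density_gamm(prep$table)

  # realized truth: deterministic density times each sampled reservoir's
  # actual random intercept, from the generator's answer key
  truth <- true_summary(inv, cfg)
  u_tab <- attr(sv, "random_intercepts")
  realized <- truth$density_kg_ha * exp(
    u_tab$u[match(truth$reservoir_id, u_tab$reservoir_id)])
  est <- class_mean_density(fit)
  for (cl in names(est)) {
    sampled <- fit$reservoirs$reservoir_id[fit$reservoirs$class_label == cl]
    true_cl <- mean(realized[truth$reservoir_id %in% sampled])
    expect_lt(abs(est[[cl]] - true_cl) / true_cl, 0.10)
  }
  invisible(utils::capture.output(
    vc <- mgcv::gam.vcomp(fit$gam, rescale = TRUE)))
  sd_hat <- vc[grep("reservoir", rownames(vc)), "std.dev"]
  expect_lt(abs(sd_hat - cfg$random_intercept_sd) / cfg$random_intercept_sd,
            0.25)

  # predictions are continuous across the extrapolation boundary
  cl1 <- names(est)[1]
  p_lo <- predict_density(fit, cl1, year = 1978)
  p_hi <- predict_density(fit, cl1, year = 1978.01)
  expect_lt(abs(p_hi - p_lo) / p_lo, 1e-2)
})
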