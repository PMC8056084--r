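test_that("the gradient hits its endpoints and stays strictly decreasing", {
  g <- simulate_gradient(simulation_config())
  expect_equal(nrow(g), 120L)
  expect_equal(g$dose_ppfd[1], 230)
  expect_equal(g$dose_ppfd[120], 0.5)
  expect_true(all(diff(g$dose_ppfd) < 0))
  expect_equal(anyDuplicated(g$dose_ppfd), 0L)
  for (decay in c("linear", "inverse_square")) {
    gi <- simulate_gradient(simulation_config(gradient_decay = decay))
    expect_equal(range(gi$dose_ppfd), c(0.5, 230))
    expect_true(all(diff(gi$dose_ppfd) < 0))
  }
  expect_error(simulation_config(max_ppfd = 1, min_ppfd = 10),
               class = "lueled_error_config")
  expect_error(simulation_config(n_positions = 2),
               class = "lueled_error_config")
})

test_that("zero variability reproduces the seasonal means exactly", {
  cfg <- simulation_config(temp_sd_C = 0, dli_cv = 0)
  env <- simulate_environment(cfg, "late_winter")
  expect_equal(nrow(env), 32L)
  expect_true(all(env$mean_temp_C == 19.3))
  expect_true(all(env$natural_dli_700 == 7.1))
  expect_equal(env$natural_dli_800, env$natural_dli_700 * 1.25)
})

test_that("realized environment means track the seasonal targets", {
  set.seed(9)
  cfg <- simulation_config()
  for (s in c("late_winter", "early_summer")) {
    target <- cfg$seasons$mean_natural_dli_700[cfg$seasons$season == s]
    env <- simulate_environment(cfg, s)
    expect_lt(abs(mean(env$natural_dli_700) - target) / target, 0.15)
    expect_true(all(env$natural_dli_800 >= env$natural_dli_700))
  }
  expect_error(simulate_environment(cfg, "monsoon"),
               class = "lueled_error_config")
})

test_that("simulation is deterministic in the seed", {
  e1 <- simulate_experiment(simulation_config(n_positions = 5), seed = 42)
  e2 <- simulate_experiment(simulation_config(n_positions = 5), seed = 42)
  e3 <- simulate_experiment(simulation_config(n_positions = 5), seed = 43)
  expect_identical(e1$observations, e2$observations)
  expect_identical(e1$environments, e2$environments)
  expect_false(identical(e1$observations$dry_weight_g,
                         e3$observations$dry_weight_g))
})

test_that("observation tables satisfy every plant-record invariant", {
  exp <- tiny_experiment(n_positions = 8, seed = 3)
  obs <- exp$observations
  expect_equal(nrow(obs), 3 * 4 * 2 * 2 * 8)
  mass_cols <- c("fresh_weight_g", "dry_weight_g", "leaf_dry_weight_g",
                 "stem_dry_weight_g", "leaf_area_m2", "hypocotyl_mm",
                 "epicotyl_mm", "internode_mm")
  for (cl in mass_cols) expect_true(all(obs[[cl]] > 0), label = cl)
  expect_equal(obs$plant_height_mm,
               obs$hypocotyl_mm + obs$epicotyl_mm + obs$internode_mm)
  expect_equal(obs$lma_g_m2, obs$leaf_dry_weight_g / obs$leaf_area_m2)
  expect_equal(obs$stem_leaf_ratio,
               obs$stem_dry_weight_g / obs$leaf_dry_weight_g)
  expect_equal(obs$dry_weight_g,
               obs$leaf_dry_weight_g + obs$stem_dry_weight_g)
  expect_equal(anyDuplicated(obs$plant_id), 0L)
})

test_that("noise-free phenomenological data returns the exact true parameters", {
  cfg <- simulation_config(n_positions = 10, noise_sd = 0, rs_sd = 0,
                           rsc_sd = 0)
  exp <- simulate_experiment(cfg, seed = 1)
  obs <- exp$observations
  cell <- obs[obs$season == "mid_spring" & obs$color == "red" &
                obs$replication == 1 & obs$harvest == "final", ]
  fit <- fit_dose_response_linear(cell, "dry_weight_g")
  tr <- cfg$traits
  # shoot dw = leaf + stem with a shared slope: exactly log-linear
  beta_true <- tr$beta_red[tr$trait == "leaf_dry_weight_g"] +
    cfg$season_beta[["mid_spring"]]
  alpha_true <- log(exp(tr$alpha[tr$trait == "leaf_dry_weight_g"]) +
                      exp(tr$alpha[tr$trait == "stem_dry_weight_g"])) +
    cfg$season_alpha[["mid_spring"]]
  expect_equal(unname(fit$coefficients["slope"]), beta_true,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["intercept"]), alpha_true,
               tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-16)
})

test_that("directly simulated efficiency records carry the configured structure", {
  set.seed(10)
  rec <- simulate_efficiency_records(
    color_effect = c(blue = 0, red = 1, white_fr = 2),
    rs_sd = 0, rsc_sd = 0, resid_sd = 0
  )
  expect_equal(nrow(rec), 48L)
  expect_equal(unique(rec$value[rec$color == "red"]), 1)
  expect_equal(unique(rec$value[rec$color == "white_fr"]), 2)
})

test_that("experiment directories round trip losslessly", {
  dir <- withr::local_tempdir()
  exp <- tiny_experiment(n_positions = 5, seed = 17)
  write_experiment(exp, dir)
  back <- read_experiment(dir)
  expect_equal(as.data.frame(back$observations)[
    order(back$observations$plant_id), "dry_weight_g"],
    as.data.frame(exp$observations)[
      order(exp$observations$plant_id), "dry_weight_g"],
    tolerance = 1e-12)
  expect_equal(nrow(back$environments), nrow(exp$environments))
  expect_equal(back$config$k, exp$config$k)
  expect_equal(back$truth$seed, 17L)
  expect_named(back$spectra, c("blue", "red", "white_fr"))
  # observations stay readable without ground truth (real-data path)
  file.remove(file.path(dir, "ground_truth.json"))
  expect_silent(read_experiment(dir))
  # corrupted schema is a validation error naming the problem
  obs <- readr::read_csv(file.path(dir, "observations.csv"),
                         show_col_types = FALSE)
  names(obs)[names(obs) == "dose_ppfd"] <- "dose"
  readr::write_csv(obs, file.path(dir, "observations.csv"))
  expect_error(read_experiment(dir), class = "lueled_error_validation",
               regexp = "dose_ppfd")
})
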