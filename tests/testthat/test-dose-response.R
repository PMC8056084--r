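test_that("noiseless log-linear data is recovered exactly", {
  d <- loglinear_data(n = 40, alpha = 1, beta = 0.2, sigma = 0)
  fit <- fit_dose_response_linear(d, "y")
  expect_equal(unname(fit$coefficients["slope"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["intercept"]), 1, tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-18)
  # constant trait: slope 0
  flat <- tibble::tibble(dose_ppfd = c(0, 10, 50, 200), y = 3)
  expect_equal(unname(fit_dose_response_linear(flat, "y")$coefficients["slope"]),
               0, tolerance = 1e-12)
})

test_that("OLS agrees with the normal-equation oracle on random data", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    d <- tibble::tibble(dose_ppfd = runif(n, 0, 230),
                        y = exp(rnorm(n, 1, 0.5)))
    fit <- fit_dose_response_linear(d, "y")
    oracle <- normal_equation_ols(sqrt(d$dose_ppfd), log(d$y))
    expect_equal(unname(fit$coefficients["intercept"]),
                 unname(oracle["intercept"]), tolerance = 1e-10)
    expect_equal(unname(fit$coefficients["slope"]), unname(oracle["slope"]),
                 tolerance = 1e-10)
    expect_equal(fit$rss, unname(oracle["rss"]), tolerance = 1e-10)
  }
})

test_that("zero-trait plants are excluded with a count; bad inputs error", {
  d <- tibble::tibble(dose_ppfd = c(0, 2, 10, 60, 150),
                      y = c(0, 0, 3, 5, 9))
  fit <- fit_dose_response_linear(d, "y")
  expect_equal(fit$n, 3L)
  expect_equal(fit$n_excluded, 2L)
  expect_error(fit_dose_response_linear(
    tibble::tibble(dose_ppfd = 1:5, y = c(-1, 1, 2, 3, 4)), "y"),
    class = "lueled_error_domain")
  expect_error(fit_dose_response_linear(
    tibble::tibble(dose_ppfd = rep(5, 5), y = 1:5), "y"),
    class = "lueled_error_rank")
  expect_error(fit_dose_response_linear(
    tibble::tibble(dose_ppfd = 1:2, y = 1:2), "y"),
    class = "lueled_error_domain")
})

test_that("noiseless monomolecular data recovers its parameters", {
  doses <- simulate_gradient(simulation_config(n_positions = 60))$dose_ppfd
  d <- tibble::tibble(dose_ppfd = doses,
                      y = exp(2 - 1.5 * exp(-0.6 * sqrt(doses))))
  fit <- fit_dose_response_mono(d, "y")
  expect_equal(unname(fit$coefficients["A"]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["B"]), 1.5, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["r"]), 0.6, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("monomolecular RSS never materially exceeds the linear RSS", {
  set.seed(7)
  for (i in 1:10) {
    d <- loglinear_data(n = 50, alpha = 0.5, beta = 0.1, sigma = 0.2)
    lin <- fit_dose_response_linear(d, "y")
    mono <- fit_dose_response_mono(d, "y")
    expect_lte(mono$rss, lin$rss * (1 + 1e-3))
  }
})

test_that("profiled fit matches a hand-solved two-parameter OLS at fixed rate", {
  # at fixed r the model is linear in (A, B): ln y = A - B z with z=exp(-r x);
  # the full fit must do at least as well as any fixed-r solution
  set.seed(12)
  d <- loglinear_data(n = 60, alpha = 0.3, beta = 0.12, sigma = 0.15)
  x <- sqrt(d$dose_ppfd); y <- log(d$y)
  mono <- fit_dose_response_mono(d, "y")
  for (r in c(0.05, 0.2, 1.0)) {
    z <- exp(-r * x)
    o <- normal_equation_ols(z, y) # ln y = c0 + c1 z, B = -c1
    expect_lte(mono$rss, unname(o["rss"]) + 1e-10)
  }
})

test_that("the F comparison selects sensibly in clear-cut cases", {
  doses <- simulate_gradient(simulation_config(n_positions = 60))$dose_ppfd
  # identical RSS: F = 0, p = 1, linear kept
  lin_d <- tibble::tibble(dose_ppfd = doses, y = exp(1 + 0.1 * sqrt(doses)))
  lin <- fit_dose_response_linear(lin_d, "y")
  cmp0 <- compare_dose_response(lin, fit_dose_response_mono(lin_d, "y"))
  expect_equal(cmp0$selected_model, "linear")
  expect_equal(cmp0$p_value, 1, tolerance = 1e-6)
  # strongly saturating noiseless data: monomolecular wins
  sat <- tibble::tibble(dose_ppfd = doses,
                        y = exp(2 - 1.8 * exp(-0.5 * sqrt(doses))))
  cmp1 <- compare_dose_response(fit_dose_response_linear(sat, "y"),
                                fit_dose_response_mono(sat, "y"))
  expect_equal(cmp1$selected_model, "monomolecular")
  expect_lt(cmp1$p_value, 1e-10)
  # different observations are refused
  other <- fit_dose_response_mono(
    tibble::tibble(dose_ppfd = doses[1:50], y = sat$y[1:50]), "y")
  expect_error(compare_dose_response(lin, other),
               class = "lueled_error_domain")
})

test_that("model selection under a true linear model is never anti-conservative", {
  # the line sits on the r -> 0 boundary of the monomolecular family, so the
  # F comparison is conservative; the selection rate must not exceed the
  # nominal level plus Monte-Carlo error
  set.seed(31)
  n_sim <- 120
  sel <- logical(n_sim)
  doses <- simulate_gradient(simulation_config())$dose_ppfd
  for (i in seq_len(n_sim)) {
    d <- loglinear_data(sigma = 0.2, doses = doses)
    sel[i] <- compare_dose_response(
      fit_dose_response_linear(d, "y"),
      fit_dose_response_mono(d, "y")
    )$selected_model == "monomolecular"
  }
  expect_lte(mean(sel), 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("tidy, glance and predict expose the fit consistently", {
  d <- loglinear_data(n = 30, alpha = 0.8, beta = 0.1, sigma = 0)
  fit <- fit_dose_response(d, "y")
  expect_equal(fit$comparison$selected_model, fit$model)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 30L)
  expect_equal(predict(fit, 16, scale = "log"), 0.8 + 0.1 * 4,
               tolerance = 1e-8)
  expect_equal(predict(fit, 16), exp(0.8 + 0.4), tolerance = 1e-8)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("the efficiency table has one row per design cell and keeps failures", {
  exp <- tiny_experiment(n_positions = 6)
  obs <- exp$observations
  tab <- efficiency_table(obs, traits = c("dry_weight_g", "plant_height_mm"),
                          select_model = FALSE)
  # 3 colors x 4 seasons x 2 reps x 2 harvests = 48 cells per trait
  expect_equal(nrow(tab), 96L)
  expect_equal(sum(tab$trait == "dry_weight_g"), 48L)
  expect_true(all(is.finite(tab$slope)))
  # a trait that breaks the fit in one cell stays present with a note
  obs_bad <- obs
  cell <- obs_bad$season == "late_winter" & obs_bad$color == "blue" &
    obs_bad$replication == 1 & obs_bad$harvest == "final"
  obs_bad$dry_weight_g[cell] <- -1
  tab_bad <- efficiency_table(obs_bad, "dry_weight_g", select_model = FALSE)
  expect_equal(nrow(tab_bad), 48L)
  bad_row <- tab_bad[tab_bad$season == "late_winter" &
                       tab_bad$color == "blue" &
                       tab_bad$replication == 1 &
                       tab_bad$harvest == "final", ]
  expect_true(is.na(bad_row$slope))
  expect_match(bad_row$note, "Negative")
})
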