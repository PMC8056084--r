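test_that("a pure color effect is detected without phantom interactions", {
  set.seed(21)
  rec <- simulate_efficiency_records(
    color_effect = c(blue = 0, red = 0.05, white_fr = 0.05)
  )
  m <- fit_efficiency_model(rec)
  an <- tidy(m)
  expect_setequal(an$term, c("color", "season", "harvest", "color:season",
                             "color:harvest", "season:harvest"))
  expect_lt(an$p_value[an$term == "color"], 0.05)
  expect_gt(an$p_value[an$term == "color:season"], 0.05)
  expect_gt(an$p_value[an$term == "color:harvest"], 0.05)
})

test_that("identical records give no significant fixed terms", {
  rec <- simulate_efficiency_records(rs_sd = 0, rsc_sd = 0, resid_sd = 0)
  rec$value <- 0.42
  m <- fit_efficiency_model(rec)
  p <- tidy(m)$p_value
  expect_false(any(p < 0.05, na.rm = TRUE))
})

test_that("balanced designs make marginal means equal raw level means", {
  set.seed(33)
  rec <- simulate_efficiency_records(
    color_effect = c(blue = 0.1, red = 0.3, white_fr = 0.2),
    season_effect = c(late_winter = 0.05, mid_spring = 0, early_summer = -0.05,
                      late_summer = 0)
  )
  m <- fit_efficiency_model(rec)
  mm <- marginal_means(m, "color")
  raw <- tapply(rec$value, rec$color, mean)
  expect_equal(mm$emmean, as.numeric(raw[mm$level]), tolerance = 1e-8)
})

test_that("letter groupings are consistent with pairwise significance", {
  set.seed(44)
  rec <- simulate_efficiency_records(
    color_effect = c(blue = 0, red = 0.2, white_fr = 0.2),
    rs_sd = 0.005, rsc_sd = 0.005, resid_sd = 0.01
  )
  m <- fit_efficiency_model(rec)
  mm <- marginal_means(m, "color")
  # blue differs from both others; red and white_fr share a letter
  blue <- mm$letter[mm$level == "blue"]
  red <- mm$letter[mm$level == "red"]
  wfr <- mm$letter[mm$level == "white_fr"]
  expect_false(any(strsplit(blue, "")[[1]] %in% strsplit(red, "")[[1]]))
  expect_false(any(strsplit(blue, "")[[1]] %in% strsplit(wfr, "")[[1]]))
  expect_true(any(strsplit(red, "")[[1]] %in% strsplit(wfr, "")[[1]]))
  expect_error(marginal_means(m, "dose"), class = "lueled_error_usage")
})

test_that("compact letter display handles separated and overlapping levels", {
  # means 3 > 2 > 1; only the extremes differ: pattern a, ab, b
  sig <- matrix(FALSE, 3, 3)
  sig[1, 3] <- sig[3, 1] <- TRUE
  expect_equal(lueled:::cld_letters(c(3, 2, 1), sig), c("a", "ab", "b"))
  # all different: distinct letters
  sig_all <- !diag(3) > 0
  expect_equal(lueled:::cld_letters(c(3, 2, 1), sig_all), c("a", "b", "c"))
  # none different: one shared letter
  expect_equal(lueled:::cld_letters(c(3, 2, 1), matrix(FALSE, 3, 3)),
               c("a", "a", "a"))
})

test_that("missing records are dropped with a note, unreplicated designs refused", {
  set.seed(5)
  rec <- simulate_efficiency_records()
  rec$value[c(3, 17)] <- NA
  m <- fit_efficiency_model(rec)
  expect_true(any(grepl("missing", m$notes)))
  expect_equal(nrow(m$data), 46L)
  expect_error(fit_efficiency_model(rec[rec$replication == 1, ]),
               class = "lueled_error_design")
  expect_error(fit_efficiency_model(rec[, c("color", "value")]),
               class = "lueled_error_schema")
})

test_that("the nested-strata fallback tests terms against their design strata", {
  set.seed(61)
  rec <- simulate_efficiency_records(
    color_effect = c(blue = 0, red = 0.05, white_fr = 0.05)
  )
  m <- fit_efficiency_model(rec, force_fallback = TRUE)
  expect_equal(m$method, "aov_nested_strata")
  an <- tidy(m)
  # split-plot error df: season vs RS (4), color and c:s vs RSC (8),
  # harvest-level terms vs the finest stratum (18)
  expect_equal(an$df_den[an$term == "season"], 4)
  expect_equal(an$df_den[an$term == "color"], 8)
  expect_equal(an$df_den[an$term == "color:season"], 8)
  expect_equal(an$df_den[an$term == "harvest"], 18)
  expect_lt(an$p_value[an$term == "color"], 0.001)
  # marginal means still available through the same interface
  expect_equal(nrow(marginal_means(m, "season")), 4L)
})

test_that("variance components are reported non-negative on the mixed path", {
  set.seed(77)
  rec <- simulate_efficiency_records(rs_sd = 0.05, rsc_sd = 0.03,
                                     resid_sd = 0.02)
  m <- fit_efficiency_model(rec)
  if (m$method == "lmer_satterthwaite") {
    expect_true(all(m$varcomp$variance >= 0))
    expect_setequal(m$varcomp$group, c("RSC", "RS", "Residual"))
  }
  gl <- glance(m)
  expect_equal(gl$n_records, 48L)
  expect_true(gl$rsch_merged)
})
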