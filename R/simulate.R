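#' Seasonal growing conditions of the reference experiment design
#'
#' Default per-season environment targets for the synthetic generator: mean
#' air temperature, mean natural daily light integral inside the greenhouse,
#' and the lengths of the growing period to the intermediate and final
#' harvest. The four seasons reproduce the reference greenhouse campaign
#' (late winter through late summer at a temperate site).
#'
#' @return A tibble with columns `season`, `mean_temp_C`,
#'   `mean_natural_dli_700`, `days_intermediate`, `days_final`.
#' @export
season_defaults <- function() {
  tibble(
    season = factor(c("late_winter", "mid_spring", "early_summer",
                      "late_summer"),
                    levels = c("late_winter", "mid_spring", "early_summer",
                               "late_summer")),
    mean_temp_C = c(19.3, 20.6, 24.4, 24.1),
    mean_natural_dli_700 = c(7.1, 9.8, 15.7, 13.8),
    days_intermediate = c(18L, 20L, 15L, 14L),
    days_final = c(32L, 28L, 29L, 33L)
  )
}

#' Template lamp spectrum for a light-color treatment
#'
#' Synthetic spectral photon flux distributions on a 1-nm grid (350-850 nm)
#' emulating the three LED treatment types: blue (peaks at 440 and 470 nm),
#' red (660 nm), and white plus far-red (broad 400-700 nm white plus a 730 nm
#' far-red peak scaled so the red:far-red ratio is exactly the design target,
#' 0.1 by default). These are synthetic stand-ins for measured lamp spectra
#' and carry normalized (relative) flux.
#'
#' @param color `"blue"`, `"red"` or `"white_fr"`.
#' @param rfr_target Design red:far-red ratio of the white+far-red lamp.
#' @return A spectrum tibble (`wavelength_nm`, `photon_flux`).
#' @export
lamp_spectrum <- function(color = c("blue", "red", "white_fr"),
                          rfr_target = 0.1) {
  color <- match.arg(color)
  wl <- 350:850
  peak <- function(center, sd, height = 1) height * exp(-(wl - center)^2 / (2 * sd^2))
  flux <- switch(color,
    blue = peak(440, 10) + peak(470, 10),
    red = peak(660, 12),
    white_fr = {
      # smooth white 400-700 plateau
      white <- 0.5 * (1 / (1 + exp(-(wl - 410) / 5))) *
        (1 / (1 + exp((wl - 690) / 5)))
      fr <- peak(730, 12)
      sp_w <- tibble(wavelength_nm = wl, photon_flux = white)
      sp_f <- tibble(wavelength_nm = wl, photon_flux = fr)
      red_w <- band_integral_value(sp_w, 655, 665)
      red_f <- band_integral_value(sp_f, 655, 665)
      fr_w <- band_integral_value(sp_w, 725, 735)
      fr_f <- band_integral_value(sp_f, 725, 735)
      # scale s of the far-red peak solving (red_w + s red_f) /
      # (fr_w + s fr_f) = target exactly, cross-band tails included
      s <- (red_w - rfr_target * fr_w) / (rfr_target * fr_f - red_f)
      white + fr * s
    }
  )
  tibble(wavelength_nm = wl, photon_flux = flux)
}

#' Default true dose-response parameters of the generator
#'
#' Per-trait baseline intercepts `alpha` (natural-log trait units at dose
#' zero, final harvest, late winter) and per-color slopes `beta` (log units
#' per sqrt(umol m-2 s-1)). Dry-matter traits share one slope per color so
#' that organ sums (shoot dry weight) remain exactly log-linear in
#' sqrt(dose). Red and white+far-red are configured equally efficient and
#' blue less so; leaf area responds slightly less than leaf dry weight so
#' leaf mass per area increases with dose.
#'
#' @return A tibble `trait, alpha, beta_blue, beta_red, beta_white_fr`.
#' @export
trait_defaults <- function() {
  tribble(
    ~trait,              ~alpha,      ~beta_blue, ~beta_red, ~beta_white_fr,
    "leaf_dry_weight_g",  log(1.2),   0.10,       0.15,      0.15,
    "stem_dry_weight_g",  log(0.4),   0.10,       0.15,      0.15,
    "leaf_area_m2",       log(0.020), 0.08,       0.13,      0.12,
    "hypocotyl_mm",       log(12),    0.02,       0.03,      0.03,
    "epicotyl_mm",        log(18),    0.04,       0.06,      0.06,
    "internode_mm",       log(35),    0.05,       0.08,      0.08
  )
}

#' Build a simulation configuration
#'
#' Collects every tunable of the synthetic experiment: the seasonal
#' environments, the supplemental light gradient, the treatment colors with
#' their electrical conversion efficacies, the true dose-response parameters
#' and noise levels, and the physical constants of the light accounting.
#' Defaults reproduce the reference design: 3 light colors x 4 seasons x
#' 2 replications, a gradient from 230 to 0.5 umol m-2 s-1 over 120 distinct
#' positions per harvest half, an 18 h photoperiod, and lognormal
#' multiplicative trait noise (sigma = 0.2 on the log scale).
#'
#' @param n_positions Plants per harvest half along the gradient.
#' @param max_ppfd,min_ppfd Gradient endpoints, umol m-2 s-1 (PPFD 400-700).
#' @param gradient_decay `"exponential"`, `"linear"` or `"inverse_square"`.
#' @param photoperiod_h Supplemental photoperiod, hours per day.
#' @param t_base Base temperature for thermal time, C.
#' @param k Canopy light extinction coefficient.
#' @param ground_area_m2 Ground area per plant, m2.
#' @param energy_factor MJ per mol PAR photons.
#' @param natural_800_factor Multiplier giving the natural 400-800 nm DLI
#'   from the 400-700 nm DLI (solar 700-800 nm photon content).
#' @param seasons Seasonal targets, see [season_defaults()].
#' @param traits True stage-1 parameters, see [trait_defaults()].
#' @param season_alpha,season_beta Named per-season additive offsets applied
#'   to every trait's intercept and slope (purely additive by default, so the
#'   color x season interaction is truly zero).
#' @param harvest_alpha Additive log-scale intercept offset of the
#'   intermediate harvest relative to the final one.
#' @param mu Named electrical conversion efficacies per color, MJ MJ-1.
#' @param noise_sd Log-scale residual standard deviation of every trait.
#' @param rs_sd,rsc_sd Standard deviations of the replication-within-season
#'   and replication-within-season-by-color random intercepts (log scale).
#' @param temp_sd_C,dli_cv Day-to-day environment variability: Gaussian SD of
#'   daily mean temperature, and lognormal coefficient of variation of the
#'   natural DLI (the lognormal is mean-calibrated, so realized period means
#'   match the seasonal target in expectation).
#' @param dry_matter_content Dry-to-fresh mass ratio used to derive fresh
#'   weight consistently from dry weight.
#' @param seedling_leaf_area_m2 Day-0 leaf-area anchor (m2); the start of
#'   every interpolated trajectory.
#' @param mode `"phenomenological"` (traits drawn from the log-linear model)
#'   or `"mechanistic"` (leaf area grows exponentially in thermal time and
#'   dry weight accrues as `lue_true` times absorbed light, making light-use
#'   efficiency exactly recoverable).
#' @param lue_true Named per-color true light-use efficiencies, g MJ-1
#'   (mechanistic mode).
#' @param rfr_target Design red:far-red ratio of the white+far-red lamp.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_positions = 120L,
    max_ppfd = 230, min_ppfd = 0.5,
    gradient_decay = c("exponential", "linear", "inverse_square"),
    photoperiod_h = 18, t_base = 11, k = 0.8,
    ground_area_m2 = 0.002025, energy_factor = 0.219,
    natural_800_factor = 1.25,
    seasons = season_defaults(),
    traits = trait_defaults(),
    season_alpha = c(late_winter = 0, mid_spring = 0.10,
                     early_summer = 0.30, late_summer = 0.25),
    season_beta = c(late_winter = 0, mid_spring = 0,
                    early_summer = -0.03, late_summer = -0.03),
    harvest_alpha = -1.8,
    mu = c(blue = 0.37, red = 0.63, white_fr = 0.37),
    noise_sd = 0.2, rs_sd = 0.05, rsc_sd = 0.03,
    temp_sd_C = 1.5, dli_cv = 0.2,
    dry_matter_content = 0.08,
    seedling_leaf_area_m2 = 5e-5,
    mode = c("phenomenological", "mechanistic"),
    lue_true = c(blue = 2.0, red = 2.6, white_fr = 2.4),
    rfr_target = 0.1) {
  gradient_decay <- match.arg(gradient_decay)
  mode <- match.arg(mode)
  if (min_ppfd >= max_ppfd) {
    abort("Gradient needs min_ppfd < max_ppfd.", class = "lueled_error_config")
  }
  if (n_positions < 3) {
    abort("Need at least 3 gradient positions.", class = "lueled_error_config")
  }
  if (noise_sd < 0 || rs_sd < 0 || rsc_sd < 0) {
    abort("Noise standard deviations must be >= 0.",
          class = "lueled_error_config")
  }
  colors <- c("blue", "red", "white_fr")
  spectra <- setNames(map(colors, lamp_spectrum, rfr_target = rfr_target),
                      colors)
  # per-color PPFD800 / PPFD700 ratio of the supplemental light
  supp_800_factor <- map_dbl(spectra, function(sp) {
    band_integral_value(sp, 400, 800) / band_integral_value(sp, 400, 700)
  })
  structure(
    list(
      n_positions = as.integer(n_positions), max_ppfd = max_ppfd,
      min_ppfd = min_ppfd, gradient_decay = gradient_decay,
      photoperiod_h = photoperiod_h, t_base = t_base, k = k,
      ground_area_m2 = ground_area_m2, energy_factor = energy_factor,
      natural_800_factor = natural_800_factor,
      seasons = seasons, traits = traits,
      season_alpha = season_alpha, season_beta = season_beta,
      harvest_alpha = harvest_alpha, mu = mu,
      noise_sd = noise_sd, rs_sd = rs_sd, rsc_sd = rsc_sd,
      temp_sd_C = temp_sd_C, dli_cv = dli_cv,
      dry_matter_content = dry_matter_content,
      seedling_leaf_area_m2 = seedling_leaf_area_m2,
      mode = mode, lue_true = lue_true, rfr_target = rfr_target,
      colors = colors, spectra = spectra,
      supp_800_factor = supp_800_factor
    ),
    class = "simulation_config"
  )
}

#' Simulate one season's daily environment
#'
#' Daily mean temperatures are Gaussian around the seasonal mean; natural
#' daily light integrals are lognormal with the seasonal mean as the
#' distribution mean (mean-calibrated: `meanlog = log(m) - sdlog^2 / 2`), so
#' realized period means track the target. The 400-800 nm integral is the
#' 400-700 nm one scaled by `natural_800_factor`. Zero variability gives
#' exactly the seasonal means every day.
#'
#' @param config A [simulation_config()].
#' @param season Season name present in `config$seasons`.
#' @return A daily-environment tibble (`day`, `mean_temp_C`,
#'   `natural_dli_700`, `natural_dli_800`, `photoperiod_h`).
#' @export
simulate_environment <- function(config, season) {
  s <- config$seasons[config$seasons$season == season, ]
  if (nrow(s) != 1) {
    abort(paste0("Unknown season: ", season), class = "lueled_error_config")
  }
  n_days <- s$days_final
  temps <- rnorm(n_days, s$mean_temp_C, config$temp_sd_C)
  if (config$dli_cv > 0) {
    sdlog <- sqrt(log(1 + config$dli_cv^2))
    dli <- stats::rlnorm(n_days,
                         meanlog = log(s$mean_natural_dli_700) - sdlog^2 / 2,
                         sdlog = sdlog)
  } else {
    dli <- rep(s$mean_natural_dli_700, n_days)
  }
  tibble(
    day = seq_len(n_days),
    mean_temp_C = temps,
    natural_dli_700 = dli,
    natural_dli_800 = dli * config$natural_800_factor,
    photoperiod_h = config$photoperiod_h
  )
}

#' Supplemental dose per gradient position
#'
#' Strictly decreasing supplemental PPFD from directly below the lamp
#' (`max_ppfd`) to the compartment edge (`min_ppfd`), by default an
#' exponential falloff in position index; every plant position receives a
#' distinct dose. Endpoints are hit exactly.
#'
#' @param config A [simulation_config()].
#' @return A tibble `position`, `dose_ppfd`.
#' @export
simulate_gradient <- function(config) {
  n <- config$n_positions
  i <- seq_len(n)
  frac <- (i - 1) / (n - 1)
  dose <- switch(config$gradient_decay,
    exponential = config$max_ppfd * (config$min_ppfd / config$max_ppfd)^frac,
    linear = config$max_ppfd - frac * (config$max_ppfd - config$min_ppfd),
    inverse_square = {
      cc <- sqrt(config$max_ppfd / config$min_ppfd) - 1
      config$max_ppfd / (1 + cc * frac)^2
    }
  )
  tibble(position = i, dose_ppfd = dose)
}

#' Simulate a complete virtual experiment
#'
#' Generates the full design — 3 light colors x 4 seasons x 2 replications x
#' 2 harvests x `n_positions` gradient plants — with the statistical
#' structure the analysis pipeline assumes.
#'
#' In `"phenomenological"` mode every primitive trait follows
#' `ln(y) = alpha + beta * sqrt(dose) + RS + RSC + e` with per-color slopes,
#' additive season offsets and lognormal noise; derived traits (shoot dry
#' and fresh weight, plant height, leaf mass per area, stem:leaf ratio) are
#' built exactly from their defining components, so every observation-table
#' invariant holds by construction.
#'
#' In `"mechanistic"` mode leaf area grows exponentially in thermal time from
#' the day-0 seedling anchor at a dose- and color-dependent rate, and shoot
#' dry weight accrues as `lue_true` times the Beer-Lambert absorbed light
#' (band 400-700 nm) accumulated to the harvest, so the pipeline's
#' light-use-efficiency estimate recovers `lue_true` exactly.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A `simulated_experiment` list: `observations` (plant table),
#'   `environments` (daily environments, all seasons), `gradient`, `spectra`,
#'   `truth` (ground-truth parameter record), `config`, `seed`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))

  envs <- config$seasons$season |>
    map(function(s) {
      simulate_environment(config, s) |> mutate(season = s, .before = 1)
    }) |>
    list_rbind()
  gradient <- simulate_gradient(config)

  design <- tidyr::expand_grid(
    season = config$seasons$season,
    replication = c(1L, 2L),
    color = factor(config$colors, levels = config$colors),
    harvest = factor(c("intermediate", "final"),
                     levels = c("intermediate", "final")),
    gradient
  )

  # replication-level random intercepts: RS (shared across colors) and RSC
  rs_tab <- tidyr::expand_grid(season = config$seasons$season,
                               replication = c(1L, 2L)) |>
    mutate(rs_effect = rnorm(n(), 0, config$rs_sd))
  rsc_tab <- tidyr::expand_grid(season = config$seasons$season,
                                replication = c(1L, 2L),
                                color = factor(config$colors,
                                               levels = config$colors)) |>
    mutate(rsc_effect = rnorm(n(), 0, config$rsc_sd))
  design <- design |>
    left_join(rs_tab, by = c("season", "replication")) |>
    left_join(rsc_tab, by = c("season", "replication", "color"))

  obs <- if (config$mode == "phenomenological") {
    simulate_traits_phenomenological(design, config)
  } else {
    simulate_traits_mechanistic(design, config, envs)
  }

  obs <- obs |>
    mutate(
      dry_weight_g = .data$leaf_dry_weight_g + .data$stem_dry_weight_g,
      fresh_weight_g = .data$dry_weight_g / config$dry_matter_content,
      plant_height_mm = .data$hypocotyl_mm + .data$epicotyl_mm +
        .data$internode_mm,
      lma_g_m2 = .data$leaf_dry_weight_g / .data$leaf_area_m2,
      stem_leaf_ratio = .data$stem_dry_weight_g / .data$leaf_dry_weight_g,
      dose_dli = ppfd_to_dli(.data$dose_ppfd, config$photoperiod_h)
    ) |>
    mutate(plant_id = sprintf("%s_r%d_%s_%s_p%03d",
                              .data$season, .data$replication, .data$color,
                              .data$harvest, .data$position),
           .before = 1) |>
    select(-any_of(c("rs_effect", "rsc_effect")))

  truth <- list(
    mode = config$mode,
    traits = config$traits,
    season_alpha = as.list(config$season_alpha),
    season_beta = as.list(config$season_beta),
    harvest_alpha = config$harvest_alpha,
    noise_sd = config$noise_sd,
    lue_true = as.list(config$lue_true),
    mu = as.list(config$mu),
    seed = as.integer(seed)
  )

  structure(
    list(observations = obs, environments = envs, gradient = gradient,
         spectra = config$spectra, truth = truth, config = config,
         seed = as.integer(seed)),
    class = "simulated_experiment"
  )
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("<simulated_experiment>", nrow(x$observations), "plants,",
      x$config$mode, "mode, seed", x$seed, "\n")
  invisible(x)
}

# ln(y) = alpha + season/harvest offsets + RS + RSC + beta * sqrt(dose) + eps
simulate_traits_phenomenological <- function(design, config) {
  tr <- config$traits
  n <- nrow(design)
  sqrt_dose <- sqrt(design$dose_ppfd)
  s_alpha <- config$season_alpha[as.character(design$season)]
  s_beta <- config$season_beta[as.character(design$season)]
  h_alpha <- ifelse(design$harvest == "intermediate", config$harvest_alpha, 0)
  out <- design
  for (row in seq_len(nrow(tr))) {
    beta <- dplyr::case_match(as.character(design$color),
      "blue" ~ tr$beta_blue[row],
      "red" ~ tr$beta_red[row],
      "white_fr" ~ tr$beta_white_fr[row]
    )
    eta <- tr$alpha[row] + s_alpha + h_alpha + design$rs_effect +
      design$rsc_effect + (beta + s_beta) * sqrt_dose
    out[[tr$trait[row]]] <- exp(eta + rnorm(n, 0, config$noise_sd))
  }
  out
}

# leaf area exponential in thermal time; dry weight = lue_true * Q_total
simulate_traits_mechanistic <- function(design, config, envs) {
  la0 <- config$seedling_leaf_area_m2
  # relative growth rate per unit thermal time, dose- and color-dependent
  rgr_base <- 0.028
  rgr_dose <- 0.0012
  color_rgr <- c(blue = 0.95, red = 1.05, white_fr = 1.0)

  season_info <- config$seasons
  out_rows <- vector("list", length = 0)
  for (s in as.character(season_info$season)) {
    env_s <- envs[envs$season == s, ]
    tt <- thermal_time(env_s, config$t_base)
    info <- season_info[season_info$season == s, ]
    d_int <- info$days_intermediate
    d_fin <- info$days_final
    # daily incident supplemental-free energy, band 700, MJ m-2 d-1
    nat_I <- dli_to_energy(env_s$natural_dli_700, config$energy_factor)
    des_s <- design[design$season == s, ]
    sup_I <- dli_to_energy(
      ppfd_to_dli(des_s$dose_ppfd, config$photoperiod_h),
      config$energy_factor
    )
    rgr <- (rgr_base + rgr_dose * sqrt(des_s$dose_ppfd)) *
      unname(color_rgr[as.character(des_s$color)])
    harvest_day <- ifelse(des_s$harvest == "intermediate", d_int, d_fin)
    # leaf area per plant-day: la0 * exp(rgr * tt_cum[day])
    q_total <- vapply(seq_len(nrow(des_s)), function(i) {
      days <- seq_len(harvest_day[i])
      la <- la0 * exp(rgr[i] * tt$tt_cum[days])
      I_day <- nat_I[days] + sup_I[i]
      sum(daily_absorbed_light(I_day, la / config$ground_area_m2, config$k))
    }, numeric(1))
    la_harvest <- la0 * exp(rgr * tt$tt_cum[harvest_day])
    dw <- unname(config$lue_true[as.character(des_s$color)]) * q_total
    des_s$leaf_dry_weight_g <- 0.75 * dw
    des_s$stem_dry_weight_g <- 0.25 * dw
    des_s$leaf_area_m2 <- la_harvest
    # lengths stay phenomenological (log-linear with mild noise-free dose response)
    des_s$hypocotyl_mm <- exp(log(12) + 0.03 * sqrt(des_s$dose_ppfd))
    des_s$epicotyl_mm <- exp(log(18) + 0.05 * sqrt(des_s$dose_ppfd))
    des_s$internode_mm <- exp(log(35) + 0.07 * sqrt(des_s$dose_ppfd))
    out_rows[[length(out_rows) + 1]] <- des_s
  }
  list_rbind(out_rows)
}

#' Simulate stage-2 efficiency records directly
#'
#' Draws one slope record per replication x season x color x harvest cell
#' from the stage-2 generative model: fixed color, season and harvest
#' effects (additive, so interactions are truly zero unless supplied),
#' random RS and RSC intercepts, and residual noise. Used to study the
#' calibration and power of the mixed-model stage in isolation.
#'
#' @param color_effect,season_effect,harvest_effect Named effect vectors
#'   (any subset; missing levels get 0).
#' @param cs_interaction Optional matrix/long tibble of color x season
#'   interaction effects; default none.
#' @param rs_sd,rsc_sd,resid_sd Standard deviations of the RS and RSC random
#'   intercepts and the residual.
#' @param n_rep Replications per season.
#' @return A records tibble (`color, season, harvest, replication, value`).
#' @export
simulate_efficiency_records <- function(
    color_effect = c(blue = 0, red = 0, white_fr = 0),
    season_effect = c(late_winter = 0, mid_spring = 0, early_summer = 0,
                      late_summer = 0),
    harvest_effect = c(intermediate = 0, final = 0),
    cs_interaction = NULL,
    rs_sd = 0.01, rsc_sd = 0.01, resid_sd = 0.02, n_rep = 2L) {
  colors <- c("blue", "red", "white_fr")
  seasons <- c("late_winter", "mid_spring", "early_summer", "late_summer")
  harvests <- c("intermediate", "final")
  d <- tidyr::expand_grid(
    season = factor(seasons, levels = seasons),
    replication = seq_len(n_rep),
    color = factor(colors, levels = colors),
    harvest = factor(harvests, levels = harvests)
  )
  rs <- tidyr::expand_grid(season = factor(seasons, levels = seasons),
                           replication = seq_len(n_rep)) |>
    mutate(rs = rnorm(n(), 0, rs_sd))
  rsc <- tidyr::expand_grid(season = factor(seasons, levels = seasons),
                            replication = seq_len(n_rep),
                            color = factor(colors, levels = colors)) |>
    mutate(rsc = rnorm(n(), 0, rsc_sd))
  d <- d |>
    left_join(rs, by = c("season", "replication")) |>
    left_join(rsc, by = c("season", "replication", "color"))
  ce <- color_effect[as.character(d$color)]
  se <- season_effect[as.character(d$season)]
  he <- harvest_effect[as.character(d$harvest)]
  ce[is.na(ce)] <- 0; se[is.na(se)] <- 0; he[is.na(he)] <- 0
  inter <- 0
  if (!is.null(cs_interaction)) {
    key <- paste(d$color, d$season, sep = ".")
    inter <- cs_interaction[key]
    inter[is.na(inter)] <- 0
  }
  d$value <- ce + se + he + inter + d$rs + d$rsc + rnorm(nrow(d), 0, resid_sd)
  d |> select(-"rs", -"rsc")
}
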