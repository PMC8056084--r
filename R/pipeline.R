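#' Per-plant light absorption and use efficiency
#'
#' Reconstructs each plant's daily leaf-area trajectory on the thermal-time
#' axis, assembles the daily incident light above it (natural plus
#' supplemental, band-matched, converted to MJ), accumulates Beer-Lambert
#' absorption to the plant's harvest day, and derives the light-use
#' efficiency `LUE = DW / Q_total`.
#'
#' Trajectories are built per gradient position: the mirrored design gives
#' every final-harvest plant an intermediate-harvest partner at the same
#' dose, so the three anchors (day-0 seedling area, intermediate leaf area,
#' final leaf area) describe one shared trajectory. When one harvest is
#' absent at a position the exact two-point exponential through the
#' remaining anchor is used.
#'
#' @param observations Plant observation table (see [read_experiment()] for
#'   the schema).
#' @param environments Daily environments with a `season` column.
#' @param band 700 (PPFD 400-700 nm) or 800 (400-800 nm) light accounting.
#' @param config A [simulation_config()] carrying the physical constants
#'   (k, base temperature, ground area, energy factor, per-color
#'   supplemental 800/700 ratios, seedling anchor, photoperiod).
#' @return The observation tibble with `q_total_MJ` (absorbed light, MJ m-2),
#'   `sl_MJ` (supplemental light received, MJ m-2), `lue` (g MJ-1) and
#'   `interp_method` appended.
#' @export
plant_light_use <- function(observations, environments, band = 700,
                            config = simulation_config()) {
  if (!band %in% c(700, 800)) {
    abort("`band` must be 700 or 800.", class = "lueled_error_usage")
  }
  obs <- as_tibble(observations)
  needed <- c("season", "replication", "color", "harvest", "position",
              "dose_ppfd", "dry_weight_g", "leaf_area_m2")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0) {
    abort(paste0("Observations missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lueled_error_schema")
  }

  seasons_present <- unique(as.character(obs$season))
  season_info <- config$seasons
  tt_by_season <- list()
  natI_by_season <- list()
  harvest_days <- list()
  for (s in seasons_present) {
    env_s <- environments[environments$season == s, ]
    if (nrow(env_s) == 0) {
      abort(paste0("No environment rows for season ", s),
            class = "lueled_error_schema")
    }
    env_s <- env_s[order(env_s$day), ]
    tt_by_season[[s]] <- thermal_time(env_s, config$t_base)$tt_cum
    nat_dli <- if (band == 800) env_s$natural_dli_800 else env_s$natural_dli_700
    natI_by_season[[s]] <- dli_to_energy(nat_dli, config$energy_factor)
    info <- season_info[season_info$season == s, ]
    harvest_days[[s]] <- c(intermediate = info$days_intermediate,
                           final = info$days_final)
  }

  band_factor <- if (band == 800) config$supp_800_factor else
    setNames(rep(1, length(config$colors)), config$colors)

  obs$q_total_MJ <- NA_real_
  obs$sl_MJ <- NA_real_
  obs$interp_method <- NA_character_

  key <- paste(obs$season, obs$replication, obs$color, obs$position, sep = "\r")
  for (idx in split(seq_len(nrow(obs)), key)) {
    rows <- obs[idx, ]
    s <- as.character(rows$season[1])
    tt <- tt_by_season[[s]]
    hdays <- harvest_days[[s]]
    day_of <- hdays[as.character(rows$harvest)]
    anchors <- tibble(
      tt = c(0, tt[day_of]),
      leaf_area_m2 = c(config$seedling_leaf_area_m2, rows$leaf_area_m2)
    ) |> arrange(.data$tt)
    traj <- interpolate_leaf_area(anchors, tt)
    lai <- traj$leaf_area_m2 / config$ground_area_m2

    sup_I <- dli_to_energy(
      ppfd_to_dli(rows$dose_ppfd[1] *
                    band_factor[[as.character(rows$color[1])]],
                  config$photoperiod_h),
      config$energy_factor
    )
    I_day <- natI_by_season[[s]] + sup_I
    q_daily <- daily_absorbed_light(I_day, lai, config$k)
    q_cum <- cumsum(q_daily)
    obs$q_total_MJ[idx] <- q_cum[day_of]
    obs$sl_MJ[idx] <- sup_I * day_of
    obs$interp_method[idx] <- attr(traj, "method")
  }

  obs$lue <- light_use_efficiency(obs$dry_weight_g, obs$q_total_MJ)
  obs
}

#' Per-plant energy use efficiency
#'
#' For each replication x season x color x harvest cell, fits the dry-weight
#' dose-response curve, attributes each plant's supplemental dry weight as
#' the prediction difference [supplemental_dw()], and converts it to EUE
#' with the color's electrical conversion efficacy.
#'
#' @param obs Output of [plant_light_use()] (needs `sl_MJ`).
#' @param config A [simulation_config()] carrying `mu` and the ground area.
#' @return `obs` with `dw_sl_g_m2` and `eue` appended.
#' @export
plant_energy_use <- function(obs, config = simulation_config()) {
  if (!"sl_MJ" %in% names(obs)) {
    abort("Run plant_light_use() first: `sl_MJ` column is required.",
          class = "lueled_error_usage")
  }
  obs$dw_sl_g_m2 <- NA_real_
  obs$eue <- NA_real_
  key <- paste(obs$season, obs$replication, obs$color, obs$harvest,
               sep = "\r")
  for (idx in split(seq_len(nrow(obs)), key)) {
    cell <- obs[idx, ]
    fit <- tryCatch(fit_dose_response_linear(cell, "dry_weight_g"),
                    error = function(e) NULL)
    if (is.null(fit)) next
    dw_sl <- suppressWarnings(supplemental_dw(fit, cell$dose_ppfd)) /
      config$ground_area_m2
    mu <- config$mu[[as.character(cell$color[1])]]
    ok <- cell$sl_MJ > 0
    eue <- rep(NA_real_, nrow(cell))
    eue[ok] <- energy_use_efficiency(dw_sl[ok], cell$sl_MJ[ok], mu)
    obs$dw_sl_g_m2[idx] <- dw_sl
    obs$eue[idx] <- eue
  }
  obs
}

#' Analyze a (real or simulated) gradient experiment end to end
#'
#' Runs the full efficiency pipeline: per-plant light absorption and LUE/EUE
#' ([plant_light_use()], [plant_energy_use()]), stage-1 dose-response fits
#' per design cell ([efficiency_table()]), and the stage-2 mixed model on
#' slopes and intercepts ([fit_efficiency_model()]) with marginal means for
#' color and season ([marginal_means()]).
#'
#' @param experiment A `simulated_experiment` (or the list returned by
#'   [read_experiment()]).
#' @param band 700 or 800: waveband of the light accounting and dose.
#' @param traits Trait columns for the stage-1 fits; defaults cover growth,
#'   morphology and the derived efficiencies.
#' @param stage2_traits Traits carried into stage 2 (default: all of
#'   `traits`).
#' @param alpha Significance level used throughout.
#' @return An `led_analysis` list: `band`, `plants` (per-plant efficiency
#'   table), `fits` (stage-1 table), `records` (long slope/intercept
#'   records), `stage2` (per trait and response kind: `model`,
#'   `means_color`, `means_season`), `anova` (stacked stage-2 ANOVA tibble),
#'   `warnings` (named counts and notes).
#' @export
analyze_experiment <- function(experiment, band = 700,
                               traits = c("fresh_weight_g", "dry_weight_g",
                                          "leaf_area_m2", "lma_g_m2",
                                          "stem_leaf_ratio",
                                          "plant_height_mm", "epicotyl_mm",
                                          "internode_mm", "lue", "eue"),
                               stage2_traits = traits, alpha = 0.05) {
  config <- experiment$config %||% simulation_config()
  obs <- plant_light_use(experiment$observations, experiment$environments,
                         band = band, config = config)
  obs <- plant_energy_use(obs, config = config)

  traits <- intersect(traits, names(obs))
  fits <- efficiency_table(obs, traits, dose = "dose_ppfd", alpha = alpha)

  records <- fits |>
    select(all_of(c("trait", "color", "season", "replication", "harvest",
                    "slope", "intercept", "note"))) |>
    pivot_longer(c("slope", "intercept"), names_to = "response_kind",
                 values_to = "value")

  stage2 <- list()
  anova_rows <- list()
  n_singular <- 0L
  for (tr in intersect(stage2_traits, unique(records$trait))) {
    for (kind in c("slope", "intercept")) {
      rec <- records |> filter(.data$trait == tr, .data$response_kind == kind)
      m <- tryCatch(fit_efficiency_model(rec), error = function(e) NULL)
      res <- list(model = m)
      if (!is.null(m)) {
        res$means_color <- tryCatch(marginal_means(m, "color", alpha),
                                    error = function(e) NULL)
        res$means_season <- tryCatch(marginal_means(m, "season", alpha),
                                     error = function(e) NULL)
      }
      stage2[[paste(tr, kind, sep = ".")]] <- res
      if (!is.null(res$model)) {
        if (res$model$singular) n_singular <- n_singular + 1L
        anova_rows[[length(anova_rows) + 1]] <-
          res$model$anova |> mutate(trait = tr, response_kind = kind,
                                    .before = 1)
      }
    }
  }

  warnings <- list(
    n_two_segment = sum(obs$interp_method == "two_segment"),
    n_two_point = sum(obs$interp_method == "two_point_exponential"),
    n_excluded_zero_trait = sum(fits$n_excluded, na.rm = TRUE),
    n_failed_cells = sum(!is.na(fits$note)),
    n_singular_stage2 = n_singular
  )

  structure(
    list(band = band, plants = obs, fits = fits, records = records,
         stage2 = stage2,
         anova = if (length(anova_rows)) list_rbind(anova_rows) else tibble(),
         warnings = warnings, alpha = alpha),
    class = "led_analysis"
  )
}

#' @export
print.led_analysis <- function(x, ...) {
  cat("<led_analysis> band", x$band, ":", nrow(x$plants), "plants,",
      nrow(x$fits), "stage-1 fits,", length(x$stage2), "stage-2 models\n")
  if (x$warnings$n_two_segment > 0) {
    cat("  two-segment interpolation fallbacks:", x$warnings$n_two_segment,
        "plants\n")
  }
  invisible(x)
}

#' Plot stage-1 slopes by color and season
#'
#' @param analysis An [analyze_experiment()] result.
#' @param trait Trait whose slopes to show.
#' @return A ggplot of per-cell slopes.
#' @export
plot_efficiencies <- function(analysis, trait = "dry_weight_g") {
  d <- analysis$fits |> filter(.data$trait == .env$trait)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$season, y = .data$slope,
                                  colour = .data$color)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = expression(Efficiency~(slope~on~ln~scale~per~sqrt(dose))),
                  title = trait) +
    ggplot2::theme_minimal()
}
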