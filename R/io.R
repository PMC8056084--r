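#' Write / read an experiment directory
#'
#' An experiment directory holds plain-text tables: `observations.csv` (one
#' row per plant), `environments.csv` (daily environments, all seasons),
#' `gradient.csv`, one `spectrum_<color>.csv` per lamp, `config.json` (the
#' scalar simulation settings needed to re-run the analysis) and, for
#' synthetic data, `ground_truth.json`. The round trip is lossless for all
#' tables; real measured data only needs `observations.csv`,
#' `environments.csv` and (optionally) `config.json` overrides.
#'
#' @param experiment A `simulated_experiment`.
#' @param dir Directory to create/fill.
#' @return `dir`, invisibly (`write_experiment`); the experiment list
#'   (`read_experiment`).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(experiment$observations, file.path(dir, "observations.csv"))
  readr::write_csv(experiment$environments, file.path(dir, "environments.csv"))
  readr::write_csv(experiment$gradient, file.path(dir, "gradient.csv"))
  for (col in names(experiment$spectra)) {
    readr::write_csv(experiment$spectra[[col]],
                     file.path(dir, paste0("spectrum_", col, ".csv")))
  }
  cfg <- experiment$config
  scalars <- list(
    n_positions = cfg$n_positions, max_ppfd = cfg$max_ppfd,
    min_ppfd = cfg$min_ppfd, gradient_decay = cfg$gradient_decay,
    photoperiod_h = cfg$photoperiod_h, t_base = cfg$t_base, k = cfg$k,
    ground_area_m2 = cfg$ground_area_m2, energy_factor = cfg$energy_factor,
    natural_800_factor = cfg$natural_800_factor,
    noise_sd = cfg$noise_sd, rs_sd = cfg$rs_sd, rsc_sd = cfg$rsc_sd,
    temp_sd_C = cfg$temp_sd_C, dli_cv = cfg$dli_cv,
    dry_matter_content = cfg$dry_matter_content,
    seedling_leaf_area_m2 = cfg$seedling_leaf_area_m2,
    mode = cfg$mode, rfr_target = cfg$rfr_target,
    mu = as.list(cfg$mu), lue_true = as.list(cfg$lue_true)
  )
  jsonlite::write_json(scalars, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(experiment$truth)) {
    jsonlite::write_json(experiment$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  obs_path <- file.path(dir, "observations.csv")
  env_path <- file.path(dir, "environments.csv")
  for (p in c(obs_path, env_path)) {
    if (!file.exists(p)) {
      abort(paste0("Missing required file: ", p),
            class = "lueled_error_validation")
    }
  }
  obs <- readr::read_csv(obs_path, show_col_types = FALSE)
  required <- c("plant_id", "season", "replication", "color", "harvest",
                "position", "dose_ppfd", "dry_weight_g", "leaf_area_m2")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    abort(paste0("observations.csv is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lueled_error_validation")
  }
  envs <- readr::read_csv(env_path, show_col_types = FALSE)
  if (!"season" %in% names(envs)) {
    abort("environments.csv needs a `season` column.",
          class = "lueled_error_validation")
  }
  validate_daily_environment(envs)

  season_levels <- c("late_winter", "mid_spring", "early_summer",
                     "late_summer")
  obs$season <- factor(obs$season,
                       levels = union(season_levels, unique(obs$season)))
  obs$season <- droplevels(obs$season)
  envs$season <- factor(envs$season, levels = levels(obs$season))
  obs$color <- factor(obs$color)
  obs$harvest <- factor(obs$harvest, levels = c("intermediate", "final"))

  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    raw$mu <- unlist(raw$mu)
    raw$lue_true <- unlist(raw$lue_true)
    do.call(simulation_config, raw)
  } else {
    simulation_config()
  }

  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }

  gradient_path <- file.path(dir, "gradient.csv")
  gradient <- if (file.exists(gradient_path)) {
    readr::read_csv(gradient_path, show_col_types = FALSE)
  } else {
    NULL
  }
  spectra_files <- list.files(dir, pattern = "^spectrum_.*\\.csv$",
                              full.names = TRUE)
  spectra <- setNames(
    map(spectra_files, read_spectrum),
    gsub("^spectrum_|\\.csv$", "", basename(spectra_files))
  )

  structure(
    list(observations = obs, environments = envs, gradient = gradient,
         spectra = spectra, truth = truth, config = config,
         seed = truth$seed %||% NA_integer_),
    class = "simulated_experiment"
  )
}

#' Write the analysis result tables
#'
#' Writes `plant_efficiency.csv`, `fits.csv`, `stage2_anova.csv` and
#' `marginal_means.csv` into `dir`.
#'
#' @param analysis An [analyze_experiment()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$plants, file.path(dir, "plant_efficiency.csv"))
  readr::write_csv(analysis$fits, file.path(dir, "fits.csv"))
  readr::write_csv(analysis$anova, file.path(dir, "stage2_anova.csv"))
  means <- imap(analysis$stage2, function(res, key) {
    if (is.null(res$model)) return(NULL)
    bind_rows(res$means_color, res$means_season) |>
      mutate(trait_response = key, .before = 1)
  }) |> purrr::compact() |> list_rbind()
  readr::write_csv(means, file.path(dir, "marginal_means.csv"))
  invisible(dir)
}
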