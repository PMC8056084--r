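# Orchestration layer: simulate -> analyze -> report, each step writing a
# run manifest so reruns are auditable and deterministic.

run_manifest <- function(dir, seed, config_hash, inputs, outputs, warnings) {
  manifest <- list(
    package = "lueled",
    version = as.character(utils::packageVersion("lueled")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = config_hash,
    inputs = inputs,
    outputs = outputs,
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Run the simulation step
#'
#' Generates a virtual experiment and writes it to `out_dir` together with a
#' run manifest (seed, config hash, package version, warnings). Identical
#' config and seed reproduce identical files.
#'
#' @param out_dir Output directory.
#' @param config A [simulation_config()]; the orchestration default scales
#'   the gradient to 60 positions per harvest half (2880 plants in total)
#'   for quick runs — pass `simulation_config()` for the full 120-plant
#'   study design.
#' @param seed Integer seed for all randomness.
#' @return The `simulated_experiment`, invisibly.
#' @export
run_simulate <- function(out_dir, config = simulation_config(n_positions = 60),
                         seed = 1) {
  experiment <- simulate_experiment(config, seed = seed)
  write_experiment(experiment, out_dir)
  run_manifest(
    out_dir, seed = as.integer(seed),
    config_hash = rlang::hash(config),
    inputs = list(), outputs = list(dir = out_dir),
    warnings = list()
  )
  invisible(experiment)
}

#' Run the analysis step
#'
#' Reads an experiment directory (synthetic or real), runs
#' [analyze_experiment()] for the chosen waveband, and writes the result
#' tables plus a manifest recording every fallback branch taken
#' (two-segment interpolations, excluded zero-trait plants, singular
#' stage-2 fits, failed cells).
#'
#' @param data_dir Experiment directory (see [read_experiment()]).
#' @param out_dir Output directory for the result tables.
#' @param band 700 or 800.
#' @param ... Passed to [analyze_experiment()].
#' @return The `led_analysis`, invisibly.
#' @export
run_analyze <- function(data_dir, out_dir, band = 700, ...) {
  experiment <- read_experiment(data_dir)
  analysis <- analyze_experiment(experiment, band = band, ...)
  write_analysis(analysis, out_dir)
  run_manifest(
    out_dir, seed = experiment$seed,
    config_hash = rlang::hash(experiment$config),
    inputs = list(data_dir = data_dir),
    outputs = list(dir = out_dir, band = band),
    warnings = analysis$warnings
  )
  invisible(analysis)
}

#' Render a text report of an analysis directory
#'
#' Summarizes the stage-2 ANOVA tables (six fixed terms per trait and
#' response kind), the marginal means with their letter groupings, and any
#' warnings recorded in the manifest, as markdown. Regeneration is
#' idempotent.
#'
#' @param results_dir Directory written by [run_analyze()].
#' @param out_file Output path (default `report.md` inside `results_dir`).
#' @return The report text, invisibly.
#' @export
run_report <- function(results_dir, out_file = file.path(results_dir,
                                                         "report.md")) {
  anova_path <- file.path(results_dir, "stage2_anova.csv")
  means_path <- file.path(results_dir, "marginal_means.csv")
  manifest_path <- file.path(results_dir, "manifest.json")
  for (p in c(anova_path, means_path)) {
    if (!file.exists(p)) {
      abort(paste0("Missing analysis output: ", p),
            class = "lueled_error_validation")
    }
  }
  an <- readr::read_csv(anova_path, show_col_types = FALSE)
  means <- readr::read_csv(means_path, show_col_types = FALSE)

  lines <- c("# Supplemental lighting efficiency report", "")
  if (file.exists(manifest_path)) {
    mf <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("Package lueled %s, seed %s, band %s.",
                       mf$version, mf$seed, mf$outputs$band), "")
    w <- mf$warnings
    if (length(w) > 0 && any(unlist(w) > 0)) {
      lines <- c(lines, "## Warnings", "")
      if ((w$n_two_segment %||% 0) > 0) {
        lines <- c(lines, sprintf(
          "- Two-segment leaf-area interpolation fallback used for %d plants.",
          w$n_two_segment))
      }
      if ((w$n_excluded_zero_trait %||% 0) > 0) {
        lines <- c(lines, sprintf(
          "- %d zero-trait plant values excluded from log-scale fits.",
          w$n_excluded_zero_trait))
      }
      if ((w$n_singular_stage2 %||% 0) > 0) {
        lines <- c(lines, sprintf(
          "- %d singular stage-2 mixed fits fell back to nested-strata ANOVA.",
          w$n_singular_stage2))
      }
      if ((w$n_failed_cells %||% 0) > 0) {
        lines <- c(lines, sprintf("- %d stage-1 cells failed to fit.",
                                  w$n_failed_cells))
      }
      lines <- c(lines, "")
    }
  }

  fmt_table <- function(d) {
    d <- as.data.frame(d)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(v) signif(v, 4))
    header <- paste0("| ", paste(names(d), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
    body <- apply(d, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
    c(header, sep, body)
  }

  for (tr in unique(an$trait)) {
    for (kind in unique(an$response_kind[an$trait == tr])) {
      lines <- c(lines, sprintf("## %s (%s)", tr, kind), "",
                 fmt_table(an |>
                             filter(.data$trait == tr,
                                    .data$response_kind == kind) |>
                             select(-"trait", -"response_kind")), "")
      mm <- means |> filter(.data$trait_response == paste(tr, kind, sep = "."))
      if (nrow(mm) > 0) {
        lines <- c(lines, "Marginal means:", "",
                   fmt_table(mm |> select(-"trait_response")), "")
      }
    }
  }
  writeLines(lines, out_file)
  invisible(paste(lines, collapse = "\n"))
}
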