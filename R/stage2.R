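#' Stage-2 mixed-model analysis of slope and intercept efficiencies
#'
#' The stage-1 fits yield one slope (efficiency) and one intercept (magnitude)
#' per replication x season x color x harvest cell. Stage 2 evaluates these
#' with a linear mixed-effects model with fixed light color, season and
#' harvest plus all two-way interactions, and random intercepts for the
#' randomization units: replication-within-season (RS),
#' replication-within-season-by-color (RSC) and
#' replication-within-season-by-color-by-harvest (RSCH):
#'
#' `value ~ (color + season + harvest)^2 + (1|RS) + (1|RSC) + (1|RSCH) + e`
#'
#' With exactly one record per RSCH cell — the usual layout, one slope per
#' curve — the RSCH variance is confounded with the residual and the term is
#' merged into the residual (noted in the result). The model is fitted by
#' REML with Satterthwaite denominator degrees of freedom
#' (\pkg{lmerTest}); if the fit is singular (one or more variance components
#' on the zero boundary), the analysis falls back to a classical
#' split-plot-style ANOVA with nested error strata
#' (`Error(RS/color/harvest)`), which tests every fixed term against its
#' design-correct stratum. The fallback is recorded, never silent.
#'
#' @param records A data frame with columns `color`, `season`, `harvest`,
#'   `replication` and the response column; typically one `trait` x
#'   `response_kind` slice of [efficiency_table()] output pivoted to a
#'   `value` column. Rows with missing response are dropped with a note.
#' @param response Name of the response column (default `"value"`).
#' @param force_fallback Use the nested-strata ANOVA unconditionally
#'   (mainly for testing the fallback path).
#' @return An `efficiency_model` object: elements `fit` (the lmer or aovlist
#'   object), `method` (`"lmer_satterthwaite"` or `"aov_nested_strata"`),
#'   `singular`, `rsch_merged`, `anova` (tibble: term, df_num, df_den,
#'   f_stat, p_value), `varcomp` (tibble of variance components, lmer path),
#'   `data`, `notes`.
#' @export
fit_efficiency_model <- function(records, response = "value",
                                 force_fallback = FALSE) {
  needed <- c("color", "season", "harvest", "replication", response)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lueled_error_schema")
  }
  d <- as_tibble(records)
  d$value <- d[[response]]
  notes <- character()
  n_missing <- sum(!is.finite(d$value))
  if (n_missing > 0) {
    notes <- c(notes, sprintf("%d records with missing value dropped", n_missing))
    d <- d[is.finite(d$value), ]
  }
  for (v in c("color", "season", "harvest", "replication")) {
    d[[v]] <- factor(d[[v]])
  }
  if (nlevels(d$replication) < 2) {
    abort("Design is unreplicated: replication stratum is inestimable.",
          class = "lueled_error_design")
  }
  d$RS <- interaction(d$replication, d$season, drop = TRUE)
  d$RSC <- interaction(d$RS, d$color, drop = TRUE)
  d$RSCH <- interaction(d$RSC, d$harvest, drop = TRUE)

  rsch_merged <- max(table(d$RSCH)) == 1L
  if (rsch_merged) {
    notes <- c(notes,
               "one record per RSCH cell: RSCH variance merged into residual")
  }

  fixed <- "value ~ (color + season + harvest)^2"
  out <- NULL
  if (!force_fallback) {
    rand <- if (rsch_merged) "(1 | RS) + (1 | RSC)" else
      "(1 | RS) + (1 | RSC) + (1 | RSCH)"
    fml <- as.formula(paste(fixed, "+", rand))
    # inline the formula in the call so emmeans can recover the model frame
    fit <- suppressMessages(suppressWarnings(
      eval(bquote(lmerTest::lmer(.(fml), data = .(d), REML = TRUE)))
    ))
    singular <- lme4::isSingular(fit, tol = 1e-4)
    if (!singular) {
      an <- suppressWarnings(stats::anova(fit, type = 3))
      anova_tbl <- tibble(
        term = rownames(an),
        df_num = an$NumDF, df_den = an$DenDF,
        f_stat = an$`F value`, p_value = an$`Pr(>F)`
      )
      vc <- as.data.frame(lme4::VarCorr(fit))
      varcomp <- tibble(group = vc$grp, variance = vc$vcov)
      out <- list(fit = fit, method = "lmer_satterthwaite",
                  singular = FALSE, anova = anova_tbl, varcomp = varcomp)
    } else {
      notes <- c(notes, "lmer fit singular: nested-strata ANOVA fallback used")
    }
  }

  if (is.null(out)) {
    fml <- as.formula(paste(fixed, "+ Error(RS/color/harvest)"))
    # the finest stratum has one observation per cell by design, which aov
    # flags as a singular Error() model; the term tests are still the
    # classical split-plot ones
    fit <- suppressWarnings(eval(bquote(stats::aov(.(fml), data = .(d)))))
    out <- list(fit = fit, method = "aov_nested_strata",
                singular = !force_fallback,
                anova = aovlist_anova(fit), varcomp = NULL)
  }

  structure(
    c(out, list(rsch_merged = rsch_merged, data = d, response = response,
                notes = notes)),
    class = "efficiency_model"
  )
}

# collect per-term F tests from the strata of an aovlist
aovlist_anova <- function(fit) {
  strata <- summary(fit)
  rows <- list()
  for (s in names(strata)) {
    tab <- strata[[s]][[1]]
    terms_here <- trimws(rownames(tab))
    resid_row <- terms_here == "Residuals"
    for (i in which(!resid_row)) {
      rows[[length(rows) + 1]] <- tibble(
        term = terms_here[i],
        df_num = tab$Df[i],
        df_den = if (any(resid_row)) tab$Df[resid_row] else NA_real_,
        f_stat = tab$`F value`[i],
        p_value = tab$`Pr(>F)`[i]
      )
    }
  }
  list_rbind(rows) |> filter(.data$term != "(Intercept)")
}

#' @export
print.efficiency_model <- function(x, ...) {
  cat("<efficiency_model>", x$method,
      if (x$singular) "(singular mixed fit, fallback)", "\n")
  print(as.data.frame(x$anova), digits = 4)
  invisible(x)
}

#' @rdname fit_efficiency_model
#' @param x,object An `efficiency_model`.
#' @param ... Unused.
#' @details `tidy()` returns the fixed-term ANOVA table; `glance()` a one-row
#'   summary with the method, singularity flag and record count.
#' @export
tidy.efficiency_model <- function(x, ...) x$anova

#' @rdname fit_efficiency_model
#' @export
glance.efficiency_model <- function(x, ...) {
  tibble(
    method = x$method, singular = x$singular, rsch_merged = x$rsch_merged,
    n_records = nrow(x$data),
    n_notes = length(x$notes)
  )
}

#' Estimated marginal means with compact letter display
#'
#' Least-squares means per level of one fixed factor, averaged over the other
#' factors, with Tukey-adjusted pairwise comparisons and a compact letter
#' display: levels sharing a letter do not differ at `alpha`.
#'
#' @param model An [fit_efficiency_model()] result.
#' @param factor One of `"color"`, `"season"`, `"harvest"`.
#' @param alpha Family-wise level for the letters (default 0.05).
#' @return A tibble `factor, level, emmean, se, df, letter`.
#' @export
marginal_means <- function(model, factor, alpha = 0.05) {
  stopifnot(inherits(model, "efficiency_model"))
  if (!factor %in% c("color", "season", "harvest")) {
    abort("`factor` must be one of color, season, harvest.",
          class = "lueled_error_usage")
  }
  emm <- suppressWarnings(suppressMessages(
    emmeans::emmeans(model$fit, specs = factor, data = model$data)
  ))
  emm_df <- as.data.frame(emm)
  lvl <- as.character(emm_df[[factor]])
  n <- length(lvl)
  if (n == 1) {
    letters_out <- "a"
  } else {
    prs <- suppressWarnings(as.data.frame(
      emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
    ))
    sig <- matrix(FALSE, n, n)
    for (row in seq_len(nrow(prs))) {
      pair <- strsplit(prs$contrast[row], " - ", fixed = TRUE)[[1]]
      pair <- gsub("^\\(|\\)$", "", trimws(pair))
      i <- match(pair[1], lvl)
      j <- match(pair[2], lvl)
      sig[i, j] <- sig[j, i] <- isTRUE(prs$p.value[row] < alpha)
    }
    letters_out <- cld_letters(emm_df$emmean, sig)
  }
  tibble(
    factor = factor, level = lvl,
    emmean = emm_df$emmean, se = emm_df$SE, df = emm_df$df,
    letter = letters_out
  )
}

#' Plot marginal means with letters
#'
#' @param means Output of [marginal_means()].
#' @return A ggplot.
#' @export
plot_marginal_means <- function(means) {
  ggplot2::ggplot(means, ggplot2::aes(x = .data$level, y = .data$emmean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$emmean - .data$se,
                                          ymax = .data$emmean + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter,
                                    y = .data$emmean + 1.5 * .data$se),
                       vjust = 0) +
    ggplot2::labs(x = means$factor[1], y = "Estimated marginal mean") +
    ggplot2::theme_minimal()
}
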