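#' Fit a log-linear dose-response curve
#'
#' Within one replicate of one light-color treatment, every plant along the
#' gradient receives a distinct supplemental dose, so a single replicate
#' yields a full dose-response curve. Traits are log transformed and the dose
#' square-root transformed before an ordinary least-squares fit, so the slope
#' is a per-sqrt-dose efficiency on the log scale and the intercept the
#' log-scale magnitude at dose zero:
#' `ln(trait) = intercept + slope * sqrt(dose)`.
#'
#' Plants with a trait value of exactly zero (e.g. no internodes formed yet)
#' cannot enter a log-scale fit; they are excluded and counted in
#' `n_excluded`. Negative trait values are an error.
#'
#' @param data A data frame of plant observations.
#' @param trait Name of the trait column (character).
#' @param dose Name of the dose column (character; default `"dose_ppfd"`,
#'   supplemental PPFD in umol m-2 s-1 at the plant's gradient position).
#' @return A `dose_response_fit` object (see Details) with elements `model`
#'   (`"linear"`), `trait`, `slope`, `intercept`, `rss`, `df`, `n`,
#'   `n_excluded`, `dose_range`.
#' @examples
#' d <- tibble::tibble(dose_ppfd = (0:20)^2, dw = exp(1 + 0.2 * (0:20)))
#' fit <- fit_dose_response_linear(d, "dw")
#' tidy(fit)
#' @export
fit_dose_response_linear <- function(data, trait, dose = "dose_ppfd") {
  xy <- prepare_dose_response(data, trait, dose)
  if (xy$n < 3) {
    abort("Need at least 3 observations with positive trait values.",
          class = "lueled_error_domain")
  }
  if (sd(xy$x) == 0) {
    abort("All doses identical: slope is not estimable.",
          class = "lueled_error_rank")
  }
  X <- cbind(1, xy$x)
  fit <- stats::lm.fit(X, xy$y)
  rss <- sum(fit$residuals^2)
  new_dose_response_fit(
    model = "linear", trait = trait, dose_var = dose,
    coefficients = c(intercept = unname(fit$coefficients[1]),
                     slope = unname(fit$coefficients[2])),
    rss = rss, df = xy$n - 2L, n = xy$n, n_excluded = xy$n_excluded,
    dose_range = range(xy$dose), x = xy$x, y = xy$y
  )
}

#' Fit a monomolecular (saturating) dose-response curve
#'
#' Saturating responses are modelled on the same transformed scale as the
#' linear fit, `ln(trait) = A - B * exp(-r * sqrt(dose))` with rate `r > 0`,
#' so the two models can be compared by an extra-sum-of-squares F-test.
#' For fixed `r` the model is linear in `(A, B)`, so fitting proceeds by
#' profiling the residual sum of squares over a deterministic log-spaced grid
#' of `r` values (closed-form `A`, `B` at each), then polishing the best
#' candidates with Levenberg-Marquardt least squares. The grid extends to very
#' small `r`, where the curve approaches the straight line, so the fitted RSS
#' never exceeds the linear fit's RSS by more than numerical tolerance.
#'
#' @inheritParams fit_dose_response_linear
#' @return A `dose_response_fit` with `model = "monomolecular"` and
#'   coefficients `A` (asymptote), `B` (range) and `r` (rate), plus the
#'   implied `slope`/`intercept` of the companion linear fit for record
#'   keeping.
#' @export
fit_dose_response_mono <- function(data, trait, dose = "dose_ppfd") {
  xy <- prepare_dose_response(data, trait, dose)
  if (xy$n < 4) {
    abort("Need at least 4 observations with positive trait values.",
          class = "lueled_error_domain")
  }
  x <- xy$x
  y <- xy$y

  # profiled RSS over r: for fixed r, OLS of y on (1, exp(-r x))
  profile_fit <- function(r) {
    z <- exp(-r * x)
    if (sd(z) < 1e-300) return(list(rss = Inf))
    f <- stats::lm.fit(cbind(1, z), y)
    list(A = unname(f$coefficients[1]), B = -unname(f$coefficients[2]),
         r = r, rss = sum(f$residuals^2))
  }
  x_scale <- max(x) - min(x)
  # from near-linear (r*range << 1) to saturation within a few percent of the
  # dose range (r*range ~ 100); spans the conventional starting rates
  r_grid <- exp(seq(log(1e-4 / max(x_scale, 1)), log(100 / max(x_scale, 1)),
                    length.out = 80))
  profs <- map(r_grid, profile_fit)
  rss_prof <- map_dbl(profs, "rss")
  best <- profs[order(rss_prof)][1:3]

  # polish the best profile candidates with Levenberg-Marquardt
  polish <- function(st) {
    tryCatch({
      f <- minpack.lm::nlsLM(
        y ~ A - B * exp(-r * x),
        data = data.frame(x = x, y = y),
        start = list(A = st$A, B = st$B, r = st$r),
        lower = c(-Inf, -Inf, 1e-8 / max(x_scale, 1)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      cf <- coef(f)
      list(A = cf[["A"]], B = cf[["B"]], r = cf[["r"]],
           rss = sum(stats::residuals(f)^2))
    }, error = function(e) NULL)
  }
  cands <- c(purrr::compact(map(best, polish)), best)
  cands <- cands[is.finite(map_dbl(cands, "rss"))]
  if (length(cands) == 0) {
    abort("Monomolecular fit failed to converge from every start.",
          class = "lueled_error_fit_failure")
  }
  win <- cands[[which.min(map_dbl(cands, "rss"))]]

  new_dose_response_fit(
    model = "monomolecular", trait = trait, dose_var = dose,
    coefficients = c(A = win$A, B = win$B, r = win$r),
    rss = win$rss, df = xy$n - 3L, n = xy$n, n_excluded = xy$n_excluded,
    dose_range = range(xy$dose), x = x, y = y
  )
}

#' Compare the linear and monomolecular fits by F-test
#'
#' Extra-sum-of-squares F-test treating the straight line (2 parameters) as
#' the reduced model and the monomolecular curve (3 parameters) as the full
#' model: `F = (RSS_lin - RSS_mono) / (RSS_mono / (n - 3))` on (1, n - 3)
#' degrees of freedom. The monomolecular curve is selected when p < `alpha`.
#'
#' @param linear_fit,mono_fit `dose_response_fit` objects for the same
#'   observations (same trait, same n).
#' @param alpha Selection level (default 0.05).
#' @return A one-row tibble: `f_stat`, `p_value`, `selected_model`.
#' @export
compare_dose_response <- function(linear_fit, mono_fit, alpha = 0.05) {
  stopifnot(inherits(linear_fit, "dose_response_fit"),
            inherits(mono_fit, "dose_response_fit"))
  if (linear_fit$n != mono_fit$n ||
      !isTRUE(all.equal(linear_fit$y, mono_fit$y))) {
    abort("Fits must be on identical observations.",
          class = "lueled_error_domain")
  }
  rss_lin <- linear_fit$rss
  rss_mono <- mono_fit$rss
  # the monomolecular family only reaches the straight line in the r -> 0
  # limit, so a fitted RSS a hair above the linear RSS means the optimum sat
  # on that boundary: clamp F at 0 there, and only error on real failures
  tol <- 1e-3 * rss_lin + 1e-9 * sum((linear_fit$y - mean(linear_fit$y))^2) +
    1e-12
  if (rss_mono > rss_lin + tol) {
    abort("Monomolecular RSS exceeds linear RSS beyond tolerance: optimization failed.",
          class = "lueled_error_fit_quality")
  }
  n <- linear_fit$n
  f_stat <- max(0, (rss_lin - rss_mono)) / (rss_mono / (n - 3))
  p_value <- pf(f_stat, 1, n - 3, lower.tail = FALSE)
  tibble(
    f_stat = f_stat, p_value = p_value,
    selected_model = if (p_value < alpha) "monomolecular" else "linear"
  )
}

#' Fit both candidate curves and select one
#'
#' Convenience wrapper: fits the log-linear and the monomolecular curve,
#' compares them by F-test, and returns the linear fit annotated with the
#' comparison and, when selected, the monomolecular coefficients.
#'
#' @inheritParams fit_dose_response_linear
#' @inheritParams compare_dose_response
#' @return A `dose_response_fit` whose `model` records the selected family
#'   and whose `comparison` element holds the F-test row. The linear slope
#'   and intercept are always retained (they are the efficiency and magnitude
#'   records for the stage-2 analysis).
#' @export
fit_dose_response <- function(data, trait, dose = "dose_ppfd", alpha = 0.05) {
  lin <- fit_dose_response_linear(data, trait, dose)
  mono <- fit_dose_response_mono(data, trait, dose)
  cmp <- compare_dose_response(lin, mono, alpha)
  out <- if (cmp$selected_model == "monomolecular") mono else lin
  out$linear_coefficients <- lin$coefficients
  out$comparison <- cmp
  out
}

# shared transform + validation for the stage-1 fits
prepare_dose_response <- function(data, trait, dose) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "lueled_error_domain")
  }
  for (col in c(trait, dose)) {
    if (!col %in% names(data)) {
      abort(paste0("Column `", col, "` not found."),
            class = "lueled_error_schema")
    }
  }
  tr <- data[[trait]]
  dd <- data[[dose]]
  keep <- !is.na(tr) & !is.na(dd)
  tr <- tr[keep]
  dd <- dd[keep]
  if (any(tr < 0)) {
    abort("Negative trait values: log transform undefined.",
          class = "lueled_error_domain")
  }
  if (any(dd < 0)) {
    abort("Negative doses are not allowed.", class = "lueled_error_domain")
  }
  pos <- tr > 0
  list(
    x = sqrt(dd[pos]), y = log(tr[pos]), dose = dd[pos],
    n = sum(pos), n_excluded = sum(!pos)
  )
}

new_dose_response_fit <- function(model, trait, dose_var, coefficients, rss,
                                  df, n, n_excluded, dose_range, x, y) {
  structure(
    list(model = model, trait = trait, dose_var = dose_var,
         coefficients = coefficients, rss = rss, df = df, n = n,
         n_excluded = n_excluded, dose_range = dose_range, x = x, y = y),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>", x$model, "fit of ln(", x$trait, ") on sqrt(",
      x$dose_var, ")\n", sep = "")
  print(round(x$coefficients, 5))
  cat("n =", x$n, " rss =", signif(x$rss, 5),
      if (x$n_excluded > 0) paste0(" (", x$n_excluded, " zero-trait plants excluded)"),
      "\n")
  invisible(x)
}

#' Predict from a dose-response fit
#'
#' @param object A `dose_response_fit`.
#' @param dose Doses at which to predict (original dose units).
#' @param scale `"natural"` (trait units, back-transformed) or `"log"`.
#' @param ... Unused.
#' @export
predict.dose_response_fit <- function(object, dose,
                                      scale = c("natural", "log"), ...) {
  scale <- match.arg(scale)
  x <- sqrt(dose)
  cf <- object$coefficients
  eta <- if (object$model == "monomolecular") {
    cf[["A"]] - cf[["B"]] * exp(-cf[["r"]] * x)
  } else {
    cf[["intercept"]] + cf[["slope"]] * x
  }
  if (scale == "log") eta else exp(eta)
}

#' @rdname fit_dose_response_linear
#' @param x A `dose_response_fit` (for `tidy`/`glance`, passed as `x`).
#' @param ... Unused.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname fit_dose_response_linear
#' @export
glance.dose_response_fit <- function(x, ...) {
  cmp <- x$comparison %||%
    tibble(f_stat = NA_real_, p_value = NA_real_, selected_model = x$model)
  tibble(
    model = x$model, trait = x$trait, n = x$n, n_excluded = x$n_excluded,
    rss = x$rss, df = x$df,
    sigma = sqrt(x$rss / x$df),
    f_stat = cmp$f_stat, p_value = cmp$p_value
  )
}

#' @rdname fit_dose_response_linear
#' @param object A `dose_response_fit` (for `autoplot`).
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  obs <- tibble(dose = object$x^2, value = exp(object$y))
  grid <- tibble(dose = seq(object$dose_range[1], object$dose_range[2],
                            length.out = 200))
  grid$value <- predict(object, grid$dose)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$dose, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0("Supplemental dose (", object$dose_var, ")"),
                  y = object$trait,
                  subtitle = paste(object$model, "fit")) +
    ggplot2::theme_minimal()
}

#' Stage-1 efficiency table: one fit per design cell
#'
#' Fits a dose-response curve for every combination of season, light color,
#' replication and harvest present in the data, for each requested trait, and
#' returns the slopes (efficiencies) and intercepts (magnitudes) in long
#' form — the records the stage-2 mixed model consumes. Cells whose fit fails
#' are kept with missing coefficients and the failure reason; they are never
#' silently dropped.
#'
#' @param data Plant observation table with columns `season`, `color`,
#'   `replication`, `harvest`, the dose column and the trait columns.
#' @param traits Character vector of trait column names.
#' @param dose Dose column name (default `"dose_ppfd"`).
#' @param select_model Fit and F-test the monomolecular alternative per cell
#'   (default TRUE); if FALSE only the linear fit is made.
#' @param alpha Model-selection level.
#' @return A tibble with one row per trait x cell:
#'   `trait,color,season,replication,harvest,model,slope,intercept,A,B,r,
#'   rss,n,n_excluded,f_stat,p_value,note`.
#' @export
efficiency_table <- function(data, traits, dose = "dose_ppfd",
                             select_model = TRUE, alpha = 0.05) {
  cell_vars <- c("season", "color", "replication", "harvest")
  missing_cols <- setdiff(c(cell_vars, dose), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing design column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lueled_error_schema")
  }
  cells <- data |>
    group_by(across(all_of(cell_vars))) |>
    group_split()

  fit_cell <- function(cell, trait) {
    meta <- cell[1, cell_vars]
    res <- tryCatch({
      lin <- fit_dose_response_linear(cell, trait, dose)
      cmp <- NULL
      monoco <- c(A = NA_real_, B = NA_real_, r = NA_real_)
      model <- "linear"
      if (select_model) {
        mono <- fit_dose_response_mono(cell, trait, dose)
        cmp <- compare_dose_response(lin, mono, alpha)
        if (cmp$selected_model == "monomolecular") {
          model <- "monomolecular"
          monoco <- mono$coefficients
        }
      }
      tibble(
        model = model,
        slope = lin$coefficients[["slope"]],
        intercept = lin$coefficients[["intercept"]],
        A = monoco[["A"]], B = monoco[["B"]], r = monoco[["r"]],
        rss = lin$rss, n = lin$n, n_excluded = lin$n_excluded,
        f_stat = if (is.null(cmp)) NA_real_ else cmp$f_stat,
        p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
        note = NA_character_
      )
    }, error = function(e) {
      tibble(model = NA_character_, slope = NA_real_, intercept = NA_real_,
             A = NA_real_, B = NA_real_, r = NA_real_, rss = NA_real_,
             n = NA_integer_, n_excluded = NA_integer_, f_stat = NA_real_,
             p_value = NA_real_, note = conditionMessage(e))
    })
    bind_cols(trait = trait, meta, res)
  }

  tidyr::expand_grid(cell = cells, trait = traits) |>
    pmap(function(cell, trait) fit_cell(cell, trait)) |>
    list_rbind() |>
    arrange(.data$trait, .data$season, .data$color, .data$replication,
            .data$harvest)
}
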