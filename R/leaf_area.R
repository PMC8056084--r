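#' Interpolate a leaf-area trajectory over thermal time
#'
#' Leaf area is measured only at harvests, but daily light absorption needs a
#' leaf area for every day. The trajectory is reconstructed on the thermal-time
#' axis from two or three anchors: a small seedling leaf area at treatment
#' start (day 0), and the measured leaf areas at the intermediate and final
#' harvests.
#'
#' With three anchors, a single log-linear regression `ln(LA) = a + b * TT` is
#' fitted through all three points and back-transformed to an exponential
#' trajectory. If that exponential misses either *measured* anchor by more
#' than `deviation_threshold` (relative error on the natural scale, default
#' 25%), the trajectory is refitted as two exact log-linear segments
#' (start to intermediate, intermediate to final), each passing through its
#' two anchors exactly. With two anchors the single exact segment is used.
#'
#' @param anchors A data frame with columns `tt` (cumulative thermal time, Cd,
#'   strictly increasing) and `leaf_area_m2` (> 0), 2 or 3 rows ordered in
#'   time. The first row is the day-0 seedling anchor.
#' @param tt_daily Cumulative thermal time per day at which to evaluate the
#'   trajectory (typically `thermal_time(env)$tt_cum`).
#' @param deviation_threshold Relative-deviation trigger for the two-segment
#'   fallback; `Inf` forces the three-point exponential.
#' @return An object of class `leaf_area_trajectory`: a tibble with columns
#'   `day`, `tt`, `leaf_area_m2`, carrying attributes `method`
#'   (`"three_point_exponential"` or `"two_segment"`), `anchor_deviation`
#'   (max relative deviation at the measured anchors under the single
#'   exponential) and `coefficients`.
#' @export
interpolate_leaf_area <- function(anchors, tt_daily,
                                  deviation_threshold = 0.25) {
  if (!is.data.frame(anchors) ||
      !all(c("tt", "leaf_area_m2") %in% names(anchors))) {
    abort("`anchors` needs columns `tt` and `leaf_area_m2`.",
          class = "lueled_error_domain")
  }
  n <- nrow(anchors)
  if (!n %in% c(2L, 3L)) {
    abort("`anchors` must have 2 or 3 rows.", class = "lueled_error_domain")
  }
  if (any(diff(anchors$tt) <= 0)) {
    abort("Anchor thermal times must be strictly increasing.",
          class = "lueled_error_domain")
  }
  if (any(anchors$leaf_area_m2 <= 0)) {
    abort("Anchor leaf areas must be positive (log-scale fit).",
          class = "lueled_error_domain")
  }

  tt_a <- anchors$tt
  la_a <- anchors$leaf_area_m2
  log_la <- log(la_a)

  # closed-form OLS of log(LA) on TT through all anchors
  b <- sum((tt_a - mean(tt_a)) * (log_la - mean(log_la))) /
    sum((tt_a - mean(tt_a))^2)
  a <- mean(log_la) - b * mean(tt_a)

  deviation <- 0
  method <- "three_point_exponential"
  if (n == 3L) {
    pred <- exp(a + b * tt_a[2:3])
    deviation <- max(abs(pred - la_a[2:3]) / la_a[2:3])
  }

  if (n == 2L || deviation > deviation_threshold) {
    method <- if (n == 2L) "two_point_exponential" else "two_segment"
    # exact log-linear segments through consecutive anchor pairs
    seg <- function(tt) {
      i <- pmin(findInterval(tt, tt_a, rightmost.closed = TRUE), n - 1L)
      i <- pmax(i, 1L)
      b_i <- (log_la[i + 1L] - log_la[i]) / (tt_a[i + 1L] - tt_a[i])
      exp(log_la[i] + b_i * (tt - tt_a[i]))
    }
    la_daily <- seg(tt_daily)
    coefs <- list(anchors = anchors)
  } else {
    la_daily <- exp(a + b * tt_daily)
    coefs <- list(intercept = a, slope = b)
  }

  out <- tibble(
    day = seq_along(tt_daily),
    tt = tt_daily,
    leaf_area_m2 = la_daily
  )
  structure(out,
            class = c("leaf_area_trajectory", class(out)),
            method = method,
            anchor_deviation = deviation,
            coefficients = coefs)
}

#' @export
print.leaf_area_trajectory <- function(x, ...) {
  cat("<leaf_area_trajectory> method:", attr(x, "method"),
      sprintf("(max anchor deviation %.1f%%)\n",
              100 * attr(x, "anchor_deviation")))
  NextMethod()
}

#' @rdname interpolate_leaf_area
#' @param x A `leaf_area_trajectory`.
#' @param ground_area_m2 Ground area per plant, m2 (default 0.002025).
#' @param ... Unused.
#' @details `autoplot()` shows the daily trajectory with the anchors when the
#'   two-segment method was used.
#' @export
trajectory_lai <- function(x, ground_area_m2 = 0.002025) {
  stopifnot(inherits(x, "leaf_area_trajectory"))
  x$leaf_area_m2 / ground_area_m2
}

#' @rdname interpolate_leaf_area
#' @param object A `leaf_area_trajectory`.
#' @export
autoplot.leaf_area_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tt,
                                       y = .data$leaf_area_m2 * 1e4)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(
      x = "Thermal time (°Cd)", y = expression(Leaf~area~(cm^2)),
      subtitle = paste("Interpolation:", attr(object, "method"))
    ) +
    ggplot2::theme_minimal()
}
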