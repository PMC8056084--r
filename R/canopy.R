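#' Thermal time (growing degree days)
#'
#' Accumulates daily mean temperature excess over a base temperature, the
#' developmental clock used to interpolate leaf area between harvests. For
#' basil the base temperature is 11 C. Daily increments are floored at zero
#' (McMaster-Wilhelm convention), so the cumulative sum is non-decreasing.
#'
#' @param env A data frame of daily environments with at least `mean_temp_C`,
#'   ordered by day.
#' @param t_base Base temperature, C (default 11).
#' @return The input tibble with columns `daily_gdd` (Cd) and `tt_cum`
#'   (cumulative Cd) appended.
#' @examples
#' thermal_time(tibble::tibble(mean_temp_C = c(19.3, 10, 21)))
#' @export
thermal_time <- function(env, t_base = 11) {
  if (!is.data.frame(env) || nrow(env) == 0 || !"mean_temp_C" %in% names(env)) {
    abort("`env` must be a non-empty data frame with `mean_temp_C`.",
          class = "lueled_error_domain")
  }
  env <- as_tibble(env)
  env$daily_gdd <- pmax(0, env$mean_temp_C - t_base)
  env$tt_cum <- cumsum(env$daily_gdd)
  env
}

#' Daily light absorption of a canopy (Beer-Lambert)
#'
#' The fraction of incident light a canopy intercepts grows with leaf area
#' index as `1 - exp(-k * LAI)`; the daily absorbed light is that fraction of
#' the daily incident light integral above the plant. `k` is the canopy light
#' extinction coefficient, 0.8 for basil.
#'
#' @param I Daily incident light above the plant, MJ m-2 d-1 (natural plus
#'   supplemental, in the same waveband). Vectorized.
#' @param lai Leaf area index, m2 leaf per m2 ground (>= 0).
#' @param k Extinction coefficient (> 0).
#' @return Absorbed light, MJ m-2 d-1, bounded by \[0, I\).
#' @examples
#' daily_absorbed_light(2, 1, 0.8) # 2 * (1 - exp(-0.8))
#' @export
daily_absorbed_light <- function(I, lai, k = 0.8) {
  if (any(I < 0, na.rm = TRUE) || any(lai < 0, na.rm = TRUE)) {
    abort("`I` and `lai` must be non-negative.", class = "lueled_error_domain")
  }
  if (any(k <= 0)) {
    abort("`k` must be positive.", class = "lueled_error_domain")
  }
  I * (1 - exp(-k * lai))
}

#' Cumulative absorbed light up to a harvest day
#'
#' @param q_daily Daily absorbed light series, MJ m-2 d-1 (all >= 0).
#' @param harvest_day Day (index into the series) up to which to accumulate;
#'   defaults to the whole series. Zero gives an empty period, i.e. 0.
#' @return Total absorbed light Q_total, MJ m-2.
#' @export
cumulative_absorbed <- function(q_daily, harvest_day = length(q_daily)) {
  if (any(q_daily < 0, na.rm = TRUE)) {
    abort("`q_daily` must be non-negative.", class = "lueled_error_domain")
  }
  if (harvest_day > length(q_daily) || harvest_day < 0) {
    abort("`harvest_day` outside the series.", class = "lueled_error_domain")
  }
  if (harvest_day == 0) return(0)
  sum(q_daily[seq_len(harvest_day)])
}

#' Light use efficiency
#'
#' Dry weight produced per unit of light energy absorbed by the canopy over
#' the growing period (g MJ-1).
#'
#' @param dw Shoot dry weight, g (>= 0). Vectorized.
#' @param q_total Total absorbed light, MJ m-2 (> 0).
#' @return LUE, g MJ-1.
#' @export
light_use_efficiency <- function(dw, q_total) {
  if (any(q_total <= 0, na.rm = TRUE)) {
    abort("`q_total` must be positive.", class = "lueled_error_domain")
  }
  dw / q_total
}

#' Energy use efficiency of supplemental lighting
#'
#' Dry weight attributable to the supplemental light, per unit of electrical
#' energy the lamp consumed. The lamp's electrical-to-photon conversion
#' efficacy `mu` (MJ light out per MJ electricity in) converts the received
#' light back to electricity: `EUE = (dw_sl / sl) * mu`. Measured efficacies
#' for the blue, red and white+far-red lamp types are 0.37, 0.63 and 0.37
#' MJ MJ-1 respectively.
#'
#' @param dw_sl Dry weight attributed to supplemental light, g m-2.
#' @param sl Supplemental light received, MJ m-2 (> 0).
#' @param mu Electrical conversion efficacy, MJ MJ-1, in \[0, 1\].
#' @return EUE, g MJ-1; exactly linear in `mu`.
#' @export
energy_use_efficiency <- function(dw_sl, sl, mu) {
  if (any(sl <= 0, na.rm = TRUE)) {
    abort("`sl` must be positive.", class = "lueled_error_domain")
  }
  if (any(mu < 0 | mu > 1, na.rm = TRUE)) {
    abort("`mu` must lie in [0, 1].", class = "lueled_error_domain")
  }
  (dw_sl / sl) * mu
}

#' Dry weight attributed to supplemental light
#'
#' Isolates the supplemental-light contribution to dry weight from a fitted
#' dose-response curve as the difference between the predicted dry weight at
#' the plant's dose and at dose zero, on the natural (gram) scale. Zero dose
#' gives exactly zero by construction; for a monotone increasing fit the
#' result is non-decreasing in dose. This prediction-difference definition is
#' an interpretation: the attribution cannot be measured directly.
#'
#' @param fit A [dose_response_fit] for a dry-weight trait.
#' @param dose Supplemental PPFD dose(s), same units the fit used.
#' @return Supplemental dry weight, g per plant (same unit as the trait).
#' @export
supplemental_dw <- function(fit, dose) {
  stopifnot(inherits(fit, "dose_response_fit"))
  rng <- fit$dose_range
  # dose 0 is exempt: the definition itself anchors there
  if (any((dose > 0 & dose < rng[1] - 1e-9) | dose > rng[2] + 1e-9)) {
    warn("Some doses lie outside the fitted dose range; extrapolating.",
         class = "lueled_warning_extrapolation")
  }
  predict(fit, dose, scale = "natural") - predict(fit, 0, scale = "natural")
}
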