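#' Validate a spectrum table
#'
#' A spectrum is a two-column table of spectral photon flux density on an
#' ascending wavelength grid: `wavelength_nm` (nm) and `photon_flux`
#' (umol m-2 s-1 nm-1). Instrument grids are used as-is; nothing is resampled.
#'
#' @param spectrum A data frame with columns `wavelength_nm` and `photon_flux`.
#' @return The validated spectrum as a tibble, invisibly usable downstream.
#' @export
validate_spectrum <- function(spectrum) {
  if (!is.data.frame(spectrum)) {
    abort("`spectrum` must be a data frame.", class = "lueled_error_spectrum")
  }
  missing_cols <- setdiff(c("wavelength_nm", "photon_flux"), names(spectrum))
  if (length(missing_cols) > 0) {
    abort(
      paste0("`spectrum` is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "lueled_error_spectrum"
    )
  }
  wl <- spectrum$wavelength_nm
  if (nrow(spectrum) < 2 || any(diff(wl) <= 0)) {
    abort("`wavelength_nm` must be strictly ascending with >= 2 points.",
          class = "lueled_error_spectrum")
  }
  if (any(!is.finite(spectrum$photon_flux)) || any(spectrum$photon_flux < 0)) {
    abort("`photon_flux` must be finite and non-negative.",
          class = "lueled_error_spectrum")
  }
  as_tibble(spectrum)
}

# Trapezoidal integral of photon_flux over [low, high], clipping the first and
# last interval at the band edges (flux is treated as piecewise linear on the
# native grid, so clipping is exact).
band_integral_value <- function(spectrum, low_nm, high_nm) {
  wl <- spectrum$wavelength_nm
  fx <- spectrum$photon_flux
  keep <- wl >= low_nm & wl <= high_nm
  # interpolate flux at the band edges when they fall between grid points
  edge_wl <- setdiff(c(low_nm, high_nm), wl[keep])
  if (length(edge_wl) > 0) {
    edge_fx <- stats::approx(wl, fx, xout = edge_wl)$y
    wl <- c(wl[keep], edge_wl)
    fx <- c(fx[keep], edge_fx)
    o <- order(wl)
    wl <- wl[o]
    fx <- fx[o]
  } else {
    wl <- wl[keep]
    fx <- fx[keep]
  }
  sum(diff(wl) * (head(fx, -1) + tail(fx, -1)) / 2)
}

#' Integrate a spectrum over a wavelength band
#'
#' Computes the photon flux (umol m-2 s-1) carried by a wavelength band, as a
#' trapezoidal integral of spectral photon flux density on the native
#' instrument grid. This is how PPFD over 400-700 nm ("PPFD700") and over
#' 400-800 nm ("PPFD800") are obtained from a measured lamp or sky spectrum.
#'
#' @param spectrum Spectrum table, see [validate_spectrum()].
#' @param low_nm,high_nm Band limits in nm; the spectrum grid must span them.
#' @return A one-row tibble with `band_low_nm`, `band_high_nm` and `value`
#'   (umol m-2 s-1).
#' @examples
#' flat <- tibble::tibble(wavelength_nm = 400:700, photon_flux = 1)
#' integrate_band(flat, 400, 700) # 300 umol m-2 s-1
#' @export
integrate_band <- function(spectrum, low_nm, high_nm) {
  spectrum <- validate_spectrum(spectrum)
  if (!is.numeric(low_nm) || !is.numeric(high_nm) || low_nm >= high_nm) {
    abort("Band limits must be numeric with low_nm < high_nm.",
          class = "lueled_error_band")
  }
  wl <- spectrum$wavelength_nm
  if (low_nm < min(wl) || high_nm > max(wl)) {
    abort(
      sprintf("Band [%g, %g] nm is outside the spectrum grid [%g, %g] nm.",
              low_nm, high_nm, min(wl), max(wl)),
      class = "lueled_error_coverage"
    )
  }
  tibble(
    band_low_nm = low_nm,
    band_high_nm = high_nm,
    value = band_integral_value(spectrum, low_nm, high_nm)
  )
}

#' Red to far-red photon flux ratio of a spectrum
#'
#' Ratio of photon flux in a narrow red band to a narrow far-red band,
#' the phytochrome-relevant descriptor of a light environment. Defaults follow
#' the common convention of 655-665 nm over 725-735 nm; the bands are
#' configurable because instruments and authors differ slightly.
#'
#' @inheritParams integrate_band
#' @param red_band,farred_band Length-2 numeric band limits (nm).
#' @return The dimensionless ratio (scale-invariant in the spectrum).
#' @export
red_farred_ratio <- function(spectrum, red_band = c(655, 665),
                             farred_band = c(725, 735)) {
  red <- integrate_band(spectrum, red_band[1], red_band[2])$value
  fr <- integrate_band(spectrum, farred_band[1], farred_band[2])$value
  if (fr <= 0) {
    abort("Far-red band integral is zero: R:FR ratio undefined.",
          class = "lueled_error_ratio")
  }
  red / fr
}

#' Convert instantaneous PPFD to a daily light integral
#'
#' @param ppfd Photon flux density, umol m-2 s-1 (vectorized, >= 0).
#' @param photoperiod_h Hours of light per day, in \[0, 24\].
#' @return DLI in mol m-2 d-1: `ppfd * photoperiod_h * 3600 * 1e-6`.
#' @examples
#' ppfd_to_dli(230, 18) # 14.904 mol m-2 d-1
#' @export
ppfd_to_dli <- function(ppfd, photoperiod_h) {
  if (any(ppfd < 0, na.rm = TRUE)) {
    abort("`ppfd` must be non-negative.", class = "lueled_error_domain")
  }
  if (any(photoperiod_h < 0 | photoperiod_h > 24, na.rm = TRUE)) {
    abort("`photoperiod_h` must lie in [0, 24].",
          class = "lueled_error_domain")
  }
  ppfd * photoperiod_h * 3600 * 1e-6
}

#' @rdname ppfd_to_dli
#' @param dli Daily light integral, mol m-2 d-1.
#' @export
dli_to_ppfd <- function(dli, photoperiod_h) {
  if (any(dli < 0, na.rm = TRUE) ||
      any(photoperiod_h <= 0 | photoperiod_h > 24, na.rm = TRUE)) {
    abort("`dli` must be >= 0 and `photoperiod_h` in (0, 24].",
          class = "lueled_error_domain")
  }
  dli / (photoperiod_h * 3600 * 1e-6)
}

#' Convert a photon daily light integral to energy
#'
#' Converts mol PAR m-2 d-1 into MJ m-2 d-1 with the standard PAR
#' energy-per-photon factor of 0.219 MJ per mol (Thimijan-Heins convention).
#'
#' @param dli Daily light integral, mol m-2 d-1 (>= 0).
#' @param factor MJ per mol of PAR photons; default 0.219.
#' @return Daily energy integral, MJ m-2 d-1.
#' @export
dli_to_energy <- function(dli, factor = 0.219) {
  if (any(dli < 0, na.rm = TRUE)) {
    abort("`dli` must be non-negative.", class = "lueled_error_domain")
  }
  dli * factor
}

#' @rdname dli_to_energy
#' @param energy Daily energy integral, MJ m-2 d-1.
#' @export
energy_to_dli <- function(energy, factor = 0.219) {
  if (any(energy < 0, na.rm = TRUE)) {
    abort("`energy` must be non-negative.", class = "lueled_error_domain")
  }
  energy / factor
}

#' Greenhouse light transmission factor
#'
#' Mean over days of the inside/outside PPFD ratio (mean of daily ratios, not
#' ratio of sums), the way a short sensor campaign relates light at plant
#' height to the weather-station reference.
#'
#' @param inside,outside Equal-length daily PPFD (or DLI) series; `outside`
#'   must be strictly positive.
#' @return The dimensionless transmission factor.
#' @export
transmission_factor <- function(inside, outside) {
  if (length(inside) != length(outside) || length(inside) == 0) {
    abort("`inside` and `outside` must be non-empty and equal length.",
          class = "lueled_error_domain")
  }
  if (any(outside <= 0)) {
    abort("`outside` values must be strictly positive.",
          class = "lueled_error_domain")
  }
  mean(inside / outside)
}

#' Supplemental to natural light ratio
#'
#' Ratio of the supplemental light sum to the natural light sum over a growing
#' period, the context indicator for supplemental-lighting efficiency: the
#' same lamp dose matters more when natural light is scarce.
#'
#' @param supplemental_sum,natural_sum Light sums over the period (same units,
#'   e.g. mol m-2); `natural_sum` must be positive.
#' @return The dimensionless SL/NL ratio.
#' @export
sl_nl_ratio <- function(supplemental_sum, natural_sum) {
  if (any(natural_sum <= 0)) {
    abort("`natural_sum` must be positive.", class = "lueled_error_domain")
  }
  if (any(supplemental_sum < 0)) {
    abort("`supplemental_sum` must be non-negative.",
          class = "lueled_error_domain")
  }
  supplemental_sum / natural_sum
}

#' Read a spectrum or daily-environment CSV
#'
#' `read_spectrum()` expects columns `wavelength_nm,photon_flux`;
#' `read_daily_environment()` expects
#' `day,mean_temp_C,natural_dli_700,natural_dli_800,photoperiod_h`.
#' Both validate invariants on read (ascending grid, non-negative flux;
#' `natural_dli_800 >= natural_dli_700 >= 0`, photoperiod in \[0, 24\]).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_spectrum <- function(path) {
  validate_spectrum(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_spectrum
#' @export
read_daily_environment <- function(path) {
  validate_daily_environment(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_spectrum
#' @param env A data frame of daily environments to validate in place.
#' @export
validate_daily_environment <- function(env) {
  required <- c("day", "mean_temp_C", "natural_dli_700", "natural_dli_800",
                "photoperiod_h")
  missing_cols <- setdiff(required, names(env))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Daily environment is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "lueled_error_schema"
    )
  }
  if (any(env$natural_dli_700 < 0) ||
      any(env$natural_dli_800 < env$natural_dli_700)) {
    abort("Need natural_dli_800 >= natural_dli_700 >= 0.",
          class = "lueled_error_schema")
  }
  if (any(env$photoperiod_h < 0 | env$photoperiod_h > 24)) {
    abort("`photoperiod_h` must lie in [0, 24].",
          class = "lueled_error_schema")
  }
  as_tibble(env)
}
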