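# Shared fixtures and independent oracles, all built in code.

# flat spectrum: `level` umol m-2 s-1 nm-1 on a 1-nm grid
flat_spectrum <- function(low = 380, high = 820, level = 1) {
  tibble::tibble(wavelength_nm = low:high, photon_flux = level)
}

# triangular peak with vertices (a, 0), (b, h), (c, 0); zero elsewhere
triangle_spectrum <- function(a = 500, b = 550, c = 620, h = 2,
                              low = 380, high = 820) {
  wl <- low:high
  up <- wl >= a & wl <= b
  down <- wl > b & wl <= c
  flux <- numeric(length(wl))
  flux[up] <- h * (wl[up] - a) / (b - a)
  flux[down] <- h * (c - wl[down]) / (c - b)
  tibble::tibble(wavelength_nm = wl, photon_flux = flux)
}

# independent layered-canopy oracle: split LAI into m layers, attenuate the
# transmitted beam multiplicatively by exp(-k * L / m) per layer, absorb the
# rest; total absorbed = I * (1 - prod of layer transmissions)
layered_absorption <- function(I, lai, k, m) {
  transmitted <- I
  absorbed <- 0
  for (layer in seq_len(m)) {
    a <- transmitted * (1 - exp(-k * lai / m))
    absorbed <- absorbed + a
    transmitted <- transmitted - a
  }
  absorbed
}

# log-linear dose-response data on the study gradient
loglinear_data <- function(n = 120, alpha = 0.5, beta = 0.15, sigma = 0,
                           doses = NULL) {
  if (is.null(doses)) {
    doses <- lueled::simulate_gradient(
      lueled::simulation_config(n_positions = n)
    )$dose_ppfd
  }
  tibble::tibble(
    dose_ppfd = doses,
    y = exp(alpha + beta * sqrt(doses) + stats::rnorm(length(doses), 0, sigma))
  )
}

# closed-form OLS of y on (1, x) via the normal equations (independent of
# lm/lm.fit); returns c(intercept, slope, rss)
normal_equation_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  c(intercept = intercept, slope = slope, rss = rss)
}

# permute color labels across whole replication x season x color units
# (both harvest records of a unit move together)
permute_colors <- function(records) {
  records |>
    dplyr::group_by(.data$season, .data$replication) |>
    dplyr::mutate(color = factor(sample(levels(.data$color))[as.integer(.data$color)],
                                 levels = levels(.data$color))) |>
    dplyr::ungroup()
}

# tiny complete experiment for pipeline tests
tiny_experiment <- function(n_positions = 6, seed = 101, ...) {
  lueled::simulate_experiment(
    lueled::simulation_config(n_positions = n_positions, ...),
    seed = seed
  )
}
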