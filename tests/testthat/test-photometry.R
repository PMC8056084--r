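test_that("band integration matches hand-computed areas", {
  flat <- flat_spectrum(level = 1)
  expect_equal(integrate_band(flat, 400, 700)$value, 300)
  expect_equal(integrate_band(flat_spectrum(level = 0), 400, 700)$value, 0)
  # triangle with vertices (500,0),(550,2),(620,0): area = 1/2 * 120 * 2
  tri <- triangle_spectrum(500, 550, 620, h = 2)
  expect_equal(integrate_band(tri, 400, 700)$value, 120)
  # trapezoid is exact for piecewise-linear flux, so sub-band areas add
  left <- integrate_band(tri, 500, 550)$value
  right <- integrate_band(tri, 550, 620)$value
  expect_equal(left, 50) # 1/2 * 50 * 2
  expect_equal(right, 70)
})

test_that("band integration is additive over adjacent bands and linear", {
  set.seed(1)
  sp <- flat_spectrum()
  sp$photon_flux <- runif(nrow(sp), 0, 3)
  b700 <- integrate_band(sp, 400, 700)$value
  b7_8 <- integrate_band(sp, 700, 800)$value
  b800 <- integrate_band(sp, 400, 800)$value
  expect_equal(b700 + b7_8, b800, tolerance = 1e-12)
  sp2 <- sp
  sp2$photon_flux <- 3.7 * sp$photon_flux
  expect_equal(integrate_band(sp2, 400, 800)$value, 3.7 * b800,
               tolerance = 1e-12)
  # hence the R:FR ratio is scale invariant
  expect_equal(red_farred_ratio(sp2), red_farred_ratio(sp), tolerance = 1e-12)
})

test_that("band integration validates coverage and spectrum shape", {
  sp <- flat_spectrum(low = 450, high = 650)
  expect_error(integrate_band(sp, 400, 700), class = "lueled_error_coverage")
  bad <- tibble::tibble(wavelength_nm = c(400, 400, 500), photon_flux = 1)
  expect_error(integrate_band(bad, 400, 500), class = "lueled_error_spectrum")
  neg <- tibble::tibble(wavelength_nm = 400:500, photon_flux = -1)
  expect_error(integrate_band(neg, 400, 500), class = "lueled_error_spectrum")
})

test_that("red:far-red ratio behaves on symmetric, design and degenerate spectra", {
  # equal flux in both bands
  expect_equal(red_farred_ratio(flat_spectrum()), 1.0)
  # the white+far-red lamp template is built to the design target of 0.1
  expect_equal(red_farred_ratio(lamp_spectrum("white_fr")), 0.1,
               tolerance = 1e-10)
  # zero far-red flux: undefined
  no_fr <- flat_spectrum()
  no_fr$photon_flux[no_fr$wavelength_nm >= 710] <- 0
  expect_error(red_farred_ratio(no_fr), class = "lueled_error_ratio")
})

test_that("PPFD/DLI/energy conversions are exact and mutually inverse", {
  expect_equal(ppfd_to_dli(123, 0), 0)
  expect_equal(ppfd_to_dli(230, 18), 14.904)
  expect_equal(ppfd_to_dli(1, 1), 0.0036)
  expect_equal(dli_to_energy(0), 0)
  expect_equal(dli_to_energy(10), 2.19)
  # round trips
  ppfd <- c(0.5, 37, 230)
  expect_equal(dli_to_ppfd(ppfd_to_dli(ppfd, 18), 18), ppfd,
               tolerance = 1e-12)
  e <- dli_to_energy(ppfd_to_dli(ppfd, 18))
  expect_equal(dli_to_ppfd(energy_to_dli(e), 18), ppfd, tolerance = 1e-12)
  expect_error(ppfd_to_dli(-1, 18), class = "lueled_error_domain")
  expect_error(ppfd_to_dli(1, 25), class = "lueled_error_domain")
  expect_error(dli_to_energy(-0.1), class = "lueled_error_domain")
})

test_that("transmission factor is the mean of daily ratios", {
  out <- c(100, 200, 150, 80, 120)
  expect_equal(transmission_factor(out, out), 1.0)
  expect_equal(transmission_factor(0.55 * out, out), 0.55)
  inside <- c(50, 120, 60, 48, 54)
  expect_equal(transmission_factor(inside, out), mean(inside / out))
  expect_error(transmission_factor(inside, c(100, 0, 150, 80, 120)),
               class = "lueled_error_domain")
})

test_that("supplemental:natural light ratio is a guarded quotient", {
  expect_equal(sl_nl_ratio(5, 5), 1.0)
  expect_equal(sl_nl_ratio(0, 7), 0)
  expect_equal(sl_nl_ratio(86, 50), 1.72)
  expect_error(sl_nl_ratio(1, 0), class = "lueled_error_domain")
})

test_that("spectrum and environment CSV round trips validate on read", {
  dir <- withr::local_tempdir()
  sp <- lamp_spectrum("red")
  readr::write_csv(sp, file.path(dir, "sp.csv"))
  expect_equal(read_spectrum(file.path(dir, "sp.csv"))$photon_flux,
               sp$photon_flux)
  env <- tibble::tibble(day = 1:3, mean_temp_C = 20, natural_dli_700 = 7,
                        natural_dli_800 = 9, photoperiod_h = 18)
  readr::write_csv(env, file.path(dir, "env.csv"))
  expect_silent(read_daily_environment(file.path(dir, "env.csv")))
  bad <- env
  bad$natural_dli_800 <- 5 # below the 400-700 integral
  readr::write_csv(bad, file.path(dir, "bad.csv"))
  expect_error(read_daily_environment(file.path(dir, "bad.csv")),
               class = "lueled_error_schema")
})
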