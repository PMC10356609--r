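test_that("band ratio averages the acceptor and donor emission bands", {
  scan <- data.frame(wavelength_nm = seq(470, 550, by = 5), intensity = 100)
  expect_equal(band_ratio(scan), 1.0)

  scan2 <- scan
  scan2$intensity[scan2$wavelength_nm >= 525 & scan2$wavelength_nm <= 535] <- 200
  scan2$intensity[scan2$wavelength_nm >= 480 & scan2$wavelength_nm <= 490] <- 100
  expect_equal(band_ratio(scan2), 2.0)

  short <- data.frame(wavelength_nm = seq(470, 520, 5), intensity = 100)
  expect_error(band_ratio(short), "acceptor")
  expect_error(band_ratio(data.frame(wavelength_nm = c(470, 470, 480),
                                     intensity = 1)), "ascending")
})

test_that("noise-free titrations are recovered essentially exactly", {
  conc <- c(0, 10^seq(-8.5, -5.5, length.out = 8))
  tt <- generate_titration(0.6, 1.0, kd = 1e-7, n_hill = 1,
                           concentrations = conc, noise_sd = 0)
  fit <- fit_hill(tt)
  expect_true(fit$converged)
  expect_lt(abs(fit$r_min - 0.6) / 0.6, 1e-6)
  expect_lt(abs(fit$r_max - 1.0) / 1.0, 1e-6)
  expect_lt(abs(fit$kd - 1e-7) / 1e-7, 1e-6)
})

test_that("a flat series is flagged unidentifiable, never silently fitted", {
  flat <- data.frame(concentration = c(0, 1e-8, 1e-7, 1e-6), ratio = 0.8)
  fit <- fit_hill(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$kd))
  expect_match(fit$message, "unidentifiable")
  expect_error(ratio_change(fit), "converge")
})

test_that("kd scales exactly with the concentration axis", {
  conc <- c(0, 10^seq(-8.5, -5.5, length.out = 8))
  tt <- generate_titration(0.6, 1.0, kd = 1e-7, concentrations = conc)
  f1 <- fit_hill(tt)
  tt2 <- tt
  tt2$concentration <- tt2$concentration * 1000
  f2 <- fit_hill(tt2)
  expect_equal(f2$kd / f1$kd, 1000, tolerance = 1e-6)
  expect_equal(f2$r_min, f1$r_min, tolerance = 1e-8)
})

test_that("fitted curves are monotone and not beaten by the generative truth", {
  conc <- c(0, 10^seq(-9, -5, length.out = 9))
  tt <- generate_titration(0.7, 1.3, kd = 3e-7, concentrations = conc,
                           noise_sd = 0, replicates = 2)
  fit <- fit_hill(tt)
  grid <- 10^seq(-10, -4, length.out = 200)
  expect_true(all(diff(fit$fitted(grid)) >= -1e-12))
  rss <- function(rmin, rmax, kd) {
    sum((tt$ratio - hill_response(tt$concentration, rmin, rmax, kd))^2)
  }
  expect_lte(rss(fit$r_min, fit$r_max, fit$kd), rss(0.7, 1.3, 3e-7) + 1e-12)
})

test_that("median kd error stays under 10% across noisy simulations", {
  conc <- c(0, 10^seq(-8.5, -5.5, length.out = 7))
  errs <- vapply(1:60, function(i) {
    tt <- generate_titration(0.6, 1.0, kd = 1e-7, concentrations = conc,
                             noise_sd = 0.01, replicates = 3, seed = 1000 + i)
    f <- fit_hill(tt)
    if (!f$converged) return(NA_real_)
    abs(f$kd - 1e-7) / 1e-7
  }, 0)
  expect_true(all(!is.na(errs)))
  expect_lt(median(errs), 0.10)
})

test_that("free Hill coefficient is recovered when the data demand it", {
  conc <- c(0, 10^seq(-8.5, -5.5, length.out = 9))
  tt <- generate_titration(0.6, 1.0, kd = 1e-7, n_hill = 2,
                           concentrations = conc, noise_sd = 0, replicates = 2)
  fit <- fit_hill(tt, fix_n = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$n_hill - 2) / 2, 1e-4)
  expect_lt(abs(fit$kd - 1e-7) / 1e-7, 1e-4)
})

test_that("ratio change reports signed percent from fitted asymptotes", {
  mk <- function(r_min, r_max) list(r_min = r_min, r_max = r_max, converged = TRUE)
  expect_equal(ratio_change(mk(1.0, 1.67)), 67)
  expect_equal(ratio_change(mk(1.0, 1.0)), 0)
  expect_equal(ratio_change(mk(1.0, 0.8)), -20)
})

test_that("titration tables round-trip through CSV", {
  tt <- generate_titration(0.6, 1.0, kd = 1e-7,
                           concentrations = c(0, 1e-8, 1e-7, 1e-6),
                           noise_sd = 0.01, replicates = 2, seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_titration(tt, path)
  back <- read_titration(path)
  expect_equal(back$concentration, tt$concentration)
  expect_equal(back$ratio, tt$ratio, tolerance = 1e-12)
})
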