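# Biosensor calibration: emission-band ratios from spectral scans and
# single-site Hill fitting of titrations.

#' Emission-band ratio from a spectral scan
#'
#' Computes the acceptor/donor emission-band ratio of a fixed-excitation
#' emission sweep: mean intensity over the acceptor band (525–535 nm by
#' default) divided by mean intensity over the donor band (480–490 nm),
#' bounds inclusive.
#'
#' @param scan Data frame with columns `wavelength_nm` (strictly ascending)
#'   and `intensity` (>= 0).
#' @param acceptor_band,donor_band Numeric length-2 wavelength bounds (nm).
#' @return The band ratio (dimensionless).
#' @export
#' @examples
#' scan <- data.frame(wavelength_nm = seq(470, 550, 5), intensity = 100)
#' band_ratio(scan)  # flat spectrum -> 1
band_ratio <- function(scan, acceptor_band = c(525, 535), donor_band = c(480, 490)) {
  if (!all(c("wavelength_nm", "intensity") %in% names(scan))) {
    stopf("`scan` needs columns wavelength_nm and intensity")
  }
  w <- scan$wavelength_nm
  if (is.unsorted(w, strictly = TRUE)) stopf("wavelengths must be strictly ascending")
  if (any(scan$intensity < 0)) stopf("intensities must be >= 0")
  band_mean <- function(band, name) {
    if (min(w) > band[1L] || max(w) < band[2L]) {
      stopf("scan [%g, %g] nm does not cover the %s band [%g, %g] nm",
            min(w), max(w), name, band[1L], band[2L])
    }
    sel <- w >= band[1L] & w <= band[2L]
    if (!any(sel)) stopf("no samples fall inside the %s band [%g, %g] nm",
                         name, band[1L], band[2L])
    mean(scan$intensity[sel])
  }
  band_mean(acceptor_band, "acceptor") / band_mean(donor_band, "donor")
}

#' Fit a single-site binding isotherm to a titration
#'
#' Least-squares fit of `R(c) = r_min + (r_max - r_min) * c^n / (kd^n + c^n)`
#' to pooled replicate points (Levenberg–Marquardt). With `fix_n = TRUE`
#' (default) the Hill coefficient is held at 1, the single independent
#' binding site model. Concentration 0 is handled exactly (`R(0) = r_min`);
#' no log transform is applied. Starting values: `r_min`/`r_max` from the
#' extreme per-concentration means, `kd` from the concentration whose mean
#' response is closest to their midpoint; bounds keep `kd` in
#' `(0, 10 * max(c)]` and, when free, `n` in `[0.5, 4]`.
#'
#' Degenerate series (no response change, so `kd` is unidentifiable) and
#' optimizer failures are returned with `converged = FALSE` — flagged, never
#' silent.
#'
#' @param series Data frame with columns `concentration` (>= 0, at least 4
#'   distinct values) and `ratio` (> 0); a `replicate` column is allowed and
#'   ignored by the fit (points are pooled).
#' @param fix_n Hold the Hill coefficient at 1?
#' @return An `fq_hill_fit` list: `r_min`, `r_max`, `kd`, `n_hill`,
#'   `se` (named standard errors), `converged`, `message`, `fitted`
#'   (function of concentration), `data`.
#' @export
#' @examples
#' tt <- generate_titration(0.6, 1.0, kd = 1e-7, concentrations =
#'                          c(0, 10^seq(-8.5, -5.5, length.out = 7)))
#' fit <- fit_hill(tt)
#' c(fit$kd, ratio_change(fit))
fit_hill <- function(series, fix_n = TRUE) {
  if (!all(c("concentration", "ratio") %in% names(series))) {
    stopf("`series` needs columns concentration and ratio")
  }
  conc <- as.numeric(series$concentration)
  ratio <- as.numeric(series$ratio)
  if (any(conc < 0)) stopf("concentrations must be >= 0")
  if (any(ratio <= 0)) stopf("ratios must be > 0")
  if (length(unique(conc)) < 4L) {
    stopf("at least 4 distinct concentrations are required for fitting")
  }

  means <- tapply(ratio, conc, mean)
  cvals <- as.numeric(names(means))
  means <- as.numeric(means)
  span <- max(means) - min(means)

  result <- function(r_min, r_max, kd, n_hill, se, converged, message) {
    structure(list(r_min = r_min, r_max = r_max, kd = kd, n_hill = n_hill,
                   se = se, converged = converged, message = message,
                   fitted = function(c) hill_response(c, r_min, r_max, kd, n_hill),
                   data = data.frame(concentration = conc, ratio = ratio)),
              class = "fq_hill_fit")
  }

  if (span <= 1e-9 * max(abs(means), 1)) {
    return(result(mean(means), mean(means), NA_real_, if (fix_n) 1 else NA_real_,
                  c(r_min = NA, r_max = NA, kd = NA),
                  FALSE, "no response change; kd unidentifiable"))
  }

  r_min0 <- min(means)
  r_max0 <- max(means)
  midpoint <- (r_min0 + r_max0) / 2
  pos <- cvals > 0
  kd0 <- cvals[pos][which.min(abs(means[pos] - midpoint))]
  if (!length(kd0) || kd0 <= 0) kd0 <- median(cvals[pos])
  cmax <- max(conc)

  df <- data.frame(conc = conc, ratio = ratio)
  fit <- tryCatch({
    if (fix_n) {
      minpack.lm::nlsLM(
        ratio ~ r_min + (r_max - r_min) * conc / (kd + conc),
        data = df, start = list(r_min = r_min0, r_max = r_max0, kd = kd0),
        lower = c(r_min = 0, r_max = 0, kd = cmax * 1e-12),
        upper = c(r_min = Inf, r_max = Inf, kd = cmax * 10),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14))
    } else {
      minpack.lm::nlsLM(
        ratio ~ r_min + (r_max - r_min) * ifelse(conc == 0, 0, conc^n) /
          (kd^n + ifelse(conc == 0, 0, conc^n)),
        data = df, start = list(r_min = r_min0, r_max = r_max0, kd = kd0, n = 1),
        lower = c(r_min = 0, r_max = 0, kd = cmax * 1e-12, n = 0.5),
        upper = c(r_min = Inf, r_max = Inf, kd = cmax * 10, n = 4),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14))
    }
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    return(result(r_min0, r_max0, NA_real_, if (fix_n) 1 else NA_real_,
                  c(r_min = NA, r_max = NA, kd = NA),
                  FALSE, paste("fit failed:", conditionMessage(fit))))
  }

  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  conv <- isTRUE(fit$convInfo$isConv)
  result(unname(cf["r_min"]), unname(cf["r_max"]), unname(cf["kd"]),
         if (fix_n) 1 else unname(cf["n"]), se, conv,
         if (conv) "converged" else "optimizer did not report convergence")
}

#' @export
print.fq_hill_fit <- function(x, ...) {
  if (is.na(x$kd)) {
    cat(sprintf("<fq_hill_fit> NOT converged: %s\n", x$message))
  } else {
    cat(sprintf("<fq_hill_fit> r_min %.4g, r_max %.4g, kd %.4g, n %.3g (%s); ratio change %+.1f%%\n",
                x$r_min, x$r_max, x$kd, x$n_hill,
                if (x$converged) "converged" else "NOT converged",
                ratio_change(x)))
  }
  invisible(x)
}

#' Emission-ratio change of a fitted sensor
#'
#' The sensor's dynamic range from the fitted asymptotes, in percent:
#' `100 * (r_max - r_min) / r_min`. Signed: negative-ratio-change sensors
#' give negative values.
#'
#' @param fit An `fq_hill_fit` from [fit_hill()] (must have converged).
#' @return Percent ratio change.
#' @export
#' @examples
#' ratio_change(list(r_min = 1, r_max = 1.67, converged = TRUE)) # +67
ratio_change <- function(fit) {
  if (!isTRUE(fit$converged)) stopf("fit did not converge; ratio change undefined")
  100 * (fit$r_max - fit$r_min) / fit$r_min
}

#' Read/write titration tables
#'
#' Titration CSVs use columns `concentration_M`, `replicate`, `ratio`.
#'
#' @param path CSV path.
#' @return `read_titration()`: data frame with columns `concentration`,
#'   `replicate`, `ratio`.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stopf("titration file '%s' does not exist", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!"concentration_M" %in% names(x)) {
    stopf("'%s' lacks the concentration_M column", path)
  }
  data.frame(concentration = x$concentration_M,
             replicate = x$replicate %||% 1L,
             ratio = x$ratio)
}

#' @rdname read_titration
#' @param series Data frame as returned by [generate_titration()].
#' @export
write_titration <- function(series, path) {
  write.csv(data.frame(concentration_M = series$concentration,
                       replicate = series$replicate %||% 1L,
                       ratio = series$ratio),
            path, row.names = FALSE)
  invisible(path)
}
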