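# Thermal-melt analysis: Boltzmann sigmoid fits of variable-temperature CD
# traces, triplicate aggregation, and thermal-phenotype classification of each
# variant x nucleotide pair against wild-type GDP/GTP references.

#' A variable-temperature CD melting curve
#'
#' @param temperature strictly increasing numeric vector, °C.
#' @param signal ellipticity (or normalized folded fraction), same length.
#' @param variant variant name, e.g. `"WT"`, `"R201C"`.
#' @param nucleotide nucleotide state: `"GDP"`, `"GTPgS"` or `"apo"`.
#' @param replicate replicate index.
#' @return an object of class `melting_curve`.
#' @export
melting_curve <- function(temperature, signal, variant = "WT",
                          nucleotide = "GDP", replicate = 1L) {
  if (length(temperature) != length(signal))
    ss_validation_error("signal", "must match length of temperature")
  if (anyNA(temperature) || anyNA(signal))
    ss_validation_error("signal", "missing values are not allowed")
  if (length(temperature) < 10L)
    ss_input_error("melting curve needs >= 10 points")
  if (any(diff(temperature) <= 0))
    ss_validation_error("temperature", "must be strictly increasing")
  structure(list(temperature = as.numeric(temperature),
                 signal = as.numeric(signal),
                 meta = list(variant = variant, nucleotide = nucleotide,
                             replicate = replicate)),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> %s/%s rep %s: %d points, %.1f-%.1f degC\n",
              x$meta$variant, x$meta$nucleotide, x$meta$replicate,
              length(x$temperature), min(x$temperature), max(x$temperature)))
  invisible(x)
}

# Robust noise scale from first differences of the signal; for a slowly
# varying sigmoid the differences are noise-dominated outside the transition.
signal_noise_mad <- function(signal) {
  stats::mad(diff(signal)) / sqrt(2)
}

melt_sse <- function(par, x, y, top = NULL, bottom = NULL) {
  if (is.null(top)) {
    yhat <- boltzmann_sigmoid(x, par[1], par[2], par[3], par[4])
  } else {
    yhat <- boltzmann_sigmoid(x, par[1], par[2], top, bottom)
  }
  sum((y - yhat)^2)
}

#' Fit a melting curve to the Boltzmann sigmoid
#'
#' Least-squares fit of
#' `Y = Bottom + (Top - Bottom) / (1 + exp((V50 - X)/Slope))`, where V50 is
#' the melting temperature T_m (temperature of half-unfolding) and Slope the
#' steepness of the transition. Initialization is deterministic: V50 at the
#' half-amplitude crossing, Slope at one tenth of the temperature range.
#'
#' A fit whose V50 falls outside the data's temperature range, or whose slope
#' is not positive (the signal must run folded -> unfolded, i.e. increase), is
#' flagged `converged = FALSE` rather than silently extrapolated.
#'
#' @param curve a [melting_curve()].
#' @param fix_normalization if `TRUE`, Top and Bottom are fixed at 1 and 0
#'   (signal must already be normalized to folded fraction); otherwise both
#'   are free parameters.
#' @return an object of class `melting_fit` with fields `v50`, `slope`, `top`,
#'   `bottom`, `sse`, `converged`, `covariance` (parameter standard errors,
#'   when available) and the curve's `meta`.
#' @export
fit_melting_curve <- function(curve, fix_normalization = FALSE) {
  if (!inherits(curve, "melting_curve"))
    ss_validation_error("curve", "must be a melting_curve")
  x <- curve$temperature
  y <- curve$signal
  amp <- diff(range(y))
  noise <- signal_noise_mad(y)
  if (noise > 0 && amp < 5 * noise)
    ss_no_transition_error(sprintf(
      "no melting transition: amplitude %.3g < 5 x noise MAD %.3g", amp, noise))
  if (amp == 0)
    ss_no_transition_error("no melting transition: flat signal")

  # deterministic initialization
  y_mid <- min(y) + amp / 2
  v50_0 <- x[which.min(abs(y - y_mid))]
  slope_0 <- diff(range(x)) / 10
  dat <- data.frame(x = x, y = y)

  fit <- NULL
  if (fix_normalization) {
    fit <- tryCatch(stats::nls(
      y ~ 1 / (1 + exp((v50 - x) / slope)), data = dat,
      start = list(v50 = v50_0, slope = slope_0),
      algorithm = "port", lower = c(min(x), 1e-3), upper = c(max(x), 1e3),
      control = stats::nls.control(warnOnly = FALSE)),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(stats::nls(
      y ~ bottom + (top - bottom) / (1 + exp((v50 - x) / slope)), data = dat,
      start = list(v50 = v50_0, slope = slope_0, top = max(y),
                   bottom = min(y)),
      algorithm = "port",
      lower = c(min(x), 1e-3, -Inf, -Inf), upper = c(max(x), 1e3, Inf, Inf),
      control = stats::nls.control(warnOnly = FALSE)),
      error = function(e) NULL)
  }

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    par <- if (fix_normalization) unname(cf[c("v50", "slope")])
           else unname(cf[c("v50", "slope", "top", "bottom")])
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
    converged <- TRUE
  } else {
    # Nelder-Mead fallback on the SSE surface (nls port can report spurious
    # singular convergence on zero-residual data)
    par0 <- if (fix_normalization) c(v50_0, slope_0)
            else c(v50_0, slope_0, max(y), min(y))
    opt <- if (fix_normalization)
      stats::optim(par0, melt_sse, x = x, y = y, top = 1, bottom = 0)
    else stats::optim(par0, melt_sse, x = x, y = y)
    par <- opt$par
    se <- NULL
    converged <- opt$convergence == 0L
  }
  # high-precision quasi-Newton polish (parameter recovery to >= 6 s.f.)
  pol <- if (fix_normalization)
    stats::optim(par, melt_sse, x = x, y = y, top = 1, bottom = 0,
                 method = "BFGS", control = list(reltol = 1e-15, maxit = 500))
  else stats::optim(par, melt_sse, x = x, y = y, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 500))
  par <- pol$par
  v50 <- par[1]; slope <- par[2]
  top <- if (fix_normalization) 1 else par[3]
  bottom <- if (fix_normalization) 0 else par[4]
  sse <- pol$value

  # orientation and range contracts: no extrapolated T_m, no inverted melt
  if (v50 < min(x) || v50 > max(x)) converged <- FALSE
  if (slope <= 0 || top <= bottom) converged <- FALSE

  structure(list(v50 = v50, slope = slope, top = top, bottom = bottom,
                 sse = sse, converged = converged, covariance = se,
                 meta = curve$meta),
            class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf(
    "<melting_fit> %s/%s: Tm = %.2f degC, slope = %.2f, converged = %s\n",
    x$meta$variant, x$meta$nucleotide, x$v50, x$slope, x$converged))
  invisible(x)
}

#' Aggregate replicate melting fits into a T_m summary
#'
#' Mean and sample standard deviation (n-1 denominator) of V50 over the
#' converged fits, the way triplicate melts are conventionally reported.
#'
#' @param fits a list of [fit_melting_curve()] results.
#' @return an object of class `tm_summary` with `tm_mean`, `tm_sd` (`NA` when
#'   only one converged replicate) and `n_replicates`.
#' @export
summarize_tm <- function(fits) {
  if (inherits(fits, "melting_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok))
    ss_aggregation_error("no converged melting fits to summarize")
  v50 <- vapply(fits[ok], function(f) f$v50, numeric(1))
  structure(list(tm_mean = mean(v50),
                 tm_sd = if (length(v50) >= 2) stats::sd(v50) else NA_real_,
                 n_replicates = length(v50)),
            class = "tm_summary")
}

#' @export
print.tm_summary <- function(x, ...) {
  sd_txt <- if (is.na(x$tm_sd)) "NA" else sprintf("%.2f", x$tm_sd)
  cat(sprintf("<tm_summary> Tm = %.2f +/- %s degC (n = %d)\n",
              x$tm_mean, sd_txt, x$n_replicates))
  invisible(x)
}

#' Classify the thermal phenotype of a variant
#'
#' A variant whose GTP-state T_m exceeds its GDP-state T_m by more than the
#' threshold is `nucleotide_responsive` (the wild-type behaviour: ~9 °C shift).
#' Otherwise the variant's overall T_m is compared with the wild-type GDP and
#' GTP reference means: it is `gdp_like` or `gtp_like` by the nearer
#' reference, and `indeterminate` when within the threshold of both (or
#' exactly equidistant).
#'
#' The default threshold is `max(3, 2 * pooled sd)` °C; the pooled sd comes
#' from the variant's own two summaries.
#'
#' @param gdp,gtp [summarize_tm()] summaries for the variant bound to GDP and
#'   to the GTP analog.
#' @param wt_gdp,wt_gtp wild-type reference summaries; `wt_gtp$tm_mean` must
#'   exceed `wt_gdp$tm_mean`.
#' @param threshold °C; `NULL` (default) applies the rule above.
#' @return an object of class `thermal_phenotype` with `delta_tm`, `category`,
#'   `threshold` and the references used.
#' @export
classify_thermal_phenotype <- function(gdp, gtp, wt_gdp, wt_gtp,
                                       threshold = NULL) {
  for (s in list(gdp, gtp, wt_gdp, wt_gtp))
    if (!inherits(s, "tm_summary"))
      ss_validation_error("summaries", "all inputs must be tm_summary objects")
  if (wt_gtp$tm_mean <= wt_gdp$tm_mean)
    ss_config_error("wt_gtp reference Tm must exceed wt_gdp reference Tm")
  if (is.null(threshold)) {
    sds <- c(gdp$tm_sd, gtp$tm_sd)
    pooled <- if (all(is.na(sds))) 0 else sqrt(mean(sds[!is.na(sds)]^2))
    threshold <- max(3, 2 * pooled)
  }
  delta <- gtp$tm_mean - gdp$tm_mean
  if (delta > threshold) {
    category <- "nucleotide_responsive"
  } else {
    tm <- mean(c(gdp$tm_mean, gtp$tm_mean))
    d_gdp <- abs(tm - wt_gdp$tm_mean)
    d_gtp <- abs(tm - wt_gtp$tm_mean)
    if (d_gdp == d_gtp || (d_gdp <= threshold && d_gtp <= threshold)) {
      category <- "indeterminate"
    } else if (d_gdp < d_gtp) {
      category <- "gdp_like"
    } else {
      category <- "gtp_like"
    }
  }
  structure(list(delta_tm = delta, category = category, threshold = threshold,
                 references = list(wt_gdp = wt_gdp, wt_gtp = wt_gtp)),
            class = "thermal_phenotype")
}

#' @export
print.thermal_phenotype <- function(x, ...) {
  cat(sprintf("<thermal_phenotype> delta Tm = %.2f degC -> %s (threshold %.2f)\n",
              x$delta_tm, x$category, x$threshold))
  invisible(x)
}

#' Read melting curves from a CSV file
#'
#' Expects columns `temperature_C`, `signal`, `variant`, `nucleotide`,
#' `replicate`; returns one [melting_curve()] per
#' variant/nucleotide/replicate combination.
#'
#' @param path CSV path.
#' @return a list of melting curves.
#' @export
read_melting_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "signal", "variant", "nucleotide", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ss_input_error(paste("missing columns:", paste(miss, collapse = ", ")))
  key <- interaction(df$variant, df$nucleotide, df$replicate, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$temperature_C), ]
    melting_curve(d$temperature_C, d$signal, variant = d$variant[1],
                  nucleotide = d$nucleotide[1], replicate = d$replicate[1])
  })
}

#' Write melting curves to CSV
#'
#' Inverse of [read_melting_csv()].
#'
#' @param curves list of [melting_curve()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_melting_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(temperature_C = cv$temperature, signal = cv$signal,
               variant = cv$meta$variant, nucleotide = cv$meta$nucleotide,
               replicate = cv$meta$replicate))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
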