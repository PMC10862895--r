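# Nucleotide-exchange kinetics: one-phase association fits of intrinsic
# tryptophan fluorescence traces recorded after GTP-analog addition.

#' A fluorescence exchange trace
#'
#' @param time increasing numeric vector (unit free; `time_unit` records it —
#'   the fitted rate constant is the reciprocal of this unit).
#' @param intensity fluorescence in arbitrary units, same length.
#' @param variant,nucleotide metadata.
#' @param time_unit label for the time axis unit (default `"min"`).
#' @return an object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, intensity, variant = "WT",
                          nucleotide = "GTPgS", time_unit = "min") {
  if (length(time) != length(intensity))
    ss_validation_error("intensity", "must match length of time")
  if (anyNA(time) || anyNA(intensity))
    ss_validation_error("intensity", "missing values are not allowed")
  if (length(time) < 20L)
    ss_input_error("kinetic trace needs >= 20 points")
  if (any(diff(time) <= 0))
    ss_validation_error("time", "must be strictly increasing")
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 meta = list(variant = variant, nucleotide = nucleotide,
                             time_unit = time_unit)),
            class = "kinetic_trace")
}

#' Fit a one-phase association model
#'
#' Least-squares fit of `Y = Y0 + (Plateau - Y0) * (1 - exp(-k * x))`, where
#' Y0 is the intensity at time zero, Plateau the fully equilibrated intensity
#' and k the rate constant in reciprocal time-axis units. Decreasing traces
#' (Plateau < Y0, seen for some loss-of-function variants) are supported: the
#' amplitude goes negative while k stays positive.
#'
#' Initialization is deterministic: Y0 from the first point, Plateau from the
#' mean of the final 5% of points, k from `ln 2 / t_half` with t_half the time
#' of half-amplitude crossing.
#'
#' @param trace a [kinetic_trace()].
#' @return an object of class `kinetic_fit` with `y0`, `plateau`, `k`,
#'   `half_time` (`ln 2 / k`), `sse`, `converged`, and the trace `meta`.
#' @export
fit_one_phase_association <- function(trace) {
  if (!inherits(trace, "kinetic_trace"))
    ss_validation_error("trace", "must be a kinetic_trace")
  x <- trace$time
  y <- trace$intensity
  amp <- diff(range(y))
  noise <- signal_noise_mad(y)
  if (noise > 0 && amp < 5 * noise)
    ss_no_signal_error(sprintf(
      "flat trace: amplitude %.3g < 5 x noise MAD %.3g", amp, noise))
  if (amp == 0) ss_no_signal_error("flat trace: zero amplitude")

  n_tail <- max(1L, ceiling(0.05 * length(y)))
  y0_0 <- y[1]
  plat_0 <- mean(utils::tail(y, n_tail))
  y_half <- y0_0 + (plat_0 - y0_0) / 2
  idx <- if (plat_0 >= y0_0) which(y >= y_half) else which(y <= y_half)
  t_half <- if (length(idx)) x[idx[1]] else stats::median(x)
  if (t_half <= min(x)) t_half <- x[max(2L, which(x > min(x))[1])]
  k_0 <- log(2) / t_half

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(stats::nls(
    y ~ y0 + (plateau - y0) * (1 - exp(-k * x)), data = dat,
    start = list(y0 = y0_0, plateau = plat_0, k = k_0),
    algorithm = "port",
    control = stats::nls.control(warnOnly = FALSE)),
    error = function(e) NULL)

  obj <- function(p) sum((y - one_phase_association(x, p[1], p[2], p[3]))^2)
  if (!is.null(fit)) {
    par <- unname(stats::coef(fit)[c("y0", "plateau", "k")])
    converged <- TRUE
  } else {
    opt <- stats::optim(c(y0_0, plat_0, k_0), obj)
    par <- opt$par
    converged <- opt$convergence == 0L
  }
  # high-precision polish
  pol <- stats::optim(par, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  y0 <- pol$par[1]; plateau <- pol$par[2]; k <- pol$par[3]
  sse <- pol$value
  if (!is.finite(k) || k <= 0) converged <- FALSE

  structure(list(y0 = y0, plateau = plateau, k = k,
                 half_time = log(2) / k, sse = sse, converged = converged,
                 meta = trace$meta),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> %s: k = %.4g /%s (t1/2 = %.3g %s), amplitude = %.3g, converged = %s\n",
    x$meta$variant, x$k, x$meta$time_unit, x$half_time, x$meta$time_unit,
    x$plateau - x$y0, x$converged))
  invisible(x)
}

#' Read kinetic traces from CSV
#'
#' Expects columns `time_s`, `intensity`, `variant`; times are converted to
#' minutes (the unit in which rate constants are conventionally quoted here).
#'
#' @param path CSV path.
#' @return list of [kinetic_trace()] objects, one per variant.
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity", "variant")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ss_input_error(paste("missing columns:", paste(miss, collapse = ", ")))
  lapply(split(df, df$variant), function(d) {
    d <- d[order(d$time_s), ]
    kinetic_trace(d$time_s / 60, d$intensity, variant = d$variant[1],
                  time_unit = "min")
  })
}
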