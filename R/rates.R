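#' Reactor geometry and conditions
#'
#' Defaults describe the 1.15 L consortium bioreactors: 0.92 L liquid and a
#' 230 mL headspace, run at room temperature (295 K) and ambient pressure.
#'
#' @param v_liquid Liquid volume, L.
#' @param v_headspace Headspace volume, L.
#' @param temperature Temperature, K.
#' @param pressure_total Total pressure, atm.
#' @param v_total Optional stated total vessel volume, L; when given it must
#'   equal `v_liquid + v_headspace`.
#' @return An object of class `"reactor_config"`.
#' @export
reactor_config <- function(v_liquid = 0.92, v_headspace = 0.23,
                           temperature = 295, pressure_total = 1,
                           v_total = NULL) {
  vals <- c(v_liquid = v_liquid, v_headspace = v_headspace,
            temperature = temperature, pressure_total = pressure_total)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("reactor config values must be strictly positive and finite")
  if (!is.null(v_total) &&
      abs(v_total - (v_liquid + v_headspace)) > 1e-9 * v_total)
    stop("v_liquid + v_headspace must equal the stated total vessel volume")
  structure(list(v_liquid = v_liquid, v_headspace = v_headspace,
                 temperature = temperature, pressure_total = pressure_total),
            class = "reactor_config")
}

#' Read a reactor configuration from YAML or JSON
#'
#' @param path File with any subset of the [reactor_config()] fields.
#' @return A `"reactor_config"`.
#' @export
read_reactor_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(reactor_config, cfg[intersect(names(cfg),
                                        names(formals(reactor_config)))])
}

#' Time series of one analyte in one phase
#'
#' @param analyte Identifier, e.g. `"NO3"`, `"C3H8"`.
#' @param times Sampling times in days, strictly increasing.
#' @param values Measurements: mmol N/L for liquid nitrogen species, mmol/L
#'   for other liquid analytes, atm partial pressure for gas analytes.
#' @param phase `"liquid"` or `"gas"`.
#' @param unit Declared unit string; defaults to `"mmol N/L"` for liquid and
#'   `"atm"` for gas.
#' @param noise_tol Values are required to exceed `-noise_tol` (slightly
#'   negative readings are measurement noise, not valid signals).
#' @return An object of class `"concentration_series"`.
#' @export
concentration_series <- function(analyte, times, values,
                                 phase = c("liquid", "gas"), unit = NULL,
                                 noise_tol = Inf) {
  phase <- match.arg(phase)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("series '", analyte, "': times and values lengths differ")
  if (length(times) && any(diff(times) <= 0))
    stop("series '", analyte, "': times must be strictly increasing")
  if (is.finite(noise_tol) && any(values < -noise_tol))
    stop("series '", analyte, "': values below the noise tolerance")
  if (is.null(unit)) unit <- if (phase == "gas") "atm" else "mmol N/L"
  if (phase == "gas" && unit != "atm")
    stop("series '", analyte, "': gas-phase series must be in atm")
  structure(list(analyte = analyte, phase = phase, times = times,
                 values = values, unit = unit),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<series> %s (%s, %s): %d points over %.3g d\n", x$analyte,
              x$phase, x$unit, length(x$times),
              if (length(x$times)) diff(range(x$times)) else 0))
  invisible(x)
}

#' Split a series into batch cycles at substrate re-spikes
#'
#' A new cycle starts wherever consecutive values jump by more than
#' `spike_threshold` times the series maximum (re-spikes approximately
#' restore the initial concentration, so the default threshold of 0.25 is
#' conservative). For product series that are flushed down at cycle starts
#' (dinitrogen gas), use `direction = "down"` to split at downward jumps.
#' Windows shorter than 3 points are dropped.
#'
#' @param series A [concentration_series()].
#' @param spike_threshold Fraction of `max(values)` a jump must exceed.
#' @param direction Detect upward (default) or downward jumps.
#' @return List of cycle windows, each a list with integer `start`/`end`
#'   (inclusive indices); empty list for an empty series.
#' @export
segment_cycles <- function(series, spike_threshold = 0.25,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  v <- series$values
  if (length(v) == 0L) return(list())
  jumps <- diff(v) * (if (direction == "down") -1 else 1)
  breaks <- which(jumps > spike_threshold * max(abs(v)))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(v))
  out <- Map(function(s, e) list(start = s, end = e), starts, ends)
  Filter(function(w) w$end - w$start >= 2L, out)
}

#' Least-squares rate from one cycle window
#'
#' Ordinary least-squares slope of concentration versus time. Consumption
#' appears as a negative slope; the sign is preserved and downstream
#' conversions take magnitudes explicitly.
#'
#' @param series A [concentration_series()].
#' @param window A window from [segment_cycles()]; `NULL` fits the whole
#'   series.
#' @return A list of class `"rate_estimate"`: `analyte`, `phase`, `unit`,
#'   `slope` (unit/day), `stderr`, `r_squared`, `n_points`, `window`.
#' @export
fit_rate <- function(series, window = NULL) {
  if (is.null(window)) window <- list(start = 1L, end = length(series$times))
  idx <- seq.int(window$start, window$end)
  if (length(idx) < 3L) stop("rate fit needs at least 3 points")
  t <- series$times[idx]; y <- series$values[idx]
  if (diff(range(t)) == 0) stop("singular fit: no spread in time")
  fit <- stats::lm(y ~ t)
  # noise-free data triggers lm's perfect-fit warning; handled via r2 below
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  se <- unname(sm$coefficients[2L, 2L])
  r2 <- if (all(abs(y - mean(y)) < .Machine$double.eps^0.5 * max(1, abs(mean(y)))))
    1 else sm$r.squared
  structure(list(analyte = series$analyte, phase = series$phase,
                 unit = series$unit, slope = slope, stderr = se,
                 r_squared = r2, n_points = length(idx), window = window),
            class = "rate_estimate")
}

# gas constant, L atm / (mol K)
.R_GAS <- 0.08206

#' Headspace partial pressure to chemical amount
#'
#' Ideal-gas conversion `n = p V / (R T)` for the reactor headspace.
#'
#' @param partial_pressure atm (>= 0).
#' @param config A [reactor_config()].
#' @return Amount in mmol.
#' @export
gas_to_moles <- function(partial_pressure, config = reactor_config()) {
  if (any(partial_pressure < 0)) stop("partial pressure must be >= 0")
  if (config$temperature <= 0) stop("temperature must be positive")
  partial_pressure * config$v_headspace /
    (.R_GAS * config$temperature) * 1000
}

# inverse: mmol in headspace -> atm
moles_to_pressure <- function(mmol, config) {
  mmol / 1000 * .R_GAS * config$temperature / config$v_headspace
}

#' Convert a fitted slope to a per-reactor rate
#'
#' Liquid analytes: slope (mmol/L/d) times liquid volume. Gas analytes:
#' slope (atm/d) through the ideal-gas conversion. The returned rate is the
#' magnitude, with the direction (consumption for negative slopes,
#' production for positive) reported alongside, matching the convention
#' that consumption and production rates are quoted as positive numbers.
#'
#' @param estimate A `"rate_estimate"` from [fit_rate()].
#' @param config A [reactor_config()].
#' @return A list of class `"reactor_rate"`: `analyte`, `rate` (mmol/d,
#'   or mmol N/d for nitrogen analytes), `stderr` (same units),
#'   `direction` (`"consumption"`, `"production"` or `"none"`).
#' @export
to_reactor_rate <- function(estimate, config = reactor_config()) {
  stopifnot(inherits(estimate, "rate_estimate"))
  scale <- if (estimate$phase == "gas") {
    if (estimate$unit != "atm") stop("gas-phase estimate must be in atm/d")
    gas_to_moles(1, config)
  } else {
    if (!grepl("mmol", estimate$unit)) stop("liquid-phase estimate must be in mmol per L per d")
    config$v_liquid
  }
  direction <- if (estimate$slope < 0) "consumption"
               else if (estimate$slope > 0) "production" else "none"
  structure(list(analyte = estimate$analyte,
                 rate = abs(estimate$slope) * scale,
                 stderr = estimate$stderr * scale,
                 direction = direction),
            class = "reactor_rate")
}

#' Read long-format series CSV
#'
#' Expects columns `time_d`, `analyte`, `phase`, `value`, `unit`, as written
#' by [write_fixture()].
#'
#' @param path CSV file path.
#' @return Named list of [concentration_series()], one per analyte.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_d", "analyte", "phase", "value", "unit")
  if (!all(need %in% names(df)))
    stop("series CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$analyte), function(d) {
    d <- d[order(d$time_d), ]
    concentration_series(d$analyte[1L], d$time_d, d$value,
                         phase = d$phase[1L], unit = d$unit[1L])
  })
  out[unique(df$analyte)]
}

#' Per-cycle rate table for a set of series
#'
#' Segments the reference analyte's series into cycles (its re-spikes mark
#' cycle starts for the whole reactor), fits an OLS rate per analyte per
#' cycle, and converts to per-reactor rates. All series must share the
#' sampling grid of the reference analyte.
#'
#' @param series_list Named list of [concentration_series()].
#' @param config A [reactor_config()].
#' @param reference Analyte whose re-spikes define the cycles.
#' @param spike_threshold Passed to [segment_cycles()].
#' @return Data frame with one row per analyte per cycle: slope, stderr,
#'   r_squared, n_points, rate (mmol/d magnitude) and direction.
#' @export
cycle_rates <- function(series_list, config = reactor_config(),
                        reference = "NO3", spike_threshold = 0.25) {
  if (!reference %in% names(series_list))
    stop("reference analyte '", reference, "' not among the series")
  windows <- segment_cycles(series_list[[reference]], spike_threshold)
  if (length(windows) == 0L) stop("no usable cycles in reference series")
  rows <- list()
  for (nm in names(series_list)) {
    s <- series_list[[nm]]
    for (k in seq_along(windows)) {
      est <- fit_rate(s, windows[[k]])
      rr <- to_reactor_rate(est, config)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = nm, cycle = k, slope = est$slope, stderr = est$stderr,
        r_squared = est$r_squared, n_points = est$n_points,
        rate_mmol_d = rr$rate, stderr_mmol_d = rr$stderr,
        direction = rr$direction, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
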