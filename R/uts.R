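#' Uniform time series
#'
#' The universal currency between all stages of the package: a uniformly
#' sampled physical waveform (pressure, area, flow or wave speed) with an
#' explicit time origin, sample interval and unit label. All internal
#' computation is in SI units (Pa, m^2, m^3/s, m/s, s); mmHg and mm appear
#' only at I/O and reporting boundaries.
#'
#' @param values Numeric vector of samples; all values must be finite.
#' @param dt Sample interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param quantity One of `"pressure"`, `"area"`, `"flow"`, `"pwv"`.
#' @param units Unit string carried as metadata (e.g. `"Pa"`, `"m2"`).
#'
#' @return An object of class `uts`.
#' @export
#' @examples
#' p <- uts(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.001,
#'          quantity = "pressure", units = "Pa")
#' uts_time(p)[1:3]
uts <- function(values, dt, t0 = 0, quantity = c("pressure", "area", "flow", "pwv"),
                units = "") {
  quantity <- match.arg(quantity)
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (length(values) < 1L) {
    stop("`values` must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all `values` must be finite", call. = FALSE)
  }
  structure(
    list(t0 = as.numeric(t0), dt = dt, values = values,
         quantity = quantity, units = units),
    class = "uts"
  )
}

#' @export
print.uts <- function(x, ...) {
  cat(sprintf("<uts> %s [%s]: %d samples, dt = %g s, t0 = %g s\n",
              x$quantity, x$units, length(x$values), x$dt, x$t0))
  cat(sprintf("  range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.uts <- function(x) length(x$values)

#' Sample times of a uniform time series
#'
#' @param x A [uts] object.
#' @return Numeric vector `t0 + (0:(n-1)) * dt`.
#' @export
uts_time <- function(x) {
  stopifnot(inherits(x, "uts"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' Total duration spanned by a series (n * dt)
#' @param x A [uts] object.
#' @return Duration in seconds, counting each sample as one interval.
#' @export
uts_duration <- function(x) {
  stopifnot(inherits(x, "uts"))
  length(x$values) * x$dt
}

stop_if_grid_mismatch <- function(a, b) {
  if (length(a$values) != length(b$values) ||
      abs(a$dt - b$dt) > 1e-12 * max(a$dt, b$dt) ||
      abs(a$t0 - b$t0) > 1e-9) {
    stop("series do not share a common time grid", call. = FALSE)
  }
  invisible(NULL)
}

#' Read a waveform CSV
#'
#' Reads the package's waveform dialect: a comma-separated file with header
#' `time_s,<quantity>_<units>`, '.' decimal separator, one row per sample.
#' The sample interval is inferred from the time column; non-uniform grids
#' (relative jitter above 1e-6) are rejected.
#'
#' @param path Path to an existing CSV file.
#' @return A [uts] object.
#' @seealso [write_waveform_csv()]
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE)
  if (ncol(df) != 2L) {
    stop("waveform CSV must have exactly two columns (time, value)", call. = FALSE)
  }
  tv <- suppressWarnings(as.numeric(df[[1L]]))
  vv <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(tv) || anyNA(vv)) {
    stop("non-numeric cell in waveform CSV: ", path, call. = FALSE)
  }
  if (length(tv) < 2L) stop("waveform CSV needs at least two rows", call. = FALSE)
  dts <- diff(tv)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * dt)) {
    stop("non-uniform time grid in waveform CSV: ", path, call. = FALSE)
  }
  nm <- names(df)[2L]
  # header is "<quantity>_<units>"; units may themselves contain underscores
  parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
  quantity <- parts[1L]
  units <- paste(parts[-1L], collapse = "_")
  if (!quantity %in% c("pressure", "area", "flow", "pwv")) {
    stop("unrecognised quantity in CSV header: ", nm, call. = FALSE)
  }
  uts(vv, dt = dt, t0 = tv[1L], quantity = quantity, units = units)
}

#' Write a waveform CSV
#'
#' Emits the dialect read by [read_waveform_csv()], at full float precision
#' (17 significant digits) so that write -> read is the identity.
#'
#' @param series A valid [uts] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_waveform_csv <- function(series, path) {
  stopifnot(inherits(series, "uts"))
  if (length(series$values) < 1L) stop("empty series", call. = FALSE)
  if (!all(is.finite(series$values))) {
    stop("series contains non-finite values", call. = FALSE)
  }
  tv <- uts_time(series)
  header <- sprintf("time_s,%s_%s", series$quantity, series$units)
  lines <- c(header, sprintf("%.17g,%.17g", tv, series$values))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Extract the final cardiac cycle from a multi-cycle series
#'
#' Returns the last window of length `period` (inclusive start, exclusive
#' end, i.e. `round(period/dt)` samples), re-timed to `t0 = 0`. This is the
#' standard post-processing step once a pulsatile simulation has settled
#' onto its periodic orbit.
#'
#' @param series A [uts] object whose duration is at least `period`.
#' @param period Cycle duration in seconds.
#' @return A [uts] containing the final cycle.
#' @export
extract_last_cycle <- function(series, period) {
  stopifnot(inherits(series, "uts"))
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("`period` must be a single positive number", call. = FALSE)
  }
  n <- length(series$values)
  nw <- round(period / series$dt)
  if (nw < 1L || nw > n) {
    stop("`period` exceeds the series duration", call. = FALSE)
  }
  idx <- (n - nw + 1L):n
  uts(series$values[idx], dt = series$dt, t0 = 0,
      quantity = series$quantity, units = series$units)
}

#' Inner cross-sectional area of a cylindrical vessel
#'
#' @param D Inner diameter in metres (> 0).
#' @return Area `pi * D^2 / 4` in m^2.
#' @export
#' @examples
#' area_from_diameter(2.064e-3) # radial artery at zero pressure
area_from_diameter <- function(D) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("`D` must be positive and finite", call. = FALSE)
  }
  pi * D^2 / 4
}

#' Percent variation between a minimum and maximum value
#'
#' Computes `100 * (vmax - vmin) / vmin`, the min-referenced percent swing
#' used to summarise how much PWV varies within a cardiac cycle.
#'
#' @param vmin Minimum value (> 0).
#' @param vmax Maximum value (>= vmin).
#' @return Percent variation.
#' @export
#' @examples
#' percent_variation(8.33, 9.87) # carotid PWV swing, ~18.5%
percent_variation <- function(vmin, vmax) {
  if (any(vmin <= 0)) stop("`vmin` must be positive", call. = FALSE)
  if (any(vmax < vmin)) stop("`vmax` must be >= `vmin`", call. = FALSE)
  100 * (vmax - vmin) / vmin
}

MMHG_PA <- 133.322387415

#' Convert between mmHg and Pa
#'
#' One mmHg is exactly 133.322387415 Pa; the round trip is exact to 1e-12
#' relative.
#'
#' @param p Pressure value(s).
#' @return Converted pressure value(s).
#' @export
mmhg_to_pa <- function(p) p * MMHG_PA

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(p) p / MMHG_PA
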