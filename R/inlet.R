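#' Parameterised pulsatile inlet flow
#'
#' A smooth canonical arterial inflow pulse built from a constant baseline
#' plus periodised Gaussian bumps (one systolic, one optional dicrotic).
#' The baseline and systolic amplitude are chosen in closed form so that
#' the period mean equals `Q_mean` exactly and the systolic maximum equals
#' `Q_peak`. The periodised Gaussians make the waveform smooth (C-infinity)
#' across the period boundary.
#'
#' @param T_cycle Cardiac period (s).
#' @param Q_mean Mean flow over one period (m^3/s).
#' @param Q_peak Peak systolic flow (m^3/s, >= Q_mean).
#' @param t_peak_frac Systolic peak time as a fraction of the period.
#' @param width_frac Systolic Gaussian width (sd) as a fraction of the period.
#' @param dicrotic_amp Relative amplitude of the dicrotic bump (0 disables).
#' @param dicrotic_time_frac,dicrotic_width_frac Timing and width of the
#'   dicrotic bump as fractions of the period.
#' @return An object of class `inlet_flow_spec`.
#' @export
inlet_flow_spec <- function(T_cycle = 0.8, Q_mean, Q_peak,
                            t_peak_frac = 0.13, width_frac = 0.03,
                            dicrotic_amp = 0.25, dicrotic_time_frac = 0.45,
                            dicrotic_width_frac = 0.08) {
  if (T_cycle <= 0 || Q_mean <= 0) stop("T_cycle and Q_mean must be positive", call. = FALSE)
  if (Q_peak < Q_mean) stop("`Q_peak` must be >= `Q_mean`", call. = FALSE)
  spec <- structure(
    list(T_cycle = T_cycle, Q_mean = Q_mean, Q_peak = Q_peak,
         t_peak_frac = t_peak_frac, width_frac = width_frac,
         dicrotic_amp = dicrotic_amp, dicrotic_time_frac = dicrotic_time_frac,
         dicrotic_width_frac = dicrotic_width_frac),
    class = "inlet_flow_spec")
  # baseline must stay non-negative for a physiological default shape
  tt <- seq(0, T_cycle, length.out = 4097L)[-4097L]
  if (min(inlet_flow_value(spec, tt)) < 0) {
    stop("inlet shape dips below zero flow; reduce Q_peak or widen the pulse",
         call. = FALSE)
  }
  spec
}

# periodised unit-height Gaussian bump shape (systolic + dicrotic)
inlet_bump_shape <- function(spec, t) {
  Tc <- spec$T_cycle
  tp <- spec$t_peak_frac * Tc
  s1 <- spec$width_frac * Tc
  td <- spec$dicrotic_time_frac * Tc
  s2 <- spec$dicrotic_width_frac * Tc
  tm <- t %% Tc
  b <- 0
  for (k in -3:3) {
    b <- b + exp(-0.5 * ((tm - tp - k * Tc) / s1)^2) +
      spec$dicrotic_amp * exp(-0.5 * ((tm - td - k * Tc) / s2)^2)
  }
  b
}

# closed-form period statistics of the bump shape
inlet_bump_stats <- function(spec) {
  Tc <- spec$T_cycle
  mean_b <- sqrt(2 * pi) * (spec$width_frac * Tc +
                              spec$dicrotic_amp * spec$dicrotic_width_frac * Tc) / Tc
  tt <- seq(0, Tc, length.out = 8193L)[-8193L]
  max_b <- max(inlet_bump_shape(spec, tt))
  list(mean = mean_b, max = max_b)
}

#' Evaluate an inlet flow spec at arbitrary times
#'
#' @param spec An [inlet_flow_spec].
#' @param t Time(s) in seconds (wrapped into the period).
#' @return Flow in m^3/s.
#' @export
inlet_flow_value <- function(spec, t) {
  stopifnot(inherits(spec, "inlet_flow_spec"))
  if (spec$Q_peak == spec$Q_mean) return(rep(spec$Q_mean, length(t)))
  st <- inlet_bump_stats(spec)
  c1 <- (spec$Q_peak - spec$Q_mean) / (st$max - st$mean)
  c0 <- spec$Q_mean - c1 * st$mean
  c0 + c1 * inlet_bump_shape(spec, t)
}

#' Synthesise one period of inlet flow
#'
#' @param spec An [inlet_flow_spec].
#' @param dt Sample interval (s).
#' @return A [uts] of quantity `"flow"` spanning exactly one period
#'   (inclusive start, exclusive end).
#' @export
synth_inlet_flow <- function(spec, dt) {
  stopifnot(inherits(spec, "inlet_flow_spec"))
  n <- round(spec$T_cycle / dt)
  tt <- (0:(n - 1L)) * dt
  uts(inlet_flow_value(spec, tt), dt = dt, t0 = 0, quantity = "flow", units = "m3_per_s")
}

#' Default inlet flow specs for the reference arteries
#'
#' Canonical 0.8 s pulses sized to each vessel: mean flows of 0.3 mL/s
#' (radial) and 6.5 mL/s (carotid) with peak flows of 1.2 and 20 mL/s, a
#' systolic peak at 13% of the cycle and a 24 ms upstroke width, in the
#' physiological range for each site.
#'
#' @return An [inlet_flow_spec].
#' @export
inlet_radial <- function() {
  inlet_flow_spec(T_cycle = 0.8, Q_mean = 3.0e-7, Q_peak = 1.2e-6)
}

#' @rdname inlet_radial
#' @export
inlet_carotid <- function() {
  inlet_flow_spec(T_cycle = 0.8, Q_mean = 6.5e-6, Q_peak = 2.0e-5)
}
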