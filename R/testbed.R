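#' Configure the 1D pulse-propagation testbed
#'
#' Bundles everything a deterministic testbed run needs: artery and blood
#' constants, tube law, Windkessel outlet, inlet flow, grid and sampling
#' controls, and the two-station measurement plan. The spatial grid is
#' uniform with `n_nodes` nodes over the vessel length; `dt` is the output
#' sampling interval (1 ms by default) — the explicit solver sub-steps
#' internally so that the advective CFL condition holds at the law's
#' maximum expected wave speed.
#'
#' @param artery An [artery_spec].
#' @param law A [tube_law].
#' @param wk A [wk3_params].
#' @param inlet An [inlet_flow_spec].
#' @param stations A [measurement_plan].
#' @param n_nodes Number of grid nodes (>= 41).
#' @param dt Output sampling interval (s).
#' @param n_cycles Number of cardiac cycles to run (>= 7 recommended for a
#'   cycle-periodic final cycle).
#' @param friction_coefficient Dimensionless velocity-profile factor `Kf`
#'   in the friction term `-Kf (mu/rho) Q/A`; `8*pi` (Poiseuille) by
#'   default, 0 for an inviscid run.
#' @param P_init Initial uniform pressure (Pa); defaults to the law's
#'   reference pressure, which shortens the transient to the periodic
#'   orbit.
#' @param P_max_expected Upper pressure bound (Pa) used to size the
#'   internal CFL sub-step; default 160 mmHg.
#' @return An object of class `testbed_config`.
#' @export
testbed_config <- function(artery, law, wk, inlet,
                           stations = measurement_plan(L_total = artery$L_total),
                           n_nodes = 201L, dt = 1e-3, n_cycles = 8L,
                           friction_coefficient = 8 * pi,
                           P_init = law$P_ref,
                           P_max_expected = mmhg_to_pa(160)) {
  stopifnot(inherits(artery, "artery_spec"), inherits(law, "tube_law"),
            inherits(wk, "wk3_params"), inherits(inlet, "inlet_flow_spec"),
            inherits(stations, "measurement_plan"))
  if (n_nodes < 41L) stop("`n_nodes` must be at least 41", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (n_cycles < 1L) stop("`n_cycles` must be at least 1", call. = FALSE)
  if (stations$x2 >= artery$L_total) {
    stop("stations must lie inside the vessel", call. = FALSE)
  }
  structure(list(artery = artery, law = law, wk = wk, inlet = inlet,
                 stations = stations, n_nodes = as.integer(n_nodes), dt = dt,
                 n_cycles = as.integer(n_cycles),
                 friction_coefficient = friction_coefficient,
                 P_init = P_init, P_max_expected = P_max_expected),
            class = "testbed_config")
}

# Riemann-invariant integral phi(A) = int c(a)/a da tabulated over the
# law's working range (dense cumulative trapezoid).
phi_table <- function(law, rho, n_tab = 4001L) {
  r <- law_range(law)
  A <- seq(r[1L], r[2L], length.out = n_tab)
  f <- analytic_pwv(law, A, rho) / A
  h <- A[2L] - A[1L]
  phi <- c(0, cumsum(0.5 * (f[-1L] + f[-n_tab]) * h))
  list(A = A, phi = phi)
}

# number of internal solver sub-steps per output sample
cfl_substeps <- function(config) {
  law <- config$law
  rho <- config$artery$rho
  r <- law_range(law)
  Pmax <- min(config$P_max_expected, pressure_from_area(law, r[2L], rho))
  A_hi <- area_from_pressure(law, Pmax, rho)
  c_max <- analytic_pwv(law, A_hi, rho)
  A_lo <- area_from_pressure(law, max(config$P_init - mmhg_to_pa(30),
                                      pressure_from_area(law, r[1L], rho)), rho)
  u_max <- config$inlet$Q_peak / A_lo
  dx <- config$artery$L_total / (config$n_nodes - 1L)
  smax <- 1.3 * (c_max + u_max) # safety factor; run-time CFL check remains
  max(1L, as.integer(ceiling(config$dt * smax / (0.9 * dx))))
}

#' Run the 1D nonlinear pulse-propagation testbed
#'
#' Integrates the 1D mass and momentum equations for a compliant tube with
#' the configured tube law, prescribed inlet flow and three-element
#' Windkessel outlet (Richtmyer two-step scheme, characteristic boundary
#' closure), for `n_cycles` cardiac cycles, and returns the ground-truth
#' pressure, area and flow waveforms of the final cycle at the two
#' measurement stations.
#'
#' @param config A [testbed_config].
#' @return A `testbed_dataset`: list with elements `S1` and `S2` (each a
#'   list of `P`, `A`, `Q` [uts] over the final cycle), and `meta`
#'   (periodicity residuals in mmHg per cycle pair, volume-balance fraction
#'   over the final cycle, solver controls, config echo).
#' @export
simulate_pulse_1d <- function(config) {
  stopifnot(inherits(config, "testbed_config"))
  artery <- config$artery
  law <- config$law
  rho <- artery$rho
  dx <- artery$L_total / (config$n_nodes - 1L)

  n_sub <- cfl_substeps(config)
  dt_s <- config$dt / n_sub
  samples_per_cycle <- round(config$inlet$T_cycle / config$dt)
  n_out <- config$n_cycles * samples_per_cycle
  n_steps <- n_out * n_sub

  Qin <- inlet_flow_value(config$inlet, (0:n_steps) * dt_s)
  tab <- phi_table(law, rho)
  A_init <- area_from_pressure(law, config$P_init, rho)

  # station interpolation weights
  xg <- (0:(config$n_nodes - 1L)) * dx
  st_w <- function(x) {
    i <- max(1L, min(config$n_nodes - 1L, findInterval(x, xg)))
    list(i = i - 1L, w = (x - xg[i]) / dx) # 0-based for C++
  }
  s1 <- st_w(config$stations$x1)
  s2 <- st_w(config$stations$x2)

  kinds <- c(constant_pwv = 0L, linear_pwv = 1L, exponential = 2L)
  p <- law$params
  pars <- switch(law$kind,
                 constant_pwv = c(p$c0, 0),
                 linear_pwv = c(p$a, p$b),
                 exponential = c(p$beta, p$gamma))

  out <- solve_pulse_1d_cpp(
    n_nodes = config$n_nodes, dx = dx, dt = dt_s, n_steps = n_steps,
    stride = n_sub, law_kind = kinds[[law$kind]], A_ref = law$A_ref,
    P_ref = law$P_ref, par1 = pars[1L], par2 = pars[2L], rho = rho,
    Kf = config$friction_coefficient, mu = artery$mu,
    Qin = Qin, Rp = config$wk$Rp, Rd = config$wk$Rd, Cc = config$wk$C,
    Pc0 = config$P_init, A_init = A_init, Q_init = Qin[1L],
    A_tab = tab$A, phi_tab = tab$phi,
    i1 = s1$i, w1 = s1$w, i2 = s2$i, w2 = s2$w)

  if (nzchar(out$error)) stop("1D solver: ", out$error, call. = FALSE)

  # periodicity residuals (station S1 pressure, successive cycle pairs)
  cyc <- function(v, k) v[((k - 1L) * samples_per_cycle + 1L):(k * samples_per_cycle)]
  resid <- if (config$n_cycles >= 2L) {
    vapply(2:config$n_cycles, function(k) {
      pa_to_mmhg(max(abs(cyc(out$P1, k) - cyc(out$P1, k - 1L))))
    }, numeric(1L))
  } else numeric(0)

  # volume balance over the final cycle (cycle endpoints are both recorded)
  k <- config$n_cycles
  idx <- ((k - 1L) * samples_per_cycle + 1L):(k * samples_per_cycle)
  idx_cl <- c(idx, idx[length(idx)] + 1L) # closed interval [ (k-1)T, kT ]
  trap <- function(v) sum(0.5 * (v[-1L] + v[-length(v)])) * config$dt
  vol_in <- trap(out$Qin[idx_cl])
  vol_out <- trap(out$Qout[idx_cl])
  dV <- out$Vol[idx_cl[length(idx_cl)]] - out$Vol[idx_cl[1L]]
  stroke <- trap(pmax(out$Qin[idx_cl] - min(out$Qin[idx_cl]), 0))
  vol_balance <- abs(vol_in - vol_out - dV) / max(stroke, vol_in)

  mk_station <- function(Pv, Av, Qv) {
    list(P = uts(Pv[idx], dt = config$dt, quantity = "pressure", units = "Pa"),
         A = uts(Av[idx], dt = config$dt, quantity = "area", units = "m2"),
         Q = uts(Qv[idx], dt = config$dt, quantity = "flow", units = "m3_per_s"))
  }

  structure(list(
    S1 = mk_station(out$P1, out$A1, out$Q1),
    S2 = mk_station(out$P2, out$A2, out$Q2),
    meta = list(
      periodicity_residual_mmhg = if (length(resid)) resid[length(resid)] else NA_real_,
      residual_by_cycle_mmhg = resid,
      volume_balance_fraction = vol_balance,
      n_cycles = config$n_cycles, n_substeps = n_sub, dt_solver = dt_s,
      samples_per_cycle = as.integer(samples_per_cycle),
      separation = config$stations$separation,
      rho = rho, config = config)),
    class = "testbed_dataset")
}

#' @export
print.testbed_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<testbed_dataset> %d samples/cycle, periodicity residual %.3g mmHg, volume balance %.3g\n",
              m$samples_per_cycle, m$periodicity_residual_mmhg, m$volume_balance_fraction))
  cat(sprintf("  S1: P in [%.1f, %.1f] mmHg\n",
              pa_to_mmhg(min(x$S1$P$values)), pa_to_mmhg(max(x$S1$P$values))))
  invisible(x)
}

# periodic fractional-sample shift of a one-cycle waveform (linear interp)
shift_periodic <- function(v, delay_samples) {
  n <- length(v)
  src <- (seq_len(n) - 1) - delay_samples
  i0 <- floor(src)
  w <- src - i0
  ia <- (i0 %% n) + 1L
  ib <- ((i0 + 1) %% n) + 1L
  (1 - w) * v[ia] + w * v[ib]
}

#' Kinematic two-station dataset from a pressure template
#'
#' Fast fixture generator for the estimation chain: station S1 carries the
#' template pressure and the law-consistent area; station S2 carries the
#' same waveform delayed over the station separation, either rigidly at the
#' diastolic wave speed (`pure_delay`) or per-sample at the instantaneous
#' wave speed (`pwv_delay`, which distorts the wave: faster systolic
#' samples arrive relatively earlier). Waveforms are treated as one exact
#' period. Flow is not modelled and is set to zero.
#'
#' @param P_template One cycle of pressure as a [uts] (Pa).
#' @param law A [tube_law] covering the template's pressure range.
#' @param rho Blood density (kg/m^3).
#' @param stations A [measurement_plan].
#' @param mode `"pure_delay"` or `"pwv_delay"`.
#' @param attenuation Fractional amplitude attenuation of the pulsatile
#'   component at S2 (0 = none), applied about the diastolic minimum.
#' @return A `testbed_dataset` (kinematic flavour; `meta$kinematic = TRUE`).
#' @export
kinematic_dataset <- function(P_template, law, rho = 1060,
                              stations = measurement_plan(),
                              mode = c("pure_delay", "pwv_delay"),
                              attenuation = 0) {
  stopifnot(inherits(P_template, "uts"), inherits(law, "tube_law"))
  mode <- match.arg(mode)
  P1 <- P_template$values
  dt <- P_template$dt
  n <- length(P1)
  A1 <- area_from_pressure(law, P1, rho)
  A_d <- A1[which.min(P1)]
  sep <- stations$separation

  if (mode == "pure_delay") {
    delay <- sep / analytic_pwv(law, A_d, rho)
    P2 <- shift_periodic(P1, delay / dt)
  } else {
    # each sample travels at its own wave speed; re-grid the arrivals
    delay_t <- sep / analytic_pwv(law, A1, rho)
    t_arr <- (seq_len(n) - 1) * dt + delay_t
    # periodic extension of the arrival map for interpolation onto the grid
    Tcyc <- n * dt
    t_ext <- c(t_arr - Tcyc, t_arr, t_arr + Tcyc)
    v_ext <- rep(P1, 3L)
    ord <- order(t_ext)
    P2 <- stats::approx(t_ext[ord], v_ext[ord], xout = (seq_len(n) - 1) * dt,
                        ties = "ordered")$y
  }
  if (attenuation > 0) {
    base <- min(P2)
    P2 <- base + (1 - attenuation) * (P2 - base)
  }
  A2 <- area_from_pressure(law, P2, rho)
  q0 <- function() uts(rep(0, n), dt = dt, quantity = "flow", units = "m3_per_s")
  mk <- function(P, A) list(
    P = uts(P, dt = dt, quantity = "pressure", units = "Pa"),
    A = uts(A, dt = dt, quantity = "area", units = "m2"),
    Q = q0())
  structure(list(S1 = mk(P1, A1), S2 = mk(P2, A2),
                 meta = list(kinematic = TRUE, mode = mode,
                             attenuation = attenuation,
                             separation = sep, rho = rho,
                             pwv_d_true = analytic_pwv(law, A_d, rho),
                             samples_per_cycle = as.integer(n))),
            class = "testbed_dataset")
}

#' Write a testbed dataset to CSV files
#'
#' One waveform CSV per series (core dialect) plus a YAML metadata sidecar.
#'
#' @param dataset A `testbed_dataset`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_dataset_csv <- function(dataset, dir, prefix = "dataset") {
  stopifnot(inherits(dataset, "testbed_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (st in c("S1", "S2")) {
    for (q in c("P", "A", "Q")) {
      p <- file.path(dir, sprintf("%s_%s_%s.csv", prefix, st, q))
      write_waveform_csv(dataset[[st]][[q]], p)
      paths <- c(paths, p)
    }
  }
  meta <- dataset$meta
  meta$config <- NULL # config echo serialised separately via scenario config
  mp <- file.path(dir, sprintf("%s_meta.yaml", prefix))
  yaml::write_yaml(meta, mp, precision = 15L)
  invisible(c(paths, mp))
}
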