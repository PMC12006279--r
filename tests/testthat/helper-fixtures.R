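# Shared fixtures: all synthetic, generated in code.

RHO <- 1060

# one-cycle synthetic pressure template (Pa), rotated so the diastolic
# minimum sits early in the cycle and the upstroke does not wrap
synth_pressure_cycle <- function(T_cycle = 0.8, dt = 1e-3,
                                 dbp = 75, sbp = 115, min_frac = 0.05) {
  n <- round(T_cycle / dt)
  tt <- (0:(n - 1)) * dt
  s <- 0
  for (k in -2:2) {
    s <- s + exp(-0.5 * ((tt - 0.20 * T_cycle - k * T_cycle) / (0.07 * T_cycle))^2) +
      0.35 * exp(-0.5 * ((tt - 0.48 * T_cycle - k * T_cycle) / (0.10 * T_cycle))^2)
  }
  s <- (s - min(s)) / (max(s) - min(s))
  shift <- which.min(s) - round(min_frac * n)
  s <- s[((seq_len(n) - 1 + shift) %% n) + 1]
  uts(mmhg_to_pa(dbp + (sbp - dbp) * s), dt = dt,
      quantity = "pressure", units = "Pa")
}

law_const <- function(c0 = 10) {
  tube_law("constant_pwv", A_ref = 3.3e-6, P_ref = mmhg_to_pa(75), c0 = c0)
}

law_linear <- function(a = 8, b = 2e6 / 3.3) {
  tube_law("linear_pwv", A_ref = 3.3e-6, P_ref = mmhg_to_pa(75), a = a, b = b)
}

area_series <- function(law, P, rho = RHO) {
  uts(area_from_pressure(law, P$values, rho), dt = P$dt, t0 = P$t0,
      quantity = "area", units = "m2")
}

# memoised default-scenario simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())

cached_dataset <- function(artery) {
  key <- paste0("ds_", artery)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_pulse_1d(default_scenario(artery))
  }
  .sim_cache[[key]]
}

cached_benchmark <- function(artery) {
  key <- paste0("bm_", artery)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_benchmark(cached_dataset(artery))
  }
  .sim_cache[[key]]
}

cached_halved_dataset <- function(artery) {
  key <- paste0("dsh_", artery)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_pulse_1d(
      default_scenario(artery, n_nodes = 401L, dt = 5e-4))
  }
  .sim_cache[[key]]
}
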