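test_that("constant inflow relaxes to the Windkessel steady state", {
  art <- artery_radial()
  law <- law_const(c0 = 10)
  Q <- 3e-7
  sp <- split_resistances(mmhg_to_pa(90) / Q, RHO, 10, law$A_ref)
  wk <- wk3_params(sp$Rp, sp$Rd, C = 0.05 / (sp$Rp + sp$Rd)) # tau = 50 ms
  inlet <- inlet_flow_spec(T_cycle = 0.8, Q_mean = Q, Q_peak = Q)
  cfg <- testbed_config(art, law, wk, inlet, n_cycles = 2L,
                        friction_coefficient = 0, P_init = mmhg_to_pa(85))
  ds <- simulate_pulse_1d(cfg)
  P_target <- Q * (wk$Rp + wk$Rd)
  expect_equal(tail(ds$S1$P$values, 1), P_target, tolerance = 5e-3)
  expect_equal(tail(ds$S2$P$values, 1), P_target, tolerance = 5e-3)
  # inviscid steady state: pressure uniform along the vessel
  expect_equal(tail(ds$S1$P$values, 1), tail(ds$S2$P$values, 1),
               tolerance = 1e-4)
})

test_that("constant-speed law propagates the foot at c0 between stations", {
  art <- artery_radial()
  law <- law_const(c0 = 10)
  Q <- 3e-7
  sp <- split_resistances(mmhg_to_pa(90) / Q, RHO, 10, law$A_ref)
  wk <- wk3_params(sp$Rp, sp$Rd, C = 3e-11)
  cfg <- testbed_config(art, law, wk, inlet_radial(), n_cycles = 6L)
  ds <- simulate_pulse_1d(cfg)
  pw <- suppressWarnings(estimate_pwvd(ds$S1$A, ds$S2$A, ds$meta$separation))
  delay <- attr(pw, "delay_s")
  expect_lt(abs(delay - ds$meta$separation / 10), 2e-3) # within 2 samples
})

test_that("default scenarios conserve volume and reach cycle periodicity", {
  for (a in c("radial", "carotid")) {
    ds <- cached_dataset(a)
    expect_lt(ds$meta$volume_balance_fraction, 0.01, label = a)
    expect_lt(ds$meta$periodicity_residual_mmhg, 0.5, label = a)
    # residual decays monotonically over the final cycles
    r <- ds$meta$residual_by_cycle_mmhg
    expect_true(all(diff(r) <= 1e-9), label = a)
    # all three series share the grid
    for (st in c("S1", "S2")) {
      expect_identical(length(ds[[st]]$P), ds$meta$samples_per_cycle)
      expect_identical(length(ds[[st]]$A), ds$meta$samples_per_cycle)
      expect_identical(length(ds[[st]]$Q), ds$meta$samples_per_cycle)
    }
  }
})

test_that("station pressures are grid-converged to below 1%", {
  for (a in c("radial", "carotid")) {
    d1 <- cached_dataset(a)
    d2 <- cached_halved_dataset(a)
    for (st in c("S1", "S2")) {
      p1 <- d1[[st]]$P$values
      p2 <- d2[[st]]$P$values[seq(1, length(d2[[st]]$P$values), by = 2)]
      expect_lt(max(abs(p1 - p2)) / mean(p1), 0.01, label = paste(a, st))
    }
  }
})

test_that("simulated pressure and area are consistent with the tube law", {
  ds <- cached_dataset("radial")
  law <- tube_law_radial()
  # station values are linear interpolations of node values, so P(interp A)
  # and interp P differ by the law's curvature over one cell
  expect_equal(ds$S1$P$values,
               pressure_from_area(law, ds$S1$A$values, RHO),
               tolerance = 1e-6)
})

test_that("pure-delay kinematic datasets shift the waveform rigidly", {
  P <- synth_pressure_cycle()
  law <- tube_law_radial()
  kd <- kinematic_dataset(P, law, RHO, mode = "pure_delay")
  expect_true(kd$meta$kinematic)
  delay <- kd$meta$separation / kd$meta$pwv_d_true
  # S2 equals S1 shifted by the construction delay (periodic interpolation)
  n <- length(P)
  src <- ((seq_len(n) - 1) - delay / P$dt)
  i0 <- floor(src); w <- src - i0
  expected <- (1 - w) * P$values[(i0 %% n) + 1] + w * P$values[((i0 + 1) %% n) + 1]
  expect_equal(kd$S2$P$values, expected, tolerance = 1e-12)
})

test_that("pwv_delay equals pure_delay for a constant-speed law", {
  P <- synth_pressure_cycle()
  law <- law_const(10)
  a <- kinematic_dataset(P, law, RHO, mode = "pure_delay")
  b <- kinematic_dataset(P, law, RHO, mode = "pwv_delay")
  expect_equal(a$S2$P$values, b$S2$P$values, tolerance = 1e-9)
})

test_that("pwv_delay advances the systole relative to the foot", {
  P <- synth_pressure_cycle()
  law <- tube_law_radial()
  A1 <- area_series(law, P)
  d_foot <- 0.06 / analytic_pwv(law, A1$values[which.min(P$values)], RHO)
  d_sys <- 0.06 / analytic_pwv(law, A1$values[which.max(P$values)], RHO)
  expect_lt(d_sys, d_foot)
  kd <- kinematic_dataset(P, law, RHO, mode = "pwv_delay")
  # systolic peak at S2 arrives earlier than a rigid foot-speed shift
  t_peak_s2 <- (which.max(kd$S2$P$values) - 1) * P$dt
  t_peak_s1 <- (which.max(P$values) - 1) * P$dt
  expect_lt(t_peak_s2 - t_peak_s1, d_foot)
  expect_gt(t_peak_s2 - t_peak_s1, 0)
})

test_that("attenuation shrinks the pulsatile component about the trough", {
  P <- synth_pressure_cycle()
  law <- law_const(10)
  kd <- kinematic_dataset(P, law, RHO, mode = "pure_delay", attenuation = 0.2)
  full <- kinematic_dataset(P, law, RHO, mode = "pure_delay")
  expect_equal(max(kd$S2$P$values) - min(kd$S2$P$values),
               0.8 * (max(full$S2$P$values) - min(full$S2$P$values)),
               tolerance = 1e-9)
})

test_that("dataset CSV export round-trips through the core dialect", {
  dir <- withr::local_tempdir()
  ds <- cached_dataset("radial")
  write_dataset_csv(ds, dir, prefix = "radial")
  r <- read_waveform_csv(file.path(dir, "radial_S1_P.csv"))
  expect_identical(r$values, ds$S1$P$values)
  meta <- yaml::read_yaml(file.path(dir, "radial_meta.yaml"))
  expect_equal(meta$volume_balance_fraction, ds$meta$volume_balance_fraction)
})

test_that("scenario configs survive a YAML round trip", {
  cfg <- default_scenario("carotid")
  p <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, p)
  r <- read_scenario_config(p)
  expect_equal(r$wk$Rp, cfg$wk$Rp, tolerance = 1e-12)
  expect_equal(r$law$params, cfg$law$params, tolerance = 1e-12)
  expect_equal(r$inlet$Q_peak, cfg$inlet$Q_peak, tolerance = 1e-12)
  expect_identical(r$n_nodes, cfg$n_nodes)
})
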