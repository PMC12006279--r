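#' Default testbed scenarios for the reference arteries
#'
#' Assembles a complete [testbed_config] for the radial or carotid
#' surrogate: reference geometry, the default exponential stiffening law,
#' the canonical inlet pulse, and Windkessel parameters initialised from
#' mean haemodynamics (`RT = P_mean/Q_mean` with a 90 mmHg mean-pressure
#' target, split at the characteristic impedance; the diastolic
#' time-constant estimate is taken from the published outlet parameter set
#' for the same artery, `tau = Rd C`: ~1.22 s radial, ~0.48 s carotid).
#' The initial parameters land near, but not
#' necessarily inside, the physiological pressure windows; run
#' [tune_scenario()] to refine them.
#'
#' @param artery `"radial"` or `"carotid"`.
#' @param n_cycles Number of cardiac cycles (default 8).
#' @param n_nodes Grid nodes (default 201).
#' @param dt Output sampling interval (s, default 1 ms).
#' @return A [testbed_config].
#' @export
default_scenario <- function(artery = c("radial", "carotid"),
                             n_cycles = 8L, n_nodes = 201L, dt = 1e-3) {
  artery <- match.arg(artery)
  art <- switch(artery, radial = artery_radial(), carotid = artery_carotid())
  law <- switch(artery, radial = tube_law_radial(), carotid = tube_law_carotid())
  inlet <- switch(artery, radial = inlet_radial(), carotid = inlet_carotid())
  tg <- tune_targets()
  wk_ref <- switch(artery, radial = wk3_radial_paper(), carotid = wk3_carotid_paper())
  est <- initial_estimates(inlet$Q_mean, mmhg_to_pa(tg$p_mean_target),
                           tau = wk_ref$Rd * wk_ref$C)
  c_ref <- analytic_pwv(law, law$A_ref, art$rho)
  sp <- split_resistances(est$RT, art$rho, c_ref, law$A_ref)
  wk <- wk3_params(sp$Rp, sp$Rd, est$C)
  testbed_config(art, law, wk, inlet,
                 stations = measurement_plan(L_total = art$L_total),
                 n_nodes = n_nodes, dt = dt, n_cycles = n_cycles)
}

#' Tune a scenario's Windkessel outlet to the pressure windows
#'
#' Wraps [wk3_tune()] with an evaluator that runs the 1D testbed and
#' measures diastolic/systolic/mean pressure, the diastolic decay time
#' constant, and the diastolic wave speed and area at station S1.
#'
#' @param config A [testbed_config].
#' @param targets A [tune_targets].
#' @param max_iter Maximum tuning iterations.
#' @return The same config with tuned Windkessel parameters; tuning
#'   attributes (`converged`, `iterations`, `trajectory`) are attached to
#'   the config's `wk`.
#' @export
tune_scenario <- function(config, targets = tune_targets(), max_iter = 20L) {
  stopifnot(inherits(config, "testbed_config"))
  rho <- config$artery$rho
  evaluator <- function(wk) {
    cfg <- config
    cfg$wk <- wk
    ds <- simulate_pulse_1d(cfg)
    P1 <- ds$S1$P; A1 <- ds$S1$A
    i_d <- which.min(P1$values)
    A_d <- A1$values[i_d]
    list(DBP = min(P1$values), SBP = max(P1$values),
         P_mean = mean(P1$values), tau = measure_tau(P1),
         c_d = analytic_pwv(config$law, A_d, rho), A_d = A_d)
  }
  wk <- wk3_tune(evaluator, targets, config$wk, rho = rho, max_iter = max_iter)
  config$wk <- wk
  config
}
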