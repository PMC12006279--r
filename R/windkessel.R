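#' Three-element Windkessel parameters
#'
#' Lumped outlet model of the truncated distal circulation: a proximal
#' resistance `Rp` (matched to the characteristic impedance `rho c / A` of
#' the upstream vessel to limit artificial reflections), a distal
#' resistance `Rd` for the peripheral microcirculation, and a compliance
#' `C` for the distal arterial storage. The reference (venous) pressure is
#' taken as 0 Pa.
#'
#' @param Rp Proximal resistance (Pa s m^-3, > 0).
#' @param Rd Distal resistance (Pa s m^-3, > 0).
#' @param C Compliance (m^3 Pa^-1, > 0).
#' @return An object of class `wk3_params`.
#' @export
wk3_params <- function(Rp, Rd, C) {
  if (Rp <= 0 || Rd <= 0 || C <= 0) {
    stop("Windkessel parameters must all be positive", call. = FALSE)
  }
  structure(list(Rp = Rp, Rd = Rd, C = C), class = "wk3_params")
}

#' @export
print.wk3_params <- function(x, ...) {
  cat(sprintf("<wk3_params> Rp = %.4g, Rd = %.4g Pa s/m3, C = %.4g m3/Pa (tau = %.3g s)\n",
              x$Rp, x$Rd, x$C, x$Rd * x$C))
  invisible(x)
}

#' Published Windkessel parameter sets
#'
#' The outlet parameter sets reported for the radial and common carotid
#' arteries after tuning against 3D fluid-structure simulations. Shipped as
#' fixtures for reference and initialisation; the 1D surrogate testbed is
#' re-tuned with [wk3_tune()] rather than reusing these verbatim.
#'
#' @return A [wk3_params].
#' @export
wk3_radial_paper <- function() wk3_params(Rp = 2.26668e9, Rd = 37.3104e9, C = 0.032595e-9)

#' @rdname wk3_radial_paper
#' @export
wk3_carotid_paper <- function() wk3_params(Rp = 0.2120e9, Rd = 1.6384e9, C = 0.2954e-9)

#' Advance the Windkessel outlet one time step
#'
#' Integrates the capacitor balance `C dPc/dt = Q - Pc/Rd` over one step
#' with the inflow held constant, using the exact integrating-factor
#' update (unconditionally stable, and exact for constant `Q`):
#' `Pc_next = Q Rd + (Pc - Q Rd) exp(-dt/(Rd C))`. The outlet pressure is
#' `P = Rp Q + Pc_next`.
#'
#' @param params A [wk3_params].
#' @param Q Inflow into the outlet (m^3/s).
#' @param Pc Stored capacitor pressure (Pa).
#' @param dt Time step (s, > 0).
#' @return List with `P` (outlet pressure, Pa) and `Pc_next` (Pa).
#' @export
wk3_outlet_advance <- function(params, Q, Pc, dt) {
  stopifnot(inherits(params, "wk3_params"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  Pinf <- Q * params$Rd
  Pc_next <- Pinf + (Pc - Pinf) * exp(-dt / (params$Rd * params$C))
  list(P = params$Rp * Q + Pc_next, Pc_next = Pc_next)
}

#' Initial Windkessel estimates from mean haemodynamics
#'
#' Total resistance as the ratio of the target mean pressure to the mean
#' inflow (`RT = P_mean / Q_mean`, zero venous pressure), and compliance as
#' the ratio of the diastolic decay time constant to the total resistance
#' (`C = tau / RT`).
#'
#' @param Q_mean Mean inflow (m^3/s, > 0).
#' @param P_mean_target Target mean pressure (Pa, > 0).
#' @param tau Diastolic exponential-decay time constant (s, > 0).
#' @return List with `RT` (Pa s m^-3) and `C` (m^3 Pa^-1).
#' @export
initial_estimates <- function(Q_mean, P_mean_target, tau) {
  if (Q_mean <= 0 || P_mean_target <= 0 || tau <= 0) {
    stop("inputs must all be positive", call. = FALSE)
  }
  RT <- P_mean_target / Q_mean
  list(RT = RT, C = tau / RT)
}

#' Split total resistance into proximal and distal parts
#'
#' The proximal resistance is matched to the characteristic impedance of
#' the upstream vessel, `Rp = rho c_d / A_d` (diastolic wave speed and
#' area), and the remainder goes to the periphery, `Rd = RT - Rp`.
#'
#' @param RT Total resistance (Pa s m^-3).
#' @param rho Blood density (kg/m^3).
#' @param c_d Diastolic wave speed (m/s).
#' @param A_d Diastolic area (m^2).
#' @return List with `Rp` and `Rd`.
#' @export
split_resistances <- function(RT, rho, c_d, A_d) {
  Rp <- rho * c_d / A_d
  if (RT <= Rp) {
    stop(sprintf("infeasible split: RT = %.4g <= Rp = %.4g", RT, Rp), call. = FALSE)
  }
  list(Rp = Rp, Rd = RT - Rp)
}

#' Pressure-window targets for Windkessel tuning
#'
#' @param dbp_window Diastolic window in mmHg, default `c(65, 85)`.
#' @param sbp_window Systolic window in mmHg, default `c(110, 130)`.
#' @param p_mean_target Target mean pressure in mmHg; defaults to
#'   `DBP_mid + (SBP_mid - DBP_mid)/3`, the usual clinical estimate.
#' @return An object of class `tune_targets`.
#' @export
tune_targets <- function(dbp_window = c(65, 85), sbp_window = c(110, 130),
                         p_mean_target = NULL) {
  if (dbp_window[1L] >= dbp_window[2L] || sbp_window[1L] >= sbp_window[2L]) {
    stop("windows must satisfy low < high", call. = FALSE)
  }
  if (is.null(p_mean_target)) {
    dbp <- mean(dbp_window); sbp <- mean(sbp_window)
    p_mean_target <- dbp + (sbp - dbp) / 3
  }
  structure(list(dbp_window = dbp_window, sbp_window = sbp_window,
                 p_mean_target = p_mean_target),
            class = "tune_targets")
}

#' Measure the diastolic decay time constant
#'
#' Log-linear fit of the pressure tail over the last 40% of diastole
#' (systolic peak to end of cycle), assuming decay towards zero venous
#' pressure: `tau = -1/slope` of `log P` vs `t`.
#'
#' @param P One cycle of pressure as a [uts] (Pa).
#' @return Time constant in seconds.
#' @export
measure_tau <- function(P) {
  stopifnot(inherits(P, "uts"))
  v <- P$values
  i_peak <- which.max(v)
  n <- length(v)
  if (n - i_peak < 5L) stop("no diastolic tail after the systolic peak", call. = FALSE)
  i_start <- i_peak + floor(0.6 * (n - i_peak))
  idx <- i_start:n
  tt <- (idx - 1) * P$dt
  fit <- stats::lm.fit(cbind(1, tt), log(v[idx]))
  slope <- fit$coefficients[2L]
  if (!is.finite(slope) || slope >= 0) {
    stop("diastolic tail is not decaying; cannot measure tau", call. = FALSE)
  }
  unname(-1 / slope)
}

#' Tune Windkessel parameters to target pressure windows
#'
#' Reproducible version of the manual tune-over-multiple-simulations loop:
#' iterate (i) rescale the total resistance by the ratio of target to
#' achieved mean pressure, (ii) re-split it with the latest diastolic wave
#' speed and area at station S1 via [split_resistances()], and (iii) apply
#' a damped multiplicative compliance update from the achieved vs target
#' pulse pressure, until diastolic and systolic pressure both lie inside
#' their windows or `max_iter` is reached.
#'
#' @param run Scenario evaluator: a function taking a [wk3_params] and
#'   returning a list with `DBP`, `SBP`, `P_mean` (Pa), `tau` (s), `c_d`
#'   (m/s), `A_d` (m^2) measured at station S1.
#' @param targets A [tune_targets].
#' @param init Initial [wk3_params].
#' @param rho Blood density (kg/m^3) for the characteristic-impedance split.
#' @param max_iter Maximum iterations (default 20).
#' @param damping Damping exponent for the compliance update (default 0.7).
#' @return The converged [wk3_params], with attributes `converged`
#'   (logical), `iterations`, and `trajectory` (data frame of the iterates).
#' @export
wk3_tune <- function(run, targets, init, rho = 1060, max_iter = 20L,
                     damping = 0.7) {
  stopifnot(inherits(targets, "tune_targets"), inherits(init, "wk3_params"))
  dbp_w <- mmhg_to_pa(targets$dbp_window)
  sbp_w <- mmhg_to_pa(targets$sbp_window)
  p_mean_t <- mmhg_to_pa(targets$p_mean_target)
  pp_t <- mean(sbp_w) - mean(dbp_w)

  wk <- init
  traj <- vector("list", max_iter + 1L)
  for (it in 0:max_iter) {
    res <- run(wk)
    traj[[it + 1L]] <- data.frame(
      iter = it, Rp = wk$Rp, Rd = wk$Rd, C = wk$C,
      DBP_mmHg = pa_to_mmhg(res$DBP), SBP_mmHg = pa_to_mmhg(res$SBP),
      P_mean_mmHg = pa_to_mmhg(res$P_mean))
    ok <- res$DBP >= dbp_w[1L] && res$DBP <= dbp_w[2L] &&
          res$SBP >= sbp_w[1L] && res$SBP <= sbp_w[2L]
    if (ok) {
      attr(wk, "converged") <- TRUE
      attr(wk, "iterations") <- it
      attr(wk, "trajectory") <- do.call(rbind, traj[1:(it + 1L)])
      return(wk)
    }
    if (it == max_iter) break
    RT <- (wk$Rp + wk$Rd) * (p_mean_t / res$P_mean)
    sp <- split_resistances(RT, rho, res$c_d, res$A_d)
    pp_a <- res$SBP - res$DBP
    C_new <- wk$C * (pp_a / pp_t)^damping
    wk <- wk3_params(sp$Rp, sp$Rd, C_new)
  }
  tr <- do.call(rbind, traj)
  stop(structure(
    class = c("wk3_tune_failure", "error", "condition"),
    list(message = sprintf("Windkessel tuning did not converge in %d iterations", max_iter),
         call = sys.call(-1), trajectory = tr)))
}
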