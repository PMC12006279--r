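#' Calibration point for BP prediction
#'
#' The anchor `(P0, A0)` shared by all prediction models: a reference
#' pressure (conventionally the diastolic BP, as obtained from a cuff
#' calibration) and the inner area measured at that same instant. By this
#' convention the diastolic prediction error is zero by construction.
#'
#' @param P0 Calibration pressure (Pa, > 0).
#' @param A0 Area at `P0` (m^2, > 0).
#' @return An object of class `calibration_point`.
#' @export
calibration_point <- function(P0, A0) {
  if (P0 <= 0 || A0 <= 0) stop("P0 and A0 must be positive", call. = FALSE)
  structure(list(P0 = P0, A0 = A0), class = "calibration_point")
}

#' Diastolic calibration from a ground-truth station
#'
#' Extracts `(P0, A0)` at the diastolic minimum of the ground-truth
#' pressure, the same time point for both quantities.
#'
#' @param P,A One cycle of pressure (Pa) and area (m^2) on a shared grid.
#' @return A [calibration_point] with attribute `index` (sample index of
#'   the diastolic minimum).
#' @export
diastolic_calibration <- function(P, A) {
  stop_if_grid_mismatch(P, A)
  i0 <- which.min(P$values)
  cp <- calibration_point(P$values[i0], A$values[i0])
  attr(cp, "index") <- i0
  cp
}

new_predicted_bp <- function(values, template, model_id, inputs) {
  structure(list(
    P_pred = uts(values, dt = template$dt, t0 = template$t0,
                 quantity = "pressure", units = "Pa"),
    model_id = model_id, inputs = inputs),
    class = "predicted_bp")
}

#' @export
print.predicted_bp <- function(x, ...) {
  v <- pa_to_mmhg(x$P_pred$values)
  cat(sprintf("<predicted_bp> model %s: %d samples, %.2f-%.2f mmHg\n",
              x$model_id, length(v), min(v), max(v)))
  invisible(x)
}

#' Model 1: BP from a single (diastolic) PWV
#'
#' The conventional single-PWV prediction obtained by closing the
#' Bramwell-Hill integral with a constant wave speed:
#' `P(t) = P0 + rho PWV_d^2 ln(A(t)/A0)`. Exact only when the artery
#' behaves linearly (constant PWV); on a stiffening artery it
#' underpredicts systolic pressure.
#'
#' @param A One cycle of area as a [uts] (m^2, all positive).
#' @param PWVd Diastolic wave speed (m/s, > 0).
#' @param calib A [calibration_point].
#' @param rho Blood density (kg/m^3).
#' @return A `predicted_bp`.
#' @export
predict_m1 <- function(A, PWVd, calib, rho) {
  stopifnot(inherits(A, "uts"), inherits(calib, "calibration_point"))
  if (any(A$values <= 0)) stop("area must be strictly positive", call. = FALSE)
  if (PWVd <= 0) stop("`PWVd` must be positive", call. = FALSE)
  v <- calib$P0 + rho * PWVd^2 * log(A$values / calib$A0)
  new_predicted_bp(v, A, "M1", list(PWVd = PWVd, calib = calib, rho = rho))
}

#' Model 2: BP from diastolic and systolic PWV via linear scaling
#'
#' Closes the Bramwell-Hill integral with the linear wave-speed scaling
#' `PWV(t) = C1 + m A(t)` (built from the diastolic/systolic endpoints),
#' giving the closed form
#' `P(t) = P0 + rho [C1^2 ln(A/A0) + m^2 (A^2 - A0^2)/2 + 2 C1 m (A - A0)]`.
#' With `m = 0` this reduces sample-wise to [predict_m1()].
#'
#' @param A One cycle of area as a [uts] (m^2, all positive).
#' @param scaling A [build_scaling()] result.
#' @param calib A [calibration_point]; by default its `A0` is checked
#'   against the scaling's `A_d` (set `check_calib = FALSE` to override).
#' @param rho Blood density (kg/m^3).
#' @param check_calib Verify `A0 == A_d` (relative 1e-6)? Default TRUE.
#' @return A `predicted_bp`.
#' @export
predict_m2 <- function(A, scaling, calib, rho, check_calib = TRUE) {
  stopifnot(inherits(A, "uts"), inherits(scaling, "pwv_scaling"),
            inherits(calib, "calibration_point"))
  if (any(A$values <= 0)) stop("area must be strictly positive", call. = FALSE)
  if (check_calib && abs(calib$A0 - scaling$A_d) > 1e-6 * scaling$A_d) {
    stop("calibration A0 differs from the scaling's diastolic area A_d; ",
         "pass check_calib = FALSE to override", call. = FALSE)
  }
  C1 <- scaling$C1; m <- scaling$m
  Av <- A$values; A0 <- calib$A0
  v <- calib$P0 + rho * (C1^2 * log(Av / A0) + m^2 * (Av^2 - A0^2) / 2 +
                           2 * C1 * m * (Av - A0))
  new_predicted_bp(v, A, "M2", list(scaling = scaling, calib = calib, rho = rho))
}

#' Model-free BP reconstruction from an arbitrary PWV series
#'
#' Numerically accumulates the rearranged Bramwell-Hill relation
#' `P(t) = P0 + rho int_{A0}^{A(t)} PWV^2 dA / A` by path-ordered
#' trapezoidal quadrature along the time path, starting at the calibration
#' sample (the sample whose area is closest to `A0`). Following the time
#' path — rather than sorting by area — keeps the dicrotic down-up passes
#' consistent on non-monotone cycles. Serves as the model-free oracle
#' against which the closed-form models are checked.
#'
#' @param A One cycle of area as a [uts] (m^2).
#' @param pwv A PWV series on the same grid (m/s).
#' @param calib A [calibration_point].
#' @param rho Blood density (kg/m^3).
#' @return A `predicted_bp` with `model_id = "general"`.
#' @export
predict_general <- function(A, pwv, calib, rho) {
  stopifnot(inherits(A, "uts"), inherits(pwv, "uts"),
            inherits(calib, "calibration_point"))
  stop_if_grid_mismatch(A, pwv)
  Av <- A$values
  f <- pwv$values^2 / Av
  n <- length(Av)
  seg <- 0.5 * (f[-n] + f[-1L]) * diff(Av) # trapezoid in A along time order
  i0 <- which.min(abs(Av - calib$A0))
  v <- numeric(n)
  v[i0] <- calib$P0
  if (i0 < n) v[(i0 + 1L):n] <- calib$P0 + rho * cumsum(seg[i0:(n - 1L)])
  if (i0 > 1L) {
    # tail sums: sum(seg[k:(i0-1)]) for k = 1..i0-1
    tails <- rev(cumsum(rev(seg[1L:(i0 - 1L)])))
    v[1L:(i0 - 1L)] <- calib$P0 - rho * tails
  }
  new_predicted_bp(v, A, "general", list(calib = calib, rho = rho))
}
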