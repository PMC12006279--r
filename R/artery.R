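#' Artery geometry and fluid constants
#'
#' Bundles the geometric description of an idealised cylindrical artery and
#' the blood properties used throughout: pressure-free inner diameter `D0`,
#' wall thickness `h` (metadata only — the 1D surrogate does not model wall
#' mechanics through `h`), total length, blood density and dynamic
#' viscosity.
#'
#' @param name Label for the artery.
#' @param D0 Pressure-free inner diameter (m).
#' @param h Wall thickness (m).
#' @param L_total Vessel length (m).
#' @param rho Blood density (kg/m^3); 1060 by default.
#' @param mu Blood dynamic viscosity (Pa s); 0.004 by default (Newtonian).
#'
#' @return An object of class `artery_spec`.
#' @export
artery_spec <- function(name, D0, h, L_total, rho = 1060, mu = 0.004) {
  if (D0 <= 0 || h <= 0 || L_total <= 0 || rho <= 0 || mu < 0) {
    stop("artery parameters out of range", call. = FALSE)
  }
  structure(list(name = name, D0 = D0, h = h, L_total = L_total,
                 rho = rho, mu = mu),
            class = "artery_spec")
}

#' @export
print.artery_spec <- function(x, ...) {
  cat(sprintf("<artery_spec> %s: D0 = %.3f mm, h = %.2f mm, L = %.0f mm, rho = %g kg/m3, mu = %g Pa s\n",
              x$name, x$D0 * 1e3, x$h * 1e3, x$L_total * 1e3, x$rho, x$mu))
  invisible(x)
}

#' Reference artery geometries
#'
#' Literature-based geometries for the radial and common carotid arteries:
#' radial D0 = 2.064 mm, h = 0.2 mm; carotid D0 = 6.4 mm, h = 0.33 mm; both
#' 110 mm long, with blood density 1060 kg/m^3 and viscosity 0.004 Pa s.
#'
#' @return An `artery_spec`.
#' @export
artery_radial <- function() {
  artery_spec("radial", D0 = 2.064e-3, h = 0.2e-3, L_total = 0.110)
}

#' @rdname artery_radial
#' @export
artery_carotid <- function() {
  artery_spec("carotid", D0 = 6.4e-3, h = 0.33e-3, L_total = 0.110)
}

#' Two-station measurement plan
#'
#' Axial positions of the two sensing stations S1 and S2 along the vessel.
#' The defaults (36 mm and 96 mm from the inlet, separation 60 mm) are the
#' positions used by the benchmark protocol throughout.
#'
#' @param x1,x2 Axial positions (m), `0 < x1 < x2 < L_total`.
#' @param L_total Vessel length used to validate the positions (m).
#' @return An object of class `measurement_plan` with a `separation` field.
#' @export
measurement_plan <- function(x1 = 0.036, x2 = 0.096, L_total = 0.110) {
  if (!(0 < x1 && x1 < x2 && x2 < L_total)) {
    stop("stations must satisfy 0 < x1 < x2 < L_total", call. = FALSE)
  }
  structure(list(x1 = x1, x2 = x2, separation = x2 - x1),
            class = "measurement_plan")
}
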