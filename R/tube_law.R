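#' Nonlinear pressure-area tube laws
#'
#' A tube law is a monotone algebraic pressure-area relation `P(A)` for a
#' compliant vessel, together with its closed-form wave speed from the
#' Bramwell-Hill relation `PWV(A) = sqrt((A/rho) dP/dA)`. Three families are
#' provided, each chosen so that a known closed-form answer exists for one
#' part of the prediction chain:
#'
#' * `constant_pwv` — `P = P_ref + rho c0^2 ln(A/A_ref)`: wave speed is `c0`
#'   for every area. This is the linear-elastic limit in which the
#'   single-PWV prediction model is exact.
#' * `linear_pwv` — `PWV(A) = a + b (A - A_ref)`, with `P(A)` obtained by
#'   integrating `rho PWV^2 / A` in closed form. This makes the linear
#'   PWV-area scaling hypothesis literally true, so the two-PWV model is
#'   exact.
#' * `exponential` — `P = P_ref + beta (exp(gamma (A/A_ref - 1)) - 1)`: a
#'   generic collagen-recruitment-style stiffening law on which neither
#'   model is exact; the surrogate for a hyperelastic arterial wall.
#'
#' All laws are restricted to the working range `[0.5 A_ref, 2 A_ref]`,
#' where they are strictly monotone and physically meaningful; operations
#' outside it raise range errors.
#'
#' @param kind One of `"constant_pwv"`, `"linear_pwv"`, `"exponential"`.
#' @param A_ref Reference area (m^2).
#' @param P_ref Pressure at `A_ref` (Pa).
#' @param c0 Wave speed (m/s), for `constant_pwv`.
#' @param a PWV at `A_ref` (m/s), for `linear_pwv`.
#' @param b PWV-vs-area slope (m/s per m^2), for `linear_pwv`.
#' @param beta Pressure scale (Pa), for `exponential`.
#' @param gamma Dimensionless stiffening rate, for `exponential`.
#'
#' @return An object of class `tube_law`.
#' @export
#' @examples
#' law <- tube_law("constant_pwv", A_ref = 3.3e-6, P_ref = mmhg_to_pa(75), c0 = 10)
#' analytic_pwv(law, 3.5e-6, rho = 1060)
tube_law <- function(kind = c("constant_pwv", "linear_pwv", "exponential"),
                     A_ref, P_ref, c0 = NULL, a = NULL, b = NULL,
                     beta = NULL, gamma = NULL) {
  kind <- match.arg(kind)
  if (A_ref <= 0) stop("`A_ref` must be positive", call. = FALSE)
  params <- switch(kind,
    constant_pwv = {
      if (is.null(c0) || c0 <= 0) stop("constant_pwv law needs c0 > 0", call. = FALSE)
      list(c0 = c0)
    },
    linear_pwv = {
      if (is.null(a) || is.null(b)) stop("linear_pwv law needs `a` and `b`", call. = FALSE)
      # PWV must stay positive over the working range
      Alo <- 0.5 * A_ref; Ahi <- 2 * A_ref
      if (a + b * (Alo - A_ref) <= 0 || a + b * (Ahi - A_ref) <= 0) {
        stop("linear_pwv law is non-positive inside the working range", call. = FALSE)
      }
      list(a = a, b = b)
    },
    exponential = {
      if (is.null(beta) || is.null(gamma) || beta <= 0 || gamma <= 0) {
        stop("exponential law needs beta > 0 and gamma > 0", call. = FALSE)
      }
      list(beta = beta, gamma = gamma)
    }
  )
  structure(list(kind = kind, A_ref = A_ref, P_ref = P_ref, params = params),
            class = "tube_law")
}

#' @export
print.tube_law <- function(x, ...) {
  ps <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)), collapse = ", ")
  cat(sprintf("<tube_law> %s: A_ref = %g m2, P_ref = %.1f mmHg, %s\n",
              x$kind, x$A_ref, pa_to_mmhg(x$P_ref), ps))
  invisible(x)
}

law_range <- function(law) c(0.5, 2) * law$A_ref

check_area_in_range <- function(law, A) {
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("area must be positive and finite", call. = FALSE)
  }
  r <- law_range(law)
  if (any(A < r[1L]) || any(A > r[2L])) {
    stop(sprintf("area outside the law's working range [%g, %g] m2",
                 r[1L], r[2L]), call. = FALSE)
  }
  invisible(NULL)
}

#' Evaluate a tube law: pressure from area
#'
#' @param law A [tube_law].
#' @param A Area(s) in m^2, inside the working range.
#' @param rho Blood density (kg/m^3).
#' @return Pressure(s) in Pa.
#' @export
pressure_from_area <- function(law, A, rho) {
  stopifnot(inherits(law, "tube_law"))
  check_area_in_range(law, A)
  A_ref <- law$A_ref
  p <- law$params
  law$P_ref + switch(law$kind,
    constant_pwv = rho * p$c0^2 * log(A / A_ref),
    linear_pwv = {
      # integral of rho * (alpha + b A)^2 / A from A_ref to A, alpha = a - b A_ref
      alpha <- p$a - p$b * A_ref
      rho * (alpha^2 * log(A / A_ref) + 2 * alpha * p$b * (A - A_ref) +
               p$b^2 * (A^2 - A_ref^2) / 2)
    },
    exponential = p$beta * (exp(p$gamma * (A / A_ref - 1)) - 1)
  )
}

#' Invert a tube law: area from pressure
#'
#' Unique inverse of [pressure_from_area()]. Closed form where it exists
#' (`constant_pwv`, `exponential`); otherwise a bracketed root solve to
#' `|P(A*) - P| < 1e-8` Pa.
#'
#' @param law A [tube_law].
#' @param P Pressure(s) in Pa, inside the law's attainable range.
#' @param rho Blood density (kg/m^3).
#' @return Area(s) in m^2.
#' @export
area_from_pressure <- function(law, P, rho) {
  stopifnot(inherits(law, "tube_law"))
  r <- law_range(law)
  Plo <- pressure_from_area(law, r[1L], rho)
  Phi <- pressure_from_area(law, r[2L], rho)
  if (any(P < Plo) || any(P > Phi)) {
    stop(sprintf("pressure outside the attainable range [%.6g, %.6g] Pa", Plo, Phi),
         call. = FALSE)
  }
  p <- law$params
  switch(law$kind,
    constant_pwv = law$A_ref * exp((P - law$P_ref) / (rho * p$c0^2)),
    exponential = law$A_ref * (1 + log1p((P - law$P_ref) / p$beta) / p$gamma),
    linear_pwv = vapply(P, function(Pi) {
      A <- stats::uniroot(function(A) pressure_from_area(law, A, rho) - Pi,
                          lower = r[1L], upper = r[2L],
                          tol = .Machine$double.eps^0.5 * law$A_ref,
                          maxiter = 200L)$root
      # Newton polish to machine precision using dP/dA = rho c^2 / A
      for (i in 1:3) {
        dPdA <- rho * analytic_pwv(law, A, rho)^2 / A
        A <- A - (pressure_from_area(law, A, rho) - Pi) / dPdA
      }
      A
    }, numeric(1L))
  )
}

#' Closed-form wave speed of a tube law
#'
#' Bramwell-Hill wave speed `sqrt((A/rho) dP/dA)` using the law's analytic
#' derivative: `c0` for `constant_pwv`, `a + b (A - A_ref)` for
#' `linear_pwv`, and the exponential law's analytic form otherwise.
#'
#' @inheritParams pressure_from_area
#' @return Wave speed(s) in m/s.
#' @export
analytic_pwv <- function(law, A, rho) {
  stopifnot(inherits(law, "tube_law"))
  check_area_in_range(law, A)
  p <- law$params
  switch(law$kind,
    constant_pwv = rep(p$c0, length(A)),
    linear_pwv = p$a + p$b * (A - law$A_ref),
    exponential = {
      dPdA <- p$beta * p$gamma / law$A_ref * exp(p$gamma * (A / law$A_ref - 1))
      sqrt(A / rho * dPdA)
    }
  )
}

# Integral of c^2(A) dA -- the "pressure potential" that puts the 1D momentum
# equation in conservative form. Additive constant is irrelevant.
tube_law_celerity_potential <- function(law, A, rho) {
  p <- law$params
  A_ref <- law$A_ref
  switch(law$kind,
    constant_pwv = p$c0^2 * A,
    linear_pwv = {
      cc <- p$a + p$b * (A - A_ref)
      if (abs(p$b) < .Machine$double.eps) p$a^2 * A else cc^3 / (3 * p$b)
    },
    exponential = {
      u <- A / A_ref
      (p$beta * A_ref / rho) * exp(p$gamma * (u - 1)) * (u - 1 / p$gamma)
    }
  )
}

#' Default surrogate tube laws for the reference arteries
#'
#' Exponential stiffening laws whose reference area is the pressure-free
#' lumen area of the corresponding artery and whose reference pressure is
#' 75 mmHg (taken as the diastolic operating point). Parameters are chosen
#' once so that, at physiological pulse pressures (~45 mmHg), the diastolic
#' wave speed and the within-cycle PWV swing fall in the physiological
#' ranges reported for each vessel: radial PWV ~10 m/s rising by ~45-50%
#' over the cycle, carotid PWV ~8.4 m/s rising by ~19%.
#'
#' @return A [tube_law].
#' @export
tube_law_radial <- function() {
  tube_law("exponential", A_ref = area_from_diameter(2.064e-3),
           P_ref = mmhg_to_pa(75), beta = 5300, gamma = 20)
}

#' @rdname tube_law_radial
#' @export
tube_law_carotid <- function() {
  tube_law("exponential", A_ref = area_from_diameter(6.4e-3),
           P_ref = mmhg_to_pa(75), beta = 18700, gamma = 4)
}
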