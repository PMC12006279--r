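# central-difference gradient with one-sided ends (uniform grid)
grad_central <- function(v, h) {
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  g <- numeric(n)
  g[1L] <- (v[2L] - v[1L]) / h
  g[n] <- (v[n] - v[n - 1L]) / h
  g[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * h)
  g
}

#' Detect the waveform foot by intersecting tangents
#'
#' Finds the fiducial "foot" of a pulse upstroke as the intersection of the
#' horizontal line through the cycle minimum and the tangent at the point
#' of maximal first derivative on the upstroke. The derivative maximum is
#' refined to sub-sample precision by parabolic interpolation, which
#' matters because at 1 ms sampling a 60 mm / 10 m/s transit is only 6
#' samples.
#'
#' @param series One cycle (or an upstroke-bracketing window) as a [uts].
#' @param window Optional time range `c(from, to)` in seconds restricting
#'   the analysis.
#' @return An object of class `foot_detection`: `t_foot`, `t_min`,
#'   `t_maxslope` (s), `slope` (units/s), `v_min`, `v_at_maxslope`.
#' @export
detect_foot <- function(series, window = NULL) {
  stopifnot(inherits(series, "uts"))
  v <- series$values
  tt <- uts_time(series)
  if (!is.null(window)) {
    keep <- tt >= window[1L] & tt <= window[2L]
    if (sum(keep) < 4L) stop("analysis window too short", call. = FALSE)
    v <- v[keep]; tt <- tt[keep]
  }
  n <- length(v)
  dt <- series$dt
  d <- grad_central(v, dt)

  # latest minimum before the largest upstroke (tie-break per convention)
  i_dmax_global <- which.max(d)
  mins <- which(v == min(v))
  tie_warned <- FALSE
  if (length(mins) > 1L) {
    tie_warned <- TRUE
    warning("multiple equal minima; using the latest before the largest upstroke",
            call. = FALSE)
  }
  cand <- mins[mins <= i_dmax_global]
  i_min <- if (length(cand)) max(cand) else min(mins)

  # upstroke after the minimum: up to the following waveform maximum
  i_after <- if (i_min < n) (i_min + 1L):n else integer(0)
  if (!length(i_after)) stop("no upstroke after the minimum", call. = FALSE)
  i_peak <- i_after[which.max(v[i_after])]
  if (i_peak <= i_min || v[i_peak] <= v[i_min]) {
    stop("non-positive upstroke: waveform is flat or decreasing", call. = FALSE)
  }
  up <- i_min:i_peak
  i_s <- up[which.max(d[up])]
  if (d[i_s] <= 0) stop("non-positive upstroke slope", call. = FALSE)

  # parabolic refinement of the derivative maximum
  delta <- 0
  slope <- d[i_s]
  if (i_s > 1L && i_s < n) {
    dm <- d[i_s - 1L]; d0 <- d[i_s]; dp <- d[i_s + 1L]
    den <- dm - 2 * d0 + dp
    if (abs(den) > .Machine$double.eps * max(abs(c(dm, d0, dp)), 1)) {
      delta <- 0.5 * (dm - dp) / den
      delta <- max(-0.5, min(0.5, delta))
      slope <- d0 - 0.25 * (dm - dp) * delta
    }
  }
  t_ms <- tt[i_s] + delta * dt
  # waveform value at the refined tangent point (linear interpolation)
  v_ms <- stats::approx(tt, v, xout = t_ms)$y
  v_min <- v[i_min]

  t_foot <- t_ms - (v_ms - v_min) / slope
  t_foot <- max(tt[i_min], min(t_foot, t_ms))

  structure(list(t_foot = t_foot, t_min = tt[i_min], t_maxslope = t_ms,
                 slope = slope, v_min = v_min, v_at_maxslope = v_ms,
                 tie_warned = tie_warned),
            class = "foot_detection")
}

#' @export
print.foot_detection <- function(x, ...) {
  cat(sprintf("<foot_detection> t_foot = %.4f s (min at %.4f s, max slope at %.4f s, slope %.4g/s)\n",
              x$t_foot, x$t_min, x$t_maxslope, x$slope))
  invisible(x)
}

#' Foot-to-foot transit-time PWV
#'
#' Diastolic pulse wave velocity from the transit time of the waveform foot
#' between two stations: `PWV_d = separation / (t_foot(S2) - t_foot(S1))`,
#' with both feet located to sub-sample precision by [detect_foot()].
#'
#' @param series1,series2 The same cycle of a waveform (typically area) at
#'   the proximal and distal station.
#' @param separation Station separation in metres (> 0).
#' @param window Optional shared analysis window passed to [detect_foot()].
#' @return PWV in m/s, with attribute `delay_s`; a warning is issued when
#'   the delay is below two samples (resolution limit).
#' @export
estimate_pwvd <- function(series1, series2, separation, window = NULL) {
  if (separation <= 0) stop("`separation` must be positive", call. = FALSE)
  f1 <- detect_foot(series1, window)
  f2 <- detect_foot(series2, window)
  delay <- f2$t_foot - f1$t_foot
  if (delay <= 0) {
    stop("non-positive transit time: stations swapped or no propagation",
         call. = FALSE)
  }
  if (delay < 2 * series1$dt) {
    warning(sprintf("transit time %.3g s is below two samples; PWV near resolution limit",
                    delay), call. = FALSE)
  }
  structure(separation / delay, delay_s = delay)
}

# robust (bisquare-iterated) local linear smoother on a uniform grid;
# fits only on `ok` samples, predicts everywhere
robust_local_linear <- function(y, ok, window = 51L, iterations = 3L) {
  n <- length(y)
  h <- window %/% 2L
  x <- seq_len(n)
  rw <- rep(1, n) # robustness weights (on ok samples)
  fit_once <- function(rw) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      j <- lo:hi
      j <- j[ok[j]]
      if (length(j) < 2L) { out[i] <- NA_real_; next }
      u <- abs(x[j] - i) / max(h, 1L)
      w <- (1 - pmin(u, 1)^3)^3 * rw[j] # tricube distance x bisquare robustness
      if (sum(w > 0) < 2L) w <- w + 1e-12
      sw <- sum(w); sx <- sum(w * x[j]); sy <- sum(w * y[j])
      sxx <- sum(w * x[j]^2); sxy <- sum(w * x[j] * y[j])
      den <- sw * sxx - sx^2
      if (abs(den) < .Machine$double.eps * max(sxx * sw, 1)) {
        out[i] <- sy / sw
      } else {
        b <- (sw * sxy - sx * sy) / den
        a <- (sy - b * sx) / sw
        out[i] <- a + b * i
      }
    }
    out
  }
  fit <- fit_once(rw)
  for (k in seq_len(iterations - 1L)) {
    r <- y - fit
    s <- stats::median(abs(r[ok]), na.rm = TRUE)
    if (!is.finite(s) || s <= 0) break
    u <- abs(r) / (6 * s)
    rw <- ifelse(u < 1, (1 - u^2)^2, 0)
    fit <- fit_once(rw)
  }
  # windows containing no usable sample (long masked runs): bridge by
  # linear interpolation between the nearest fitted values
  if (anyNA(fit)) {
    ok_fit <- which(!is.na(fit))
    fit <- stats::approx(ok_fit, fit[ok_fit], xout = seq_len(n), rule = 2)$y
  }
  fit
}

#' Theoretical time-varying PWV from pressure and area waveforms
#'
#' Evaluates the Bramwell-Hill wave speed
#' `PWV(t) = sqrt((A/rho) dP/dA)` pointwise, with `dP/dA` computed as the
#' ratio of the time gradients of `P` and `A` (central differences).
#' Samples where `|dA/dt|` falls below a threshold fraction of its cycle
#' maximum are masked (the ratio is 0/0-indeterminate at area extrema) and
#' filled by a robust local-linear smoother, which also removes the sharp
#' over/undershoots the raw gradient ratio produces.
#'
#' The default smoother window of 21 samples (~21 ms at 1 ms sampling) is
#' wide enough to suppress gradient noise but narrow enough not to bias
#' the fast systolic upstroke, where PWV(t) changes over ~100 ms; wider
#' windows visibly flatten the systolic PWV peak.
#'
#' @param P,A One cycle of pressure (Pa) and area (m^2) on a shared grid.
#' @param rho Blood density (kg/m^3).
#' @param mask_threshold Masking threshold as a fraction of `max |dA/dt|`
#'   (default 0.02).
#' @param smooth_window Smoother window in samples (default 21).
#' @param smooth_iterations Robustness iterations (default 3).
#' @return A [uts] of quantity `"pwv"` (m/s) with attribute `masked`
#'   (logical vector marking filled samples).
#' @export
theoretical_pwv <- function(P, A, rho, mask_threshold = 0.02,
                            smooth_window = 21L, smooth_iterations = 3L) {
  stopifnot(inherits(P, "uts"), inherits(A, "uts"))
  stop_if_grid_mismatch(P, A)
  if (any(A$values <= 0)) stop("area must be strictly positive", call. = FALSE)
  dPdt <- grad_central(P$values, P$dt)
  dAdt <- grad_central(A$values, A$dt)
  masked <- abs(dAdt) < mask_threshold * max(abs(dAdt))
  dPdA <- dPdt / dAdt
  neg <- !masked & dPdA < 0
  if (sum(neg) > 0.1 * sum(!masked)) {
    stop("dP/dA is negative over more than 10% of unmasked samples; input is non-physical",
         call. = FALSE)
  }
  masked <- masked | neg
  raw <- rep(NA_real_, length(dPdA))
  raw[!masked] <- sqrt(A$values[!masked] / rho * dPdA[!masked])
  sm <- robust_local_linear(ifelse(masked, 0, raw), ok = !masked,
                            window = smooth_window,
                            iterations = smooth_iterations)
  out <- uts(sm, dt = P$dt, t0 = P$t0, quantity = "pwv", units = "m_per_s")
  attr(out, "masked") <- masked
  out
}

#' Systolic PWV from a theoretical PWV series
#'
#' The systolic wave speed is taken directly as the cycle maximum of the
#' smoothed theoretical PWV(t): no practical transit-time estimator exists
#' for the systolic peak because wave reflections distort it.
#'
#' @param pwv_series One smoothed cycle of PWV as a [uts].
#' @return PWV_s in m/s.
#' @export
extract_pwvs <- function(pwv_series) {
  stopifnot(inherits(pwv_series, "uts"))
  v <- pwv_series$values
  if (!length(v) || anyNA(v)) stop("PWV series is empty or contains NA", call. = FALSE)
  max(v)
}

#' Linearity of PWV vs area over the systolic upstroke
#'
#' Ordinary least squares of instantaneous PWV on area restricted to the
#' systolic upstroke (waveform foot to area maximum by default), the
#' empirical check behind the linear PWV-area scaling.
#'
#' @param pwv_series One cycle of PWV as a [uts] (m/s).
#' @param A The matching area cycle as a [uts] (m^2).
#' @param window Optional time range `c(from, to)` (s) for the fit; default
#'   is `[t_foot(A), t(max A)]`.
#' @return List with `slope` (m/s per m^2), `intercept` (m/s), `r_squared`,
#'   and `n` (samples used).
#' @export
fit_linear_scaling <- function(pwv_series, A, window = NULL) {
  stopifnot(inherits(pwv_series, "uts"), inherits(A, "uts"))
  stop_if_grid_mismatch(pwv_series, A)
  tt <- uts_time(A)
  if (is.null(window)) {
    ft <- detect_foot(A)
    window <- c(ft$t_foot, tt[which.max(A$values)])
  }
  keep <- tt >= window[1L] & tt <= window[2L] & !is.na(pwv_series$values)
  if (sum(keep) < 10L) stop("fewer than 10 samples in the upstroke window", call. = FALSE)
  x <- A$values[keep]; y <- pwv_series$values[keep]
  if (max(x) - min(x) < 1e-12) stop("degenerate area range in the fit window", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       n = sum(keep))
}

#' Linear PWV-area scaling from diastolic and systolic endpoints
#'
#' The two-point linear scaling `PWV(t) = PWV_d + m (A(t) - A_d)` =
#' `C1 + m A(t)`, with `m = (PWV_s - PWV_d)/(A_s - A_d)` and
#' `C1 = PWV_d - m A_d`. Evaluating the line at `A_d` and `A_s` reproduces
#' the endpoints exactly.
#'
#' @param PWVd,PWVs Diastolic and systolic wave speed (m/s).
#' @param A_d,A_s Diastolic and systolic area (m^2, `A_s > A_d`).
#' @return An object of class `pwv_scaling` with fields `PWVd`, `PWVs`,
#'   `A_d`, `A_s`, `m`, `C1`.
#' @export
build_scaling <- function(PWVd, PWVs, A_d, A_s) {
  if (A_s <= A_d) stop("`A_s` must exceed `A_d`", call. = FALSE)
  if (PWVd < 0) stop("PWV values must be non-negative", call. = FALSE)
  if (PWVs < PWVd) {
    warning("PWVs < PWVd: inverted stiffening; proceeding", call. = FALSE)
  }
  m <- (PWVs - PWVd) / (A_s - A_d)
  C1 <- PWVd - m * A_d
  structure(list(PWVd = PWVd, PWVs = PWVs, A_d = A_d, A_s = A_s,
                 m = m, C1 = C1),
            class = "pwv_scaling")
}

#' @export
print.pwv_scaling <- function(x, ...) {
  cat(sprintf("<pwv_scaling> PWVd = %.3f, PWVs = %.3f m/s; m = %.4g m/s per m2, C1 = %.4g m/s\n",
              x$PWVd, x$PWVs, x$m, x$C1))
  invisible(x)
}

#' Evaluate a linear PWV-area scaling at given areas
#'
#' @param scaling A [build_scaling()] result.
#' @param A Area(s) in m^2.
#' @return PWV value(s) `C1 + m A` in m/s.
#' @export
scaling_pwv <- function(scaling, A) {
  stopifnot(inherits(scaling, "pwv_scaling"))
  scaling$C1 + scaling$m * A
}
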