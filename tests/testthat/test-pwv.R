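make_ramp <- function(dt = 5e-4, t_on = 0.2, slope = 5, t_end = 0.4) {
  tt <- seq(0, t_end, by = dt)
  uts(pmax(0, (tt - t_on)) * slope, dt = dt, quantity = "area", units = "m2")
}

test_that("foot of a flat-then-ramp signal is the ramp onset", {
  s <- make_ramp()
  f <- suppressWarnings(detect_foot(s)) # flat baseline ties the minimum
  expect_equal(f$t_foot, 0.2, tolerance = 2e-4)
  expect_true(f$t_min <= f$t_foot && f$t_foot <= f$t_maxslope)

  # translation equivariance: +15 ms shift moves the foot by +15 ms
  s2 <- make_ramp(t_on = 0.215)
  f2 <- suppressWarnings(detect_foot(s2))
  expect_equal(f2$t_foot - f$t_foot, 0.015, tolerance = 2e-4)
})

test_that("foot detection is invariant under positive affine amplitude scaling", {
  P <- synth_pressure_cycle()
  f0 <- detect_foot(P)
  for (ab in list(c(3, 0), c(0.25, 500), c(7, -2000))) {
    s <- uts(ab[1] * P$values + ab[2], dt = P$dt, quantity = "pressure", units = "Pa")
    expect_equal(detect_foot(s)$t_foot, f0$t_foot, tolerance = 1e-9)
  }
})

test_that("foot matches a 100x-oversampled brute-force intersection", {
  # Gaussian-smoothed ramp has the closed form s*sigma*(z*pnorm(z)+dnorm(z))
  sig <- 5e-3; slope <- 5; t_on <- 0.2
  f_smooth <- function(t) {
    z <- (t - t_on) / sig
    slope * sig * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  coarse <- uts(f_smooth(seq(0, 0.4, by = 1e-3)), dt = 1e-3,
                quantity = "area", units = "m2")
  got <- suppressWarnings(detect_foot(coarse))$t_foot # baseline underflows to ties

  # brute force at 100x sampling: discrete max-slope tangent vs minimum line
  tt <- seq(0, 0.4, by = 1e-5)
  v <- f_smooth(tt)
  d <- diff(v) / 1e-5
  i <- which.max(d)
  t_ms <- tt[i] + 0.5e-5
  v_ms <- (v[i] + v[i + 1]) / 2
  oracle <- t_ms - (v_ms - min(v)) / max(d)
  expect_equal(got, oracle, tolerance = 5e-4)
})

test_that("foot detection rejects non-rising signals", {
  flat <- uts(rep(1, 100), dt = 1e-3, quantity = "area", units = "m2")
  expect_error(suppressWarnings(detect_foot(flat)))
  falling <- uts(seq(10, 1, length.out = 100), dt = 1e-3,
                 quantity = "area", units = "m2")
  expect_error(detect_foot(falling))
})

test_that("transit-time PWV recovers constructed pure delays within 1%", {
  P <- synth_pressure_cycle()
  # several speeds; all give delays of >= 5 samples over 60 mm
  for (c0 in c(6, 9, 11)) {
    law <- law_const(c0)
    kd <- kinematic_dataset(P, law, RHO, mode = "pure_delay")
    pw <- estimate_pwvd(kd$S1$A, kd$S2$A, kd$meta$separation)
    expect_equal(as.numeric(pw), c0, tolerance = 0.01)
  }
  # hand case: 10 ms delay over 0.060 m is 6 m/s
  kd <- kinematic_dataset(P, law_const(6), RHO, mode = "pure_delay")
  expect_equal(attr(estimate_pwvd(kd$S1$A, kd$S2$A, 0.060), "delay_s"),
               0.010, tolerance = 1e-4)
  # swapped stations: non-positive delay is an error
  expect_error(estimate_pwvd(kd$S2$A, kd$S1$A, 0.060), "non-positive")
})

test_that("theoretical PWV is flat for a constant-speed law", {
  P <- synth_pressure_cycle()
  law <- law_const(10)
  A <- area_series(law, P)
  pt <- theoretical_pwv(P, A, RHO)
  expect_lt(max(abs(pt$values - 10)) / 10, 0.005)
})

test_that("theoretical PWV matches the single-point Bramwell-Hill formula", {
  # sqrt(A/rho * dP/dA) with A = 3.0e-6, dP/dA = 3.533e10 -> 10.0 m/s
  expect_equal(sqrt(3.0e-6 / 1060 * 3.533e10), 10.0, tolerance = 1e-3)
})

test_that("theoretical PWV tracks the analytic law at unmasked samples", {
  P <- synth_pressure_cycle()
  for (law in list(law_linear(), tube_law_radial(), tube_law_carotid())) {
    A <- area_series(law, P)
    pt <- theoretical_pwv(P, A, RHO)
    ok <- !attr(pt, "masked")
    truth <- analytic_pwv(law, A$values[ok], RHO)
    expect_lt(max(abs(pt$values[ok] - truth) / truth), 0.01, label = law$kind)
  }
})

test_that("theoretical PWV rejects mismatched grids and inverted stiffness", {
  P <- synth_pressure_cycle()
  law <- tube_law_radial()
  A <- area_series(law, P)
  A_short <- uts(A$values[-1], dt = A$dt, quantity = "area", units = "m2")
  expect_error(theoretical_pwv(P, A_short, RHO), "grid")
  # area strictly decreasing in pressure: non-physical dP/dA < 0 everywhere
  A_neg <- uts(2 * mean(A$values) - A$values, dt = A$dt,
               quantity = "area", units = "m2")
  expect_error(theoretical_pwv(P, A_neg, RHO), "non-physical")
})

test_that("systolic PWV extraction takes the cycle maximum", {
  s <- uts(rep(10, 50), dt = 1e-3, quantity = "pwv", units = "m_per_s")
  expect_identical(extract_pwvs(s), 10)
  P <- synth_pressure_cycle()
  law <- law_linear()
  A <- area_series(law, P)
  pt <- theoretical_pwv(P, A, RHO)
  expect_equal(extract_pwvs(pt), analytic_pwv(law, max(A$values), RHO),
               tolerance = 0.01)
})

test_that("upstroke linearity fit recovers an exact linear generator", {
  P <- synth_pressure_cycle()
  law <- law_linear(a = 8, b = 2e7 / 33)
  A <- area_series(law, P)
  pwv <- uts(analytic_pwv(law, A$values, RHO), dt = P$dt,
             quantity = "pwv", units = "m_per_s")
  fit <- fit_linear_scaling(pwv, A)
  expect_equal(fit$slope, 2e7 / 33, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_linear_scaling(pwv, A, window = c(0, 1e-3)), "10 samples")
})

test_that("linear scaling reproduces its endpoints exactly", {
  sc <- build_scaling(PWVd = 8, PWVs = 12, A_d = 1.0e-6, A_s = 1.2e-6)
  expect_equal(sc$m, 2.0e7)
  expect_equal(sc$C1, -12)
  expect_equal(scaling_pwv(sc, sc$A_d), sc$PWVd, tolerance = 1e-14)
  expect_equal(scaling_pwv(sc, sc$A_s), sc$PWVs, tolerance = 1e-14)
  sc0 <- build_scaling(10, 10, 1e-6, 1.2e-6)
  expect_identical(sc0$m, 0)
  expect_identical(sc0$C1, 10)
  expect_error(build_scaling(8, 12, 1.2e-6, 1.0e-6), "exceed")
  expect_warning(build_scaling(12, 8, 1.0e-6, 1.2e-6), "inverted")
})
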