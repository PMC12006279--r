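test_that("every model returns exactly P0 where A equals A0", {
  P <- synth_pressure_cycle()
  law <- tube_law_radial()
  A <- area_series(law, P)
  calib <- diastolic_calibration(P, A)
  i0 <- attr(calib, "index")
  m1 <- predict_m1(A, 10, calib, RHO)
  expect_identical(m1$P_pred$values[i0], calib$P0)
  sc <- build_scaling(10, 12, calib$A0, max(A$values))
  m2 <- predict_m2(A, sc, calib, RHO)
  expect_identical(m2$P_pred$values[i0], calib$P0)
  pwv <- uts(rep(10, length(A)), dt = A$dt, quantity = "pwv", units = "m_per_s")
  g <- predict_general(A, pwv, calib, RHO)
  expect_identical(g$P_pred$values[i0], calib$P0)
})

test_that("model 1 evaluates the logarithmic closed form (hand value)", {
  # rho = 1060, PWVd = 10, A/A0 = 1.1, P0 = 80 mmHg -> 155.78 mmHg
  A0 <- 3e-6
  A <- uts(c(A0, 1.1 * A0, A0), dt = 1e-3, quantity = "area", units = "m2")
  calib <- calibration_point(mmhg_to_pa(80), A0)
  m1 <- predict_m1(A, 10, calib, 1060)
  expect_equal(pa_to_mmhg(m1$P_pred$values[2]), 155.78, tolerance = 1e-4)
  expect_error(predict_m1(A, -1, calib, 1060), "positive")
})

test_that("model 2 evaluates its three-term bracket (hand value)", {
  # scaling {8, 12, 1.0e-6, 1.2e-6} -> m = 2e7, C1 = -12;
  # dP = 1060 * (144 ln 1.2 + 88 - 96) = 19349.6 Pa at A = A_s
  sc <- build_scaling(8, 12, 1.0e-6, 1.2e-6)
  calib <- calibration_point(mmhg_to_pa(75), 1.0e-6)
  A <- uts(c(1.0e-6, 1.2e-6, 1.0e-6), dt = 1e-3, quantity = "area", units = "m2")
  m2 <- predict_m2(A, sc, calib, 1060)
  expect_equal(m2$P_pred$values[2] - calib$P0, 19349.6, tolerance = 1e-4)
})

test_that("model 2 reduces to model 1 when the scaling slope vanishes", {
  P <- synth_pressure_cycle()
  law <- tube_law_carotid()
  A <- area_series(law, P)
  calib <- diastolic_calibration(P, A)
  sc <- build_scaling(9.3, 9.3, calib$A0, max(A$values)) # m = 0, C1 = 9.3
  m2 <- predict_m2(A, sc, calib, RHO)
  m1 <- predict_m1(A, 9.3, calib, RHO)
  expect_equal(m2$P_pred$values, m1$P_pred$values, tolerance = 1e-14)
})

test_that("model 1 is exact on constant-speed data, model 2 on linear-speed data", {
  P <- synth_pressure_cycle()
  # constant law: M1 with PWVd = c0 reproduces the true pressure
  lawc <- law_const(10)
  Ac <- area_series(lawc, P)
  calc <- diastolic_calibration(P, Ac)
  m1 <- predict_m1(Ac, 10, calc, RHO)
  expect_lt(max(abs(m1$P_pred$values - P$values)) / max(P$values), 1e-9)
  # linear law with oracle endpoints: M2 reproduces the true pressure
  lawl <- law_linear()
  Al <- area_series(lawl, P)
  call <- diastolic_calibration(P, Al)
  A_s <- max(Al$values)
  sc <- build_scaling(analytic_pwv(lawl, call$A0, RHO),
                      analytic_pwv(lawl, A_s, RHO), call$A0, A_s)
  m2 <- predict_m2(Al, sc, call, RHO)
  expect_lt(max(abs(m2$P_pred$values - P$values)) / max(P$values), 1e-9)
})

test_that("on stiffening data M1 underpredicts and M2 beats it", {
  P <- synth_pressure_cycle()
  law <- tube_law_radial()
  A <- area_series(law, P)
  calib <- diastolic_calibration(P, A)
  A_s <- max(A$values)
  c_d <- analytic_pwv(law, calib$A0, RHO)
  m1 <- predict_m1(A, c_d, calib, RHO)
  sc <- build_scaling(c_d, analytic_pwv(law, A_s, RHO), calib$A0, A_s)
  m2 <- predict_m2(A, sc, calib, RHO)
  e1 <- peak_systole_error(m1, P)
  e2 <- peak_systole_error(m2, P)
  expect_lt(attr(e1, "signed_mmhg"), 0) # systolic underprediction
  expect_lt(as.numeric(e2), as.numeric(e1))
})

test_that("M1 never exceeds truth when PWV is non-decreasing in area", {
  P <- synth_pressure_cycle()
  for (law in list(tube_law_radial(), law_linear())) {
    A <- area_series(law, P)
    calib <- diastolic_calibration(P, A)
    m1 <- predict_m1(A, analytic_pwv(law, calib$A0, RHO), calib, RHO)
    above <- A$values >= calib$A0
    expect_true(all(m1$P_pred$values[above] <= P$values[above] + 1e-6),
                label = law$kind)
  }
})

test_that("the general integral matches both closed forms", {
  P <- synth_pressure_cycle()
  law <- tube_law_radial()
  A <- area_series(law, P)
  calib <- diastolic_calibration(P, A)
  # constant integrand -> M1
  pwv_c <- uts(rep(10, length(A)), dt = A$dt, quantity = "pwv", units = "m_per_s")
  g1 <- predict_general(A, pwv_c, calib, RHO)
  m1 <- predict_m1(A, 10, calib, RHO)
  expect_lt(max(abs(g1$P_pred$values - m1$P_pred$values)) / max(P$values), 1e-6)
  # affine integrand -> M2
  sc <- build_scaling(9, 13, calib$A0, max(A$values))
  pwv_l <- uts(scaling_pwv(sc, A$values), dt = A$dt, quantity = "pwv",
               units = "m_per_s")
  g2 <- predict_general(A, pwv_l, calib, RHO)
  m2 <- predict_m2(A, sc, calib, RHO)
  expect_lt(max(abs(g2$P_pred$values - m2$P_pred$values)) / max(P$values), 1e-6)
})

test_that("the Bramwell-Hill round trip recovers the true pressure", {
  P <- synth_pressure_cycle()
  for (law in list(tube_law_radial(), tube_law_carotid())) {
    A <- area_series(law, P)
    pt <- theoretical_pwv(P, A, RHO)
    g <- predict_general(A, pt, diastolic_calibration(P, A), RHO)
    expect_lt(pa_to_mmhg(max(abs(g$P_pred$values - P$values))), 0.1,
              label = law$kind)
  }
})

test_that("model 2 checks calibration consistency with the scaling", {
  P <- synth_pressure_cycle()
  law <- tube_law_radial()
  A <- area_series(law, P)
  sc <- build_scaling(10, 12, min(A$values), max(A$values))
  off <- calibration_point(mmhg_to_pa(75), 1.01 * min(A$values))
  expect_error(predict_m2(A, sc, off, RHO), "A_d")
  expect_s3_class(predict_m2(A, sc, off, RHO, check_calib = FALSE),
                  "predicted_bp")
})
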