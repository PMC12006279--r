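test_that("waveform CSV write -> read is the identity at full precision", {
  s <- uts(c(1, 2, 3) + pi * 1e-7, dt = 0.001, quantity = "pressure", units = "Pa")
  p <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(s, p)
  r <- read_waveform_csv(p)
  expect_identical(r$values, s$values)
  expect_equal(r$dt, s$dt, tolerance = 1e-12)
  expect_identical(r$quantity, "pressure")
  expect_identical(r$units, "Pa")

  # longer random series round-trips bit-exactly too
  set.seed(7)
  s2 <- uts(runif(257, 9000, 16000), dt = 5e-4, quantity = "area", units = "m2")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(s2, p2)
  expect_identical(read_waveform_csv(p2)$values, s2$values)
})

test_that("waveform CSV rejects malformed input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,pressure_Pa", "0,1", "0.001,2", "0.003,3"), p)
  expect_error(read_waveform_csv(p), "non-uniform")
  writeLines(c("time_s,pressure_Pa", "0,1", "0.001,two"), p)
  expect_error(read_waveform_csv(p), "non-numeric")
  s <- uts(c(1, 2, 3), dt = 1e-3, quantity = "flow", units = "m3_per_s")
  s$values[2] <- NaN # invariant broken after construction
  expect_error(write_waveform_csv(s, p), "finite")
  expect_error(uts(c(1, NA, 3), dt = 1e-3, quantity = "flow", units = "x"), "finite")
})

test_that("extract_last_cycle returns the final period window re-timed to zero", {
  Tc <- 0.8; dt <- 1e-3
  one <- sin(2 * pi * (0:(round(Tc / dt) - 1)) * dt / Tc)
  s <- uts(rep(one, 5), dt = dt, quantity = "pressure", units = "Pa")
  lc <- extract_last_cycle(s, Tc)
  expect_equal(lc$values, one, tolerance = 0)
  expect_identical(lc$t0, 0)
  expect_identical(length(lc), as.integer(round(Tc / dt)))

  # trending series: pure index arithmetic (round(T/dt) trailing samples)
  tr <- uts(seq_len(1000), dt = dt, quantity = "flow", units = "x")
  w <- extract_last_cycle(tr, 0.25)
  expect_identical(w$values, as.numeric(751:1000))

  # exactly one period is the identity up to the t0 reset
  s1 <- uts(one, dt = dt, t0 = 3, quantity = "pressure", units = "Pa")
  expect_equal(extract_last_cycle(s1, Tc)$values, one)
  expect_error(extract_last_cycle(s1, 2 * Tc), "duration")
  expect_error(extract_last_cycle(s1, -1), "positive")
})

test_that("area_from_diameter matches hand-evaluated lumen areas", {
  expect_equal(area_from_diameter(2.064e-3), 3.3458e-6, tolerance = 1e-4)
  expect_equal(area_from_diameter(6.4e-3), 3.2170e-5, tolerance = 1e-4)
  expect_equal(area_from_diameter(2 / sqrt(pi)), 1)
  expect_error(area_from_diameter(0), "positive")
})

test_that("percent_variation is min-referenced and scale-invariant", {
  expect_equal(percent_variation(5, 5), 0)
  expect_equal(percent_variation(10, 15), 50)
  expect_equal(percent_variation(8.33, 9.87), 18.5, tolerance = 1e-2)
  for (k in c(0.1, 3, 1e6)) {
    expect_equal(percent_variation(k * 8.33, k * 9.87),
                 percent_variation(8.33, 9.87))
  }
  expect_error(percent_variation(0, 1), "positive")
  expect_error(percent_variation(2, 1), ">=")
})

test_that("pressure unit conversion is exact and invertible", {
  expect_identical(mmhg_to_pa(0), 0)
  expect_equal(mmhg_to_pa(1), 133.322387415)
  expect_equal(mmhg_to_pa(100), 13332.24, tolerance = 1e-6)
  x <- c(0.001, 75, 120, 1e4)
  expect_equal(pa_to_mmhg(mmhg_to_pa(x)), x, tolerance = 1e-12)
})

test_that("domain type constructors enforce their invariants", {
  expect_error(uts(numeric(0), dt = 1e-3, quantity = "flow", units = "x"), "at least one")
  expect_error(uts(1:3, dt = 0, quantity = "flow", units = "x"), "positive")
  expect_error(artery_spec("bad", D0 = -1, h = 1e-4, L_total = 0.1), "out of range")
  expect_error(measurement_plan(0.09, 0.03), "x1 < x2")
  expect_error(measurement_plan(0.036, 0.2, L_total = 0.11), "x1 < x2")
  mp <- measurement_plan()
  expect_equal(mp$separation, 0.060)
})
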