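test_that("smoothing-spline fit reproduces a known generating function", {
  hr <- seq(50, 130, by = 5)
  tab <- data.frame(hr_bpm = hr, systolic_s = 0.4 - 0.001 * hr,
                    diastolic_s = 60 / hr - (0.4 - 0.001 * hr))
  model <- fit_phase_duration_splines(tab)
  grid <- seq(50, 130, by = 1)
  pred <- vapply(grid, function(h) phase_durations(model, h)[["systolic_s"]],
                 numeric(1))
  expect_lt(max(abs(pred - (0.4 - 0.001 * grid))), 0.001)  # within 1 ms
})

test_that("near-interpolating fit passes through tabulated knots", {
  tab <- phase_duration_reference(seq(50, 120, by = 10))
  model <- fit_phase_duration_splines(tab, spar = 0)
  for (h in c(60, 90, 110)) {
    expect_equal(phase_durations(model, h)[["systolic_s"]],
                 tab$systolic_s[tab$hr_bpm == h], tolerance = 1e-6)
  }
})

test_that("reference-table preconditions are enforced", {
  tab <- phase_duration_reference()[1:3, ]
  expect_error(fit_phase_duration_splines(tab), "insufficient")
  bad <- phase_duration_reference()
  bad$systolic_s[2] <- -0.1
  expect_error(fit_phase_duration_splines(bad), "positive")
  expect_error(fit_phase_duration_splines(data.frame(x = 1)), "columns")
})

test_that("evaluation outside the heart-rate range clamps with a warning", {
  model <- fit_phase_duration_splines(phase_duration_reference())
  expect_warning(lo <- phase_durations(model, 20), "clamped")
  expect_equal(unname(lo["systolic_s"]),
               unname(phase_durations(model, 40)[["systolic_s"]]))
})

test_that("timing scaling is the identity at the resting heart rate", {
  model <- fit_phase_duration_splines(phase_duration_reference())
  rest <- cardiac_timing(60, 0.02, 0.39, source = "doppler")
  scaled <- scale_timing(rest, 60, model)
  expect_equal(scaled$avc_time, rest$avc_time, tolerance = 1e-9)
  expect_equal(scaled$cycle_length, rest$cycle_length, tolerance = 1e-9)
  expect_identical(scaled$source, "scaled")
})

test_that("timing scaling follows the systolic-fraction ratio", {
  # systolic fraction rising linearly from 0.37 at HR 60 to 0.44 at HR 120:
  # at HR 120 a 0.37 s resting systole must scale to 0.44 * 0.5 = 0.22 s
  hr <- seq(50, 130, by = 5)
  frac <- 0.37 + (hr - 60) * (0.44 - 0.37) / 60
  tab <- data.frame(hr_bpm = hr, systolic_s = frac * 60 / hr,
                    diastolic_s = (1 - frac) * 60 / hr)
  model <- fit_phase_duration_splines(tab, spar = 0)
  rest <- cardiac_timing(60, 0, 0.37, source = "doppler")
  ex <- scale_timing(rest, 120, model)
  expect_equal(ex$cycle_length, 0.5, tolerance = 1e-9)
  expect_equal(ex$avc_time - ex$mvc_time, 0.22, tolerance = 1e-3)
})

test_that("scaling refuses non-rest sources and infeasible windows", {
  model <- fit_phase_duration_splines(phase_duration_reference())
  rest <- cardiac_timing(60, 0, 0.39, source = "doppler")
  scaled <- scale_timing(rest, 90, model)
  expect_error(scale_timing(scaled, 100, model), "doppler or visual")
  # resting systole almost filling the cycle cannot fit at high rate
  long_sys <- cardiac_timing(60, 0, 0.95, source = "visual")
  expect_error(suppressWarnings(scale_timing(long_sys, 135, model)),
               "infeasible")
})

test_that("packaged reference table has the expected rate dependence", {
  model <- fit_phase_duration_splines(phase_duration_reference())
  hr <- seq(60, 120, by = 5)
  sys <- vapply(hr, function(h) phase_durations(model, h)[["systolic_s"]],
                numeric(1))
  expect_true(all(diff(sys) < 0))             # absolute systole shortens
  expect_true(all(diff(sys * hr / 60) > 0))   # systolic fraction rises
})

test_that("ejection frame counting uses the half-open [MVC, AVC) window", {
  t1 <- cardiac_timing(88, 0, 0.34, cycle_length = 60 / 88,
                       source = "visual")
  expect_true(ejection_frame_count(t1, 90) %in% c(30, 31))
  t2 <- cardiac_timing(60, 0, 0.5, source = "visual")
  expect_identical(ejection_frame_count(t2, 50), 25L)
  # near-degenerate window keeps only the MVC sample
  t3 <- cardiac_timing(60, 0, 1e-6, source = "visual")
  expect_identical(ejection_frame_count(t3, 50), 1L)
})

test_that("cardiac_timing validates its invariants", {
  expect_error(cardiac_timing(60, 0.5, 0.3), "invalid timing")
  expect_error(cardiac_timing(60, 0, 0.4, cycle_length = 1.2),
               "inconsistent")
})
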