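make_curve <- function(systolic, diastolic = NULL) {
  # systolic values become the samples inside [MVC, AVC]; a short diastolic
  # tail completes the cycle
  if (is.null(diastolic)) {
    diastolic <- rep(systolic[length(systolic)], 3)
  }
  s <- c(systolic, diastolic)
  fr <- 50
  n <- length(s)
  tm <- cardiac_timing(heart_rate = 60 / (n / fr), mvc_time = 0,
                       avc_time = (length(systolic) - 1) / fr + 1e-9,
                       cycle_length = n / fr, source = "visual")
  strain_curve(time = (seq_len(n) - 1) / fr, strain = s, timing = tm,
               frame_rate = fr)
}

test_that("systolic decomposition reproduces worked sign-run examples", {
  segs <- segment_systole(make_curve(c(0, -5, -3, -8, -6, -10)))
  expect_identical(segs$type,
                   c("shortening", "stretch", "shortening", "stretch",
                     "shortening"))
  expect_equal(segs$change, c(-5, 2, -5, 2, -4))
  expect_false(any(segs$pre_shortening_stretch))
  expect_equal(compute_srs(segs), 4)
  expect_equal(compute_ss(segs), 14)

  mono <- segment_systole(make_curve(c(0, -4, -8, -12)))
  expect_identical(nrow(mono), 1L)
  expect_equal(mono$change, -12)
  expect_equal(compute_srs(mono), 0)
  expect_equal(compute_ss(mono), 12)

  pre <- segment_systole(make_curve(c(0, 2, -6, -10)))
  expect_identical(pre$type, c("stretch", "shortening"))
  expect_true(pre$pre_shortening_stretch[1])
  expect_equal(pre$change, c(2, -12))
  expect_equal(compute_srs(pre), 0)  # pre-shortening stretch excluded
  expect_equal(compute_ss(pre), 12)
})

test_that("all-stretch systole yields zero shortening", {
  segs <- segment_systole(make_curve(c(0, 1, 2), diastolic = c(1, 0, 0)))
  expect_equal(compute_ss(segs), 0)
  expect_equal(compute_srs(segs), 0)  # stretch never follows shortening
})

test_that("window preconditions are enforced", {
  c2 <- make_curve(c(0, -5, -3, -8))
  c2$timing$avc_time <- 0.5 / 50
  expect_error(segment_systole(c2), "too short")
})

test_that("SDI is the stretch/shortening ratio with a division guard", {
  expect_equal(compute_sdi(4, 14), 4 / 14, tolerance = 1e-12)
  expect_equal(compute_sdi(0, 10), 0)
  expect_error(compute_sdi(3, 0), "undefined")
})

test_that("SDI is invariant to amplitude scaling and resampling", {
  base <- c(0, -5, -3, -8, -6, -10)
  for (c_scale in c(0.25, 2, 7)) {
    idx <- discoordination_indices(make_curve(base * c_scale))
    expect_equal(idx$sdi, 4 / 14, tolerance = 1e-12)
  }
  # same shape sampled twice as densely (linear interpolation)
  dense <- approx(seq_along(base), base, n = 11)$y
  fr <- 50
  tm <- cardiac_timing(60 / (14 / fr), 0, 10 / fr + 1e-9,
                       cycle_length = 14 / fr, source = "visual")
  cd <- strain_curve((0:13) / fr, c(dense, -10, -10, -10), tm,
                     frame_rate = fr)
  expect_equal(discoordination_indices(cd)$sdi, 4 / 14, tolerance = 1e-12)
})

test_that("decomposition matches the brute-force oracle on random curves", {
  for (seed in 1:300) {
    cv <- random_curve(seed)
    segs <- segment_systole(cv)
    idx_sys <- which(cv$time <= cv$timing$avc_time + 1e-9)
    orc <- oracle_decompose(cv$strain[idx_sys])
    expect_equal(compute_ss(segs), orc$ss, tolerance = 1e-12)
    expect_equal(compute_srs(segs), orc$srs, tolerance = 1e-12)
    pre_str <- sum(segs$change[segs$type == "stretch" &
                                 segs$pre_shortening_stretch])
    expect_equal(pre_str, orc$pre, tolerance = 1e-12)
  }
})

test_that("telescoping identity holds exactly", {
  for (seed in 301:500) {
    cv <- random_curve(seed)
    segs <- segment_systole(cv)
    ss <- compute_ss(segs)
    srs <- compute_srs(segs)
    pre <- sum(segs$change[segs$type == "stretch" &
                             segs$pre_shortening_stretch])
    idx_sys <- which(cv$time <= cv$timing$avc_time + 1e-9)
    delta <- cv$strain[max(idx_sys)] - cv$strain[1]
    expect_lt(abs(ss - (srs + pre) - (-delta)), 1e-9)
  }
})

test_that("a noise floor suppresses micro-oscillations", {
  cv <- make_curve(c(0, -5, -4.98, -8, -6, -10))
  expect_equal(compute_srs(segment_systole(cv)), 2.02, tolerance = 1e-9)
  segs <- segment_systole(cv, noise_floor = 0.05)
  expect_equal(compute_srs(segs), 2, tolerance = 1e-9)
})

test_that("SDI response classification covers the three patterns", {
  expect_identical(classify_sdi_response(0.40, 0.20, 0.25),
                   "consistent_improvement")
  expect_identical(classify_sdi_response(0.20, 0.28, 0.30),
                   "consistent_worsening")
  expect_identical(classify_sdi_response(0.30, 0.20, 0.35), "reciprocal")
  expect_error(classify_sdi_response(NA, 0.2, 0.3), "undefined")
})
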