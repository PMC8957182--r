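test_that("pattern validation rejects inconsistent targets", {
  expect_error(strain_pattern("non_lbbb_type", target_ss = 15,
                              target_srs = 2), "invalid pattern")
  expect_error(strain_pattern("lbbb_type", target_ss = 3, target_srs = 4),
               "infeasible")
  expect_error(strain_pattern("lbbb_type", target_ss = 14, target_srs = 4,
                              peak_systolic_strain = -16),
               "infeasible")
  expect_error(strain_pattern("lbbb_type", target_ss = 14, target_srs = 4,
                              peak_systolic_strain = -5),
               "infeasible")
})

test_that("non-LBBB curves shorten monotonically through systole", {
  curve <- generate_strain_curve(strain_pattern("non_lbbb_type", 15),
                                 timing_for_hr(60), 90, seed = 2)
  idx <- which(curve$time <= curve$timing$avc_time + 1e-9)
  expect_true(all(diff(curve$strain[idx]) <= 0))
  idx_res <- discoordination_indices(curve)
  expect_equal(idx_res$srs_sept, 0)
  expect_equal(idx_res$ss, 15, tolerance = 0.05)
})

test_that("generated curves hit their SS and SRS targets", {
  cases <- expand.grid(ss = c(8, 14, 20), srs = c(0, 2, 4, 6),
                       hr = c(60, 90), fr = c(50, 90))
  cases <- cases[cases$ss - cases$srs >= 4, ]
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    fam <- if (cs$srs > 0) "lbbb_type" else "non_lbbb_type"
    curve <- generate_strain_curve(strain_pattern(fam, cs$ss, cs$srs),
                                   timing_for_hr(cs$hr), cs$fr, seed = i)
    idx <- discoordination_indices(curve)
    expect_equal(idx$ss, cs$ss, tolerance = 0.05)
    expect_equal(idx$srs_sept, cs$srs, tolerance = 0.05)
    # analytic SDI of the generated curve equals target_srs / target_ss
    if (cs$srs > 0) {
      expect_equal(idx$sdi, cs$srs / cs$ss, tolerance = 1e-2)
    }
    expect_identical(length(curve$time),
                     as.integer(round(curve$timing$cycle_length * cs$fr)))
    expect_equal(curve$strain[1], 0)
  }
})

test_that("pre-stretch and a prescribed peak are honoured", {
  pat <- strain_pattern("lbbb_type", target_ss = 14, target_srs = 4,
                        pre_stretch = 1.5)
  curve <- generate_strain_curve(pat, timing_for_hr(70), 90, seed = 5)
  segs <- segment_systole(curve)
  pre <- sum(segs$change[segs$pre_shortening_stretch])
  expect_equal(pre, 1.5, tolerance = 0.05)
  expect_equal(compute_srs(segs), 4, tolerance = 0.05)
  expect_equal(compute_ss(segs), 14, tolerance = 0.05)

  pat2 <- strain_pattern("lbbb_type", target_ss = 14, target_srs = 4,
                         peak_systolic_strain = -12)
  curve2 <- generate_strain_curve(pat2, timing_for_hr(70), 90, seed = 5)
  expect_equal(min(curve2$strain), -12, tolerance = 0.05)
  idx2 <- discoordination_indices(curve2)
  expect_equal(idx2$ss, 14, tolerance = 0.05)
  expect_equal(idx2$srs_sept, 4, tolerance = 0.05)
})

test_that("generation is deterministic under a fixed seed", {
  pat <- strain_pattern("lbbb_type", 14, 4)
  a <- generate_strain_curve(pat, timing_for_hr(75), 90, seed = 42)
  b <- generate_strain_curve(pat, timing_for_hr(75), 90, seed = 42)
  expect_identical(a$strain, b$strain)
  c <- generate_strain_curve(pat, timing_for_hr(75), 90, seed = 43)
  expect_false(identical(a$strain, c$strain))
})

test_that("generator preconditions are enforced", {
  pat <- strain_pattern("lbbb_type", 14, 4)
  expect_error(generate_strain_curve(pat, timing_for_hr(70), 40), "50")
  tm <- cardiac_timing(70, 0.05, 0.4, source = "visual")
  expect_error(generate_strain_curve(pat, tm, 90), "mvc_time = 0")
})

test_that("post-systolic behaviour switches between recoil and plateau", {
  tm <- timing_for_hr(70)
  rec <- generate_strain_curve(
    strain_pattern("lbbb_type", 14, 4, post_systolic_behavior =
                     "recoil_to_zero"), tm, 90, seed = 2)
  pla <- generate_strain_curve(
    strain_pattern("lbbb_type", 14, 4, post_systolic_behavior =
                     "plateau"), tm, 90, seed = 2)
  n <- length(rec$strain)
  expect_equal(rec$strain[n], 0, tolerance = 1e-9)
  expect_lt(pla$strain[n], -3)  # plateau holds well below baseline
})
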