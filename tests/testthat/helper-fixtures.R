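# Shared fixtures and independent oracles, all built in code.

# reference phase-duration model used throughout
ref_model <- fit_phase_duration_splines(phase_duration_reference())

# a desk-scale band geometry (fits a 260 x 200 px image) so tracking tests
# stay fast; the acceptance tests use the full 800 x 600 default
small_geometry <- function() {
  septal_band_geometry(center = c(130, 290), radius = 190,
                       theta_mid = -pi / 2, half_span = 0.30,
                       thickness = 22)
}

timing_for_hr <- function(hr) {
  cardiac_timing(hr, 0, phase_durations(ref_model, hr)[["systolic_s"]],
                 source = "scaled")
}

quick_truth <- function(ss, srs, hr = 80, frame_rate = 90, seed = 1,
                        geometry = small_geometry()) {
  fam <- if (srs > 0) "lbbb_type" else "non_lbbb_type"
  curve <- generate_strain_curve(strain_pattern(fam, ss, srs),
                                 timing_for_hr(hr), frame_rate, seed = seed)
  ground_truth_cycle(curve, geometry)
}

quick_loop <- function(truth, noise_level = 0, dropout_fraction = 0,
                       seed = 1, intensity = "baseline") {
  synthesize_cine_loop(
    truth,
    acquisition_condition(intensity, truth$timing$heart_rate,
                          truth$strain_curve$frame_rate, noise_level,
                          dropout_fraction),
    image_size = c(260, 200), seed = seed, n_scatterers = 800)
}

quick_track <- function(loop, truth, ...) {
  estimate_displacements(loop, truth$mesh, block_size = 13,
                         search_radius = 4, ...)
}

# a zero-deformation ground truth (static scene)
static_truth <- function(n_frames = 20, geometry = small_geometry()) {
  tm <- cardiac_timing(60, 0, 0.37, source = "visual")
  zc <- strain_curve(time = (seq_len(n_frames) - 1) / 90,
                     strain = rep(0, n_frames), timing = tm,
                     frame_rate = 90)
  ground_truth_cycle(zc, geometry)
}

# Brute-force sign-run oracle for the systolic decomposition: enumerates
# runs of the sign of first differences and sums them, independent of the
# package's rle/merging implementation.
oracle_decompose <- function(s) {
  d <- diff(s)
  ss <- 0; srs <- 0; pre <- 0
  seen_short <- FALSE
  i <- 1
  while (i <= length(d)) {
    if (d[i] == 0) { i <- i + 1; next }
    sgn <- sign(d[i])
    run <- 0
    while (i <= length(d) && (d[i] == 0 || sign(d[i]) == sgn)) {
      run <- run + d[i]; i <- i + 1
    }
    if (sgn < 0) { ss <- ss + abs(run); seen_short <- TRUE }
    else if (seen_short) srs <- srs + run
    else pre <- pre + run
  }
  list(ss = ss, srs = srs, pre = pre)
}

# random piecewise-linear "systolic" strain curve for property tests:
# a strain_curve whose systole spans most of the samples
random_curve <- function(seed, n = 25) {
  set.seed(seed)
  fr <- 50
  n_sys <- n - 4
  incr <- round(stats::rnorm(n - 1, 0, 2), 3)
  s <- c(0, cumsum(incr))
  tm <- cardiac_timing(heart_rate = 60 / (n / fr), mvc_time = 0,
                       avc_time = (n_sys - 1) / fr + 1e-9,
                       cycle_length = n / fr, source = "visual")
  strain_curve(time = (seq_len(n) - 1) / fr, strain = s, timing = tm,
               frame_rate = fr)
}

# Brute-force integer NCC matcher (independent oracle for block matching)
bf_ncc <- function(a, b, r0, c0, r1, c1, bh) {
  av <- a[(r0 - bh):(r0 + bh), (c0 - bh):(c0 + bh)]
  bv <- b[(r1 - bh):(r1 + bh), (c1 - bh):(c1 + bh)]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(as.vector(av), as.vector(bv))
}

bf_match <- function(a, b, px, py, bh, search) {
  # px, py 0-based; returns best integer (dx, dy) by exhaustive search
  c0 <- round(px) + 1; r0 <- round(py) + 1
  best <- -2; bdx <- 0; bdy <- 0
  for (dy in -search:search) {
    for (dx in -search:search) {
      r1 <- r0 + dy; c1 <- c0 + dx
      if (r1 - bh < 1 || r1 + bh > nrow(b) ||
          c1 - bh < 1 || c1 + bh > ncol(b)) next
      v <- bf_ncc(a, b, r0, c0, r1, c1, bh)
      if (v > best) { best <- v; bdx <- dx; bdy <- dy }
    }
  }
  c(bdx, bdy, best)
}

expect_error_matching <- function(expr, pattern) {
  testthat::expect_error(expr, regexp = pattern)
}
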