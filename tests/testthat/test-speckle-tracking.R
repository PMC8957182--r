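test_that("a static loop tracks to zero displacement and zero strain", {
  truth <- static_truth()
  loop <- quick_loop(truth, seed = 2)
  field <- quick_track(loop, truth)
  expect_lt(max(abs(field$dx)), 0.1)
  expect_lt(max(abs(field$dy)), 0.1)
  rec <- accumulate_strain(field, truth$timing)
  expect_lt(max(abs(rec$strain)), 0.05)
})

test_that("uniform translation is recovered within 0.2 px", {
  # speckle band translating rightward at 2 px/frame
  set.seed(31)
  n_sc <- 500
  sx <- runif(n_sc, 20, 160)
  sy <- runif(n_sc, 60, 110)
  amp <- runif(n_sc, 0.2, 1)
  frames <- lapply(0:5, function(k) {
    septostrain:::cpp_render_speckle(sx + 2 * k, sy, amp, 160, 220, 2)
  })
  seq <- image_sequence(frames, 50)
  poly <- rbind(c(25, 65), c(155, 65), c(155, 105), c(25, 105))
  mesh <- build_mesh(poly)
  field <- estimate_displacements(seq, mesh, block_size = 13,
                                  search_radius = 4)
  expect_lt(abs(mean(field$dx) - 2), 0.2)
  expect_lt(abs(mean(field$dy)), 0.2)
  # rigid motion has zero spatial derivative
  tm <- cardiac_timing(60, 0, 0.08, source = "visual")
  rec <- accumulate_strain(field, tm)
  expect_lt(max(abs(rec$strain)), 0.3)
})

test_that("strain is exactly invariant to a constant displacement offset", {
  # straight band: the longitudinal direction is spatially constant, so a
  # rigid shift of every mesh point in every frame cannot create strain
  # (on a curved band, tangent rotation couples rigid motion into apparent
  # strain, which is why drift is reported as a diagnostic there)
  poly <- rbind(c(0, 0), c(300, 0), c(300, 60), c(0, 60))
  mesh <- build_mesh(poly)
  n_frames <- 15
  set.seed(123)
  traj <- array(NA_real_, c(n_frames, 11, 31, 2))
  for (k in seq_len(n_frames)) {
    lam <- 1 - 0.01 * (k - 1)
    traj[k, , , 1] <- 150 + lam * (mesh$points[, , 1] - 150) +
      rnorm(341, 0, 0.1)
    traj[k, , , 2] <- mesh$points[, , 2] + rnorm(341, 0, 0.1)
  }
  field <- structure(list(
    positions = traj, valid = array(TRUE, c(n_frames - 1, 11, 31)),
    mesh = mesh, frame_rate = 50), class = "displacement_field")
  shifted <- field
  for (k in 2:n_frames) {
    shifted$positions[k, , , 1] <- field$positions[k, , , 1] + 17.3
    shifted$positions[k, , , 2] <- field$positions[k, , , 2] - 4.1
  }
  tm <- cardiac_timing(200, 0, 0.2, cycle_length = 15 / 50,
                       source = "visual")
  a <- accumulate_strain(field, tm)
  b <- accumulate_strain(shifted, tm)
  expect_lt(max(abs(a$strain - b$strain)), 1e-9)
})

test_that("an analytic uniform-contraction field yields the exact strain", {
  # longitudinal coordinates contract linearly to a factor 0.9 by cycle
  # mid-point: strain must pass through -10% there
  poly <- rbind(c(0, 0), c(300, 0), c(300, 60), c(0, 60))
  mesh <- build_mesh(poly)
  n_frames <- 21
  mid <- 150
  traj <- array(NA_real_, c(n_frames, 11, 31, 2))
  for (k in seq_len(n_frames)) {
    lam <- 1 - 0.1 * min(k - 1, 10) / 10
    traj[k, , , 1] <- mid + lam * (mesh$points[, , 1] - mid)
    traj[k, , , 2] <- mesh$points[, , 2]
  }
  field <- structure(list(
    positions = traj, valid = array(TRUE, c(n_frames - 1, 11, 31)),
    mesh = mesh, frame_rate = 50), class = "displacement_field")
  tm <- cardiac_timing(143, 0, 0.2, cycle_length = 21 / 50,
                       source = "visual")
  rec <- accumulate_strain(field, tm)
  expect_equal(rec$strain[11], -10, tolerance = 1e-6)
  expect_equal(rec$strain[21], -10, tolerance = 1e-6)
  expect_equal(rec$strain[1], 0)
})

test_that("integer peaks equal a brute-force search over the window", {
  set.seed(77)
  img1 <- matrix(runif(60 * 60), 60, 60)
  # shift img1 by (3, -2) with wraparound to build img2
  img2 <- img1[c(3:60, 1:2), c(59:60, 1:58)]
  px <- c(20, 25, 30, 35)
  py <- c(20, 30, 25, 35)
  m <- septostrain:::cpp_block_match(img1, img2, px, py, 7, 5)
  for (i in seq_along(px)) {
    bf <- bf_match(img1, img2, px[i], py[i], 7, 5)
    expect_identical(m[i, 5], bf[1])
    expect_identical(m[i, 6], bf[2])
    expect_equal(m[i, 3], bf[3], tolerance = 1e-9)
  }
  expect_true(all(m[, 5] == 2) && all(m[, 6] == -2))
})

test_that("blocks leaving the image are flagged invalid, not errors", {
  set.seed(5)
  img <- matrix(runif(50 * 50), 50, 50)
  m <- septostrain:::cpp_block_match(img, img, c(2, 25), c(2, 25), 10, 3)
  expect_identical(m[1, 4], 0)   # near-corner block out of bounds
  expect_identical(m[2, 4], 1)
  expect_true(is.na(m[1, 1]))
})

test_that("full tracking recovers generator strain within tolerance", {
  cases <- list(c(10, 0, 90), c(16, 5, 70))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    truth <- quick_truth(cs[1], cs[2], hr = cs[3], seed = 40 + i)
    loop <- quick_loop(truth, seed = 50 + i)
    field <- quick_track(loop, truth)
    rec <- accumulate_strain(field, truth$timing)
    expect_lt(sqrt(mean((rec$strain - truth$strain_curve$strain)^2)), 1)
    idx <- discoordination_indices(rec)
    expect_lt(abs(idx$ss - cs[1]), 1.5)
    expect_lt(abs(idx$srs_sept - cs[2]), 1.5)
  }
})

test_that("tracking is deterministic for identical inputs", {
  truth <- quick_truth(12, 3, seed = 8)
  loop <- quick_loop(truth, noise_level = 0.2, seed = 13)
  f1 <- quick_track(loop, truth)
  f2 <- quick_track(loop, truth)
  expect_identical(f1$dx, f2$dx)
  expect_identical(f1$dy, f2$dy)
  r1 <- accumulate_strain(f1, truth$timing)
  r2 <- accumulate_strain(f2, truth$timing)
  expect_identical(r1$strain, r2$strain)
})

test_that("strain is undefined when most of the mesh is lost", {
  truth <- quick_truth(12, 3, seed = 9)
  loop <- quick_loop(truth, seed = 14)
  field <- quick_track(loop, truth)
  field$valid[3, , 1:20] <- FALSE  # 64% of points invalid in one pair
  expect_error(accumulate_strain(field, truth$timing), "undefined")
})
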