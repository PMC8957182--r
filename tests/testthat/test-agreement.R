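test_that("curve similarity handles resampling and normalisation", {
  curve <- generate_strain_curve(strain_pattern("lbbb_type", 14, 4),
                                 timing_for_hr(60), 90, seed = 3)
  short <- approx(seq(0, 1, length.out = length(curve$strain)),
                  curve$strain, xout = seq(0, 1, length.out = 60))$y
  expect_gt(curve_similarity(curve$strain, short), 0.995)
  expect_equal(curve_similarity(curve$strain, -curve$strain), -1,
               tolerance = 1e-12)
  expect_equal(curve_similarity(curve$strain, 2 * curve$strain), 1,
               tolerance = 1e-12)
  # symmetry in the arguments
  a <- curve$strain
  b <- short + 0.5 * sin(seq(0, 6, length.out = 60))
  expect_equal(curve_similarity(a, b), curve_similarity(b, a),
               tolerance = 1e-12)
  expect_error(curve_similarity(rep(1, 50), a), "zero variance")
})

test_that("Bland-Altman matches hand-computed values", {
  ba <- bland_altman(c(10, 8, 9), c(12, 8, 7))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 2)
  expect_equal(ba$loa_low, -3.92)
  expect_equal(ba$loa_high, 3.92)
  expect_identical(ba$n_pairs, 3L)

  same <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$bias, 0)
  expect_equal(same$sd, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  expect_error(bland_altman(1, 2), "insufficient")
})

test_that("Bland-Altman invariants: LoA width and sign flip on swap", {
  set.seed(12)
  a <- rnorm(20, 10, 2); b <- a + rnorm(20, 0.5, 1)
  ba <- bland_altman(a, b)
  expect_lt(abs((ba$loa_high - ba$loa_low) - 2 * 1.96 * ba$sd), 1e-9)
  ba_sw <- bland_altman(b, a)
  expect_equal(ba_sw$bias, -ba$bias, tolerance = 1e-12)
  # incomplete pairs are dropped with a message
  a[3] <- NA
  expect_message(ba_na <- bland_altman(a, b), "dropped 1")
  expect_identical(ba_na$n_pairs, 19L)
})

test_that("ICC(A,1) is exact on canonical cases", {
  expect_equal(icc_absolute_single(rbind(c(1, 1), c(2, 2), c(3, 3)))$icc, 1)
  expect_error(icc_absolute_single(matrix(5, 3, 2)), "degenerate")
  expect_error(icc_absolute_single(rbind(c(1, NA), c(2, 3), c(3, 4))),
               "missing")
  expect_error(icc_absolute_single(rbind(c(1, 2), c(2, 3))), "subjects")
})

test_that("ICC(A,1) agrees with an independent ANOVA decomposition", {
  aov_icc <- function(m) {
    # independent route: two-way ANOVA via stats::aov, then McGraw-Wong
    n <- nrow(m); k <- ncol(m)
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(seq_len(n), k)),
                    rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  m_off <- rbind(c(1, 2), c(2, 3), c(3, 4))
  r <- icc_absolute_single(m_off)
  expect_lt(r$icc, 1)
  expect_equal(r$icc, aov_icc(m_off), tolerance = 1e-9)
  set.seed(99)
  for (i in 1:20) {
    m <- matrix(rnorm(20, 10, 3), 10, 2) +
      matrix(rnorm(2, 0, 0.5), 10, 2, byrow = TRUE)
    r <- icc_absolute_single(m)
    expect_equal(r$icc, aov_icc(m), tolerance = 1e-9)
    expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])
  }
})

test_that("ICC(A,1) point estimate and CI match an external reference", {
  # fixed 10 x 2 matrix; reference values computed independently with
  # pingouin.intraclass_corr (ICC(A,1) row): ICC = 0.769925, CI [0.32, 0.94]
  m <- matrix(c(9, 6, 8, 7, 10, 6, 3, 8, 5, 7,
                8, 5, 8, 6, 9, 4, 5, 7, 5, 9), ncol = 2)
  r <- icc_absolute_single(m)
  expect_equal(r$icc, 0.769925, tolerance = 1e-6)
  expect_equal(round(r$ci, 2), c(0.32, 0.94))
})

test_that("ICC estimator recovers known variance components", {
  # y_ij = mu + s_i + r_j + e_ij, var 4 / 0.25 / 1 -> ICC = 4 / 5.25
  set.seed(2024)
  n <- 4000; k <- 2
  s <- rnorm(n, 0, 2)
  r <- rnorm(k, 0, 0.5)
  m <- outer(s, rep(1, k)) + outer(rep(1, n), r) +
    matrix(rnorm(n * k), n, k)
  est <- icc_absolute_single(m)$icc
  expect_lt(abs(est - 4 / 5.25), 0.05)
})

test_that("Cohen's kappa matches hand computation", {
  a <- c(rep("x", 20), rep("x", 5), rep("y", 10), rep("y", 15))
  b <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  # confusion [[20, 5], [10, 15]]: p_o = 0.70, p_e = 0.50, kappa = 0.40
  expect_equal(cohen_kappa(a, b), 0.4, tolerance = 1e-12)
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # agreement exactly at chance: p_o = p_e -> kappa = 0
  a0 <- c("p", "p", "q", "q")
  b0 <- c("p", "q", "p", "q")
  expect_equal(cohen_kappa(a0, b0), 0)
  expect_error(cohen_kappa(c("u", "u"), c("u", "u")), "undefined")
})

test_that("kappa agrees with e1071 and is 1 only for identical vectors", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (i in 1:10) {
    a <- sample(letters[1:3], 40, replace = TRUE)
    b <- ifelse(runif(40) < 0.7, a, sample(letters[1:3], 40, replace = TRUE))
    tab <- table(factor(a, levels = letters[1:3]),
                 factor(b, levels = letters[1:3]))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-9)
    if (!identical(a, b)) expect_lt(cohen_kappa(a, b), 1)
  }
})

test_that("paired t-test guards and matches the closed form", {
  expect_error(paired_ttest(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
  a <- c(3, 1, 4, 0, 5); b <- c(1, 3, 2, 2, 3)
  d <- a - b
  r <- paired_ttest(a, b)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$df, 4)
  # mean difference zero -> t = 0, p = 1
  r0 <- paired_ttest(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
})

test_that("feasibility tally reproduces the accounting structure", {
  # 165 potential loops of which 137 acquired -> 83% acquisition
  n <- 165
  log <- data.frame(
    condition = rep(c("baseline", "vt30", "vt60", "vt90", "recovery"),
                    length.out = n),
    acquired = c(rep(TRUE, 137), rep(FALSE, 28)),
    attended_both_visits = TRUE,
    sufficient_quality = c(rep(TRUE, 105), rep(FALSE, 60)),
    grade = NA_character_)
  tab <- feasibility_tally(log)
  ov <- tab[tab$condition == "overall", ]
  expect_identical(ov$potential, 165L)
  expect_identical(ov$acquired, 137L)
  expect_equal(ov$acquired_pct, 83, tolerance = 0.5)

  perfect <- data.frame(condition = "baseline", acquired = TRUE,
                        attended_both_visits = TRUE,
                        sufficient_quality = TRUE,
                        grade = "good")[rep(1, 10), ]
  tp <- feasibility_tally(perfect)
  expect_true(all(tp$acquired_pct == 100))
  expect_true(all(tp$sufficient_quality_pct == 100))
  expect_identical(tp$good[tp$condition == "overall"], 10L)

  empty <- feasibility_tally(log[0, ])
  expect_identical(nrow(empty), 0L)
})
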