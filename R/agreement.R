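#' Normalised strain-curve similarity
#'
#' Pearson correlation between two strain curves after harmonising their
#' sampling and amplitude: the longer curve is down-sampled by linear
#' interpolation to the shorter curve's sample count (cycle lengths differ
#' when heart rate differs between visits), and each curve is divided by
#' its peak absolute strain. Pearson's r is itself scale-invariant, so the
#' amplitude normalisation affects the returned normalised curves, not r.
#'
#' @param curve_a,curve_b [strain_curve()] objects (or plain numeric
#'   vectors) covering one cycle each.
#' @return Pearson correlation coefficient.
#' @export
curve_similarity <- function(curve_a, curve_b) {
  a <- if (inherits(curve_a, "strain_curve")) curve_a$strain else curve_a
  b <- if (inherits(curve_b, "strain_curve")) curve_b$strain else curve_b
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 3, length(b) >= 3)
  n <- min(length(a), length(b))
  resample <- function(x, n) {
    if (length(x) == n) return(x)
    stats::approx(seq(0, 1, length.out = length(x)), x,
                  xout = seq(0, 1, length.out = n))$y
  }
  a <- resample(a, n); b <- resample(b, n)
  if (max(abs(a)) == 0 || max(abs(b)) == 0 ||
      stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: a curve has zero variance", call. = FALSE)
  }
  a <- a / max(abs(a)); b <- b / max(abs(b))
  stats::cor(a, b)
}

#' Bland-Altman agreement analysis
#'
#' @param value_a,value_b Paired measurements in the same units; incomplete
#'   pairs (NA in either member) are dropped with a message.
#' @param loa_multiplier Multiplier for the limits of agreement (1.96 for
#'   95% limits).
#' @return List with `bias` (mean difference a - b), `sd` (sample SD of
#'   differences), `loa_low`, `loa_high`, `n_pairs`, `n_dropped`.
#' @export
bland_altman <- function(value_a, value_b, loa_multiplier = 1.96) {
  stopifnot(length(value_a) == length(value_b))
  ok <- is.finite(value_a) & is.finite(value_b)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("bland_altman: dropped %d incomplete pair(s)", n_dropped))
  }
  d <- value_a[ok] - value_b[ok]
  if (length(d) < 2) {
    stop("insufficient data: need >= 2 complete pairs", call. = FALSE)
  }
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - loa_multiplier * s,
       loa_high = bias + loa_multiplier * s,
       n_pairs = length(d), n_dropped = n_dropped)
}

#' Intraclass correlation ICC(A,1): two-way model, absolute agreement,
#' single measurement
#'
#' Computed from the two-way ANOVA mean squares (subjects = rows, raters =
#' columns): `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% confidence interval follows the standard F-distribution interval
#' for this form (McGraw & Wong).
#'
#' @param m Complete numeric matrix, subjects in rows, raters/measurements
#'   in columns (n >= 3 subjects, k >= 2 raters). No imputation: missing
#'   cells are an error.
#' @param conf_level Confidence level for the interval.
#' @return List with `icc`, `ci` (length-2 vector), `ms` (the mean
#'   squares), `n`, `k`.
#' @export
icc_absolute_single <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) {
    stop("missing data: ICC requires a complete subjects x raters matrix",
         call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) {
    stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) {
    stop("degenerate variance: ICC denominator is not positive",
         call. = FALSE)
  }
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(lower, upper),
       ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k)
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and chance agreement `p_e` from the product of
#' the marginal distributions.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors (factors or
#'   atomic); the category set is the union of both.
#' @return Kappa coefficient.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b),
            length(ratings_a) >= 2)
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    stop("undefined kappa: chance agreement is 1 (both raters constant)",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Paired Student's t-test on measurement pairs
#'
#' Thin guard around [stats::t.test()] for paired data: differences with
#' zero variance (which make the statistic undefined) raise an error
#' instead of returning infinity.
#'
#' @param value_a,value_b Paired measurements.
#' @return List with `t`, `df`, `p_value`, `mean_difference`, `n_pairs`.
#' @export
paired_ttest <- function(value_a, value_b) {
  stopifnot(length(value_a) == length(value_b))
  ok <- is.finite(value_a) & is.finite(value_b)
  d <- value_a[ok] - value_b[ok]
  if (length(d) < 2) {
    stop("insufficient data: need >= 2 complete pairs", call. = FALSE)
  }
  if (stats::sd(d) == 0) {
    stop("undefined test: differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(value_a[ok], value_b[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate),
       n_pairs = length(d))
}

#' Feasibility accounting across acquisition attempts
#'
#' Tallies, per condition and overall, how many loops were acquired, how
#' many belong to subjects attending both visits, how many passed the
#' quality rule, and the quality-grade distribution - the accounting
#' structure of an exercise-echocardiography feasibility table.
#'
#' @param log Data.frame with one row per potential loop and columns
#'   `condition`, `acquired` (logical), `attended_both_visits` (logical),
#'   `sufficient_quality` (logical) and `grade` (character, NA when not
#'   graded).
#' @return Data.frame with one row per condition plus an `"overall"` row:
#'   counts and percentages at each accounting stage.
#' @export
feasibility_tally <- function(log) {
  req <- c("condition", "acquired", "attended_both_visits",
           "sufficient_quality", "grade")
  if (!all(req %in% names(log))) {
    stop("log must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(log) == 0) {
    return(data.frame(condition = character(0), potential = integer(0),
                      acquired = integer(0), acquired_pct = numeric(0),
                      attended_twice = integer(0),
                      attended_twice_pct = numeric(0),
                      sufficient_quality = integer(0),
                      sufficient_quality_pct = numeric(0),
                      good = integer(0), moderate = integer(0),
                      poor = integer(0)))
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tally_one <- function(d, label) {
    acq <- sum(d$acquired)
    att <- sum(d$acquired & d$attended_both_visits)
    suf <- sum(d$acquired & d$attended_both_visits & d$sufficient_quality)
    gr <- d$grade[d$acquired & !is.na(d$grade)]
    data.frame(condition = label, potential = nrow(d), acquired = acq,
               acquired_pct = pct(acq, nrow(d)),
               attended_twice = att, attended_twice_pct = pct(att, acq),
               sufficient_quality = suf,
               sufficient_quality_pct = pct(suf, acq),
               good = sum(gr == "good"), moderate = sum(gr == "moderate"),
               poor = sum(gr == "poor"))
  }
  conds <- unique(log$condition)
  out <- do.call(rbind, lapply(conds, function(cd) {
    tally_one(log[log$condition == cd, , drop = FALSE], cd)
  }))
  rbind(out, tally_one(log, "overall"))
}
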