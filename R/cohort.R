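#' Default exercise-intensity acquisition conditions
#'
#' One row per measurement point of the exercise protocol (rest, 30/60/90%
#' of the ventilatory threshold, recovery), with typical heart rates for a
#' heart-failure cohort on such a protocol and a default mapping from
#' intensity to image degradation. Higher intensity brings more body motion
#' and respiration, hence more noise and a higher chance of occlusion /
#' out-of-plane signal loss.
#'
#' @param frame_rate Frame rate in Hz applied to all conditions.
#' @return Data.frame with columns `intensity`, `hr_median`, `hr_iqr`,
#'   `noise_level`, `dropout_fraction`, `frame_rate`.
#' @export
default_conditions <- function(frame_rate = 90) {
  data.frame(
    intensity = c("baseline", "vt30", "vt60", "vt90", "recovery"),
    hr_median = c(60, 79, 90, 97, 78),
    hr_iqr = c(8, 15, 16, 25, 25),
    noise_level = c(0.10, 0.15, 0.25, 0.45, 0.25),
    dropout_fraction = c(0.000, 0.003, 0.006, 0.015, 0.008),
    frame_rate = frame_rate,
    stringsAsFactors = FALSE)
}

# relative exercise load per measurement point (0 at rest)
exercise_weight <- function(intensity) {
  c(baseline = 0, vt30 = 0.6, vt60 = 1.0, vt90 = 1.3,
    recovery = 0.5)[intensity]
}

#' Simulate a two-visit exercise-echocardiography cohort
#'
#' Every subject is assigned a base strain pattern (LBBB-type with rebound
#' stretch, or non-LBBB with monotone shortening) and visits the lab twice.
#' Each visit's pattern parameters are the subject's base parameters plus
#' independent zero-mean Gaussian noise with SD `visit_noise_sd`
#' (physiological day-to-day variation), so paired visit differences have
#' SD `sqrt(2) * visit_noise_sd`. Observer measurements are the analytic
#' indices plus independent zero-mean noise with SD `observer_noise_sd` per
#' observer. A manifest records every generated loop with its condition,
#' seed and truth indices.
#'
#' Exercise modulates discoordination heterogeneously: each subject draws
#' an exercise-response factor (log scale, SD `exercise_response_sd`) that
#' scales the rebound-stretch target with intensity, so septal coordination
#' consistently improves in some subjects and worsens in others, with
#' reciprocal responses at the margin; systolic shortening is mildly
#' depressed with intensity (higher afterload). The response is a subject
#' property, shared by both visits: with `visit_noise_sd = 0` the two
#' visits remain identical.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Data.frame as returned by [default_conditions()] (any
#'   subset of rows).
#' @param visit_noise_sd SD (percent strain) of the per-visit perturbation
#'   of the pattern's SS and SRS targets.
#' @param observer_noise_sd SD (percent strain) of per-observer measurement
#'   noise added to SS and SRS.
#' @param seed Integer master seed; all randomness derives from it.
#' @param lbbb_fraction Probability that a subject has the LBBB-type
#'   pattern.
#' @param exercise_response_sd SD of the per-subject exercise-response
#'   factor on the log-SDI scale (0 disables exercise dependence).
#' @param generate_images If TRUE, a speckle cine-loop is synthesised for
#'   every loop (memory-heavy; keep n_subjects small). If FALSE only
#'   ground-truth cycles and analytic indices are produced.
#' @param geometry Band geometry used when generating images.
#' @param image_size Image size `c(width, height)` when generating images.
#'
#' @return An object of class `cohort`: `manifest` data.frame (one row per
#'   subject x visit x condition) and `loops`, a list with the
#'   `ground_truth_cycle` (and `image_sequence` when requested) per
#'   manifest row.
#' @export
simulate_cohort <- function(n_subjects, conditions = default_conditions(),
                            visit_noise_sd = 0, observer_noise_sd = 0,
                            seed = 1, lbbb_fraction = 0.44,
                            exercise_response_sd = 0.5,
                            generate_images = FALSE,
                            geometry = septal_band_geometry(),
                            image_size = c(800, 600)) {
  stopifnot(n_subjects >= 2, visit_noise_sd >= 0, observer_noise_sd >= 0,
            nrow(conditions) >= 1)
  model <- fit_phase_duration_splines(phase_duration_reference())
  rows <- list(); loops <- list()
  idx <- 0
  with_seed(seed, {
    for (s in seq_len(n_subjects)) {
      lbbb <- stats::runif(1) < lbbb_fraction
      base_ss <- stats::runif(1, 10, 18)
      base_srs <- if (lbbb) stats::runif(1, 2, 6) else 0
      hr_jit <- stats::rnorm(2 * nrow(conditions), 0, 1)
      # subject-level exercise response, shared by both visits; the small
      # negative centre makes improvement of coordination the majority
      # response under submaximal exercise
      resp <- stats::rnorm(1, -0.1, exercise_response_sd)
      cond_jit <- stats::rnorm(nrow(conditions), 0, 0.15)
      exw <- exercise_weight(conditions$intensity)
      for (v in 1:2) {
        ss_v <- max(1, base_ss + stats::rnorm(1, 0, visit_noise_sd))
        srs_v <- if (lbbb) {
          max(0, base_srs + stats::rnorm(1, 0, visit_noise_sd))
        } else 0
        for (ci in seq_len(nrow(conditions))) {
          idx <- idx + 1
          cond_row <- conditions[ci, ]
          hr <- clamp(cond_row$hr_median +
                        hr_jit[(v - 1) * nrow(conditions) + ci] *
                        cond_row$hr_iqr / 1.35, 48, 135)
          loop_seed <- derive_seed(seed, idx)
          # acoustic window varies between loops: lognormal jitter around
          # the condition's median noise level
          noise_lv <- cond_row$noise_level *
            stats::rlnorm(1, 0, if (cond_row$noise_level > 0) 0.35 else 0)
          cond <- acquisition_condition(
            intensity = cond_row$intensity, heart_rate = hr,
            frame_rate = cond_row$frame_rate,
            noise_level = noise_lv,
            dropout_fraction = cond_row$dropout_fraction)
          sys_t <- phase_durations(model, hr)[["systolic_s"]]
          timing <- cardiac_timing(heart_rate = hr, mvc_time = 0,
                                   avc_time = sys_t, source = "scaled")
          w <- exw[ci]
          ss_c <- ss_v * exp(-0.06 * w)
          srs_c <- if (lbbb) {
            min(srs_v * exp((resp + cond_jit[ci]) * w), 0.8 * ss_c)
          } else 0
          pattern <- strain_pattern(
            family = if (lbbb) "lbbb_type" else "non_lbbb_type",
            target_ss = ss_c, target_srs = srs_c)
          curve <- generate_strain_curve(pattern, timing,
                                         frame_rate = cond_row$frame_rate,
                                         seed = loop_seed)
          truth <- ground_truth_cycle(curve, geometry)
          ai <- truth$analytic_indices
          # three readings: observer 1 twice (intra) and observer 2 once
          obs <- lapply(1:3, function(o) {
            srs_o <- max(0, ai$srs_sept +
                           stats::rnorm(1, 0, observer_noise_sd))
            ss_o <- max(0.5, ai$ss + stats::rnorm(1, 0, observer_noise_sd))
            c(srs = srs_o, ss = ss_o, sdi = srs_o / ss_o)
          })
          loop <- list(truth = truth)
          if (generate_images) {
            loop$sequence <- synthesize_cine_loop(
              truth, cond, image_size = image_size, seed = loop_seed)
          }
          loops[[idx]] <- loop
          rows[[idx]] <- data.frame(
            loop_id = idx, subject = s, visit = v,
            condition = cond_row$intensity, heart_rate = hr,
            frame_rate = cond_row$frame_rate,
            noise_level = noise_lv,
            dropout_fraction = cond_row$dropout_fraction,
            seed = loop_seed, family = pattern$family,
            target_ss = ss_c, target_srs = srs_c,
            srs_true = ai$srs_sept, ss_true = ai$ss, sdi_true = ai$sdi,
            srs_obs1 = obs[[1]][["srs"]], ss_obs1 = obs[[1]][["ss"]],
            sdi_obs1 = obs[[1]][["sdi"]],
            srs_obs1b = obs[[2]][["srs"]], ss_obs1b = obs[[2]][["ss"]],
            sdi_obs1b = obs[[2]][["sdi"]],
            srs_obs2 = obs[[3]][["srs"]], ss_obs2 = obs[[3]][["ss"]],
            sdi_obs2 = obs[[3]][["sdi"]],
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  structure(list(manifest = do.call(rbind, rows), loops = loops,
                 n_subjects = n_subjects, seed = seed,
                 visit_noise_sd = visit_noise_sd,
                 observer_noise_sd = observer_noise_sd,
                 generate_images = generate_images),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects x 2 visits x %d conditions = %d loops (%s)\n",
    x$n_subjects, nrow(x$manifest) / (2 * x$n_subjects), nrow(x$manifest),
    if (x$generate_images) "with images" else "analytic only"))
  invisible(x)
}
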