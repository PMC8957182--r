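#' Septal strain pattern specification
#'
#' Describes the morphology of a septal longitudinal strain curve by its
#' decomposition targets. The LBBB-type family shows early shortening
#' interrupted by systolic rebound stretch; the non-LBBB family shortens
#' monotonically through systole (zero rebound stretch).
#'
#' @param family `"lbbb_type"`, `"non_lbbb_type"` or `"custom"`.
#' @param target_ss Target systolic shortening, percent strain (> 0).
#' @param target_srs Target systolic rebound stretch, percent strain (>= 0).
#'   Must be 0 for the non-LBBB family.
#' @param pre_stretch Stretch before the first shortening onset, percent
#'   (>= 0); excluded from rebound stretch by definition.
#' @param peak_systolic_strain Optional most-negative strain value, percent.
#'   If omitted it is the end-systolic value `pre_stretch + target_srs -
#'   target_ss`. A supplied value must be reachable (no more negative than
#'   shortening allows, and at least as negative as end-systole).
#' @param post_systolic_behavior Diastolic behaviour: `"recoil_to_zero"`
#'   (strain returns to baseline by end of cycle) or `"plateau"` (strain is
#'   held before a late partial return).
#'
#' @return An object of class `strain_pattern`.
#' @export
strain_pattern <- function(family = c("lbbb_type", "non_lbbb_type", "custom"),
                           target_ss, target_srs = 0, pre_stretch = 0,
                           peak_systolic_strain = NULL,
                           post_systolic_behavior = c("recoil_to_zero",
                                                      "plateau")) {
  family <- match.arg(family)
  post_systolic_behavior <- match.arg(post_systolic_behavior)
  stopifnot(is.numeric(target_ss), target_ss > 0,
            is.numeric(target_srs), target_srs >= 0,
            is.numeric(pre_stretch), pre_stretch >= 0)
  if (family == "non_lbbb_type" && target_srs > 0) {
    stop("invalid pattern: non-LBBB family requires target_srs = 0",
         call. = FALSE)
  }
  end_sys <- pre_stretch + target_srs - target_ss
  if (end_sys >= 0) {
    stop("infeasible pattern: systole must end below baseline ",
         "(target_ss must exceed pre_stretch + target_srs)", call. = FALSE)
  }
  if (!is.null(peak_systolic_strain)) {
    stopifnot(is.numeric(peak_systolic_strain))
    if (peak_systolic_strain > end_sys + 1e-9) {
      stop("infeasible pattern: peak_systolic_strain cannot be above the ",
           "end-systolic value", call. = FALSE)
    }
    if (pre_stretch - peak_systolic_strain > target_ss + 1e-9) {
      stop("infeasible pattern: peak_systolic_strain deeper than total ",
           "shortening allows", call. = FALSE)
    }
    if (family == "non_lbbb_type" &&
        abs(peak_systolic_strain - end_sys) > 1e-9) {
      stop("infeasible pattern: monotone shortening peaks at end-systole",
           call. = FALSE)
    }
  }
  structure(list(family = family, target_ss = target_ss,
                 target_srs = target_srs, pre_stretch = pre_stretch,
                 peak_systolic_strain = peak_systolic_strain,
                 post_systolic_behavior = post_systolic_behavior),
            class = "strain_pattern")
}

#' Generate a ground-truth septal strain curve
#'
#' Builds a piecewise-smooth strain curve over one cardiac cycle whose
#' decomposition into shortening and stretch segments reproduces the
#' pattern's SS and SRS targets. Knots are placed on the frame-sample grid
#' and joined with monotone cubic Hermite segments, so the sampled curve's
#' sign-run decomposition hits the targets exactly; the seed jitters knot
#' timing and the depth of the first shortening without disturbing the
#' targets.
#'
#' @param pattern A [strain_pattern()].
#' @param timing A [cardiac_timing()] with `mvc_time = 0` (curves are
#'   referenced to MVC).
#' @param frame_rate Frame rate in Hz, in \[50, 90\].
#' @param seed Integer seed controlling morphology jitter.
#'
#' @return A [strain_curve()] with `round(cycle_length * frame_rate)`
#'   samples starting at 0% strain at MVC.
#' @export
generate_strain_curve <- function(pattern, timing, frame_rate = 90,
                                  seed = 1) {
  stopifnot(inherits(pattern, "strain_pattern"),
            inherits(timing, "cardiac_timing"))
  if (frame_rate < 50 || frame_rate > 90) {
    stop("frame_rate must lie in [50, 90] Hz", call. = FALSE)
  }
  if (abs(timing$mvc_time) > 1e-9) {
    stop("generator requires timing referenced to MVC (mvc_time = 0)",
         call. = FALSE)
  }
  n <- round(timing$cycle_length * frame_rate)
  j_end <- floor(timing$avc_time * frame_rate + 1e-9)  # last systolic sample
  if (j_end < 8 || n - j_end < 4) {
    stop("cycle too short at this frame rate to place the pattern",
         call. = FALSE)
  }
  ss <- pattern$target_ss
  srs <- pattern$target_srs
  pre <- pattern$pre_stretch
  end_sys <- pre + srs - ss

  with_seed(seed, {
    ki <- 0; kv <- 0  # knot indices and values, starting at (0, 0)
    j_pre <- 0
    if (pre > 0) {
      j_pre <- max(1L, round(stats::runif(1, 0.08, 0.15) * j_end))
      ki <- c(ki, j_pre); kv <- c(kv, pre)
    }
    if (srs > 0) {
      # one rebound episode: shorten, stretch back up, shorten again
      if (is.null(pattern$peak_systolic_strain)) {
        d1 <- stats::runif(1, 0.35, 0.55) * (ss - srs)
      } else {
        d1 <- pre - pattern$peak_systolic_strain
      }
      j1 <- clamp(round(stats::runif(1, 0.35, 0.50) * j_end),
                  j_pre + 2, j_end - 4)
      j2 <- clamp(round(stats::runif(1, 0.60, 0.75) * j_end),
                  j1 + 2, j_end - 2)
      ki <- c(ki, j1, j2, j_end)
      kv <- c(kv, pre - d1, pre - d1 + srs, end_sys)
    } else {
      jm <- clamp(round(0.5 * j_end), j_pre + 2, j_end - 2)
      frac <- stats::runif(1, 0.55, 0.75)
      ki <- c(ki, jm, j_end)
      kv <- c(kv, pre - frac * ss, end_sys)
    }
    # diastole
    if (pattern$post_systolic_behavior == "recoil_to_zero") {
      jr <- round((j_end + n - 1) / 2)
      if (jr > j_end + 1 && jr < n - 2) {
        ki <- c(ki, jr); kv <- c(kv, 0.25 * end_sys)
      }
      ki <- c(ki, n - 1); kv <- c(kv, 0)
    } else {
      jh <- round(j_end + 0.6 * (n - 1 - j_end))
      if (jh > j_end + 1 && jh < n - 2) {
        ki <- c(ki, jh); kv <- c(kv, end_sys)
      }
      ki <- c(ki, n - 1); kv <- c(kv, 0.6 * end_sys)
    }
    strain <- mono_hermite(ki, kv, 0:(n - 1))
    strain_curve(time = (0:(n - 1)) / frame_rate, strain = strain,
                 timing = timing, frame_rate = frame_rate)
  })
}
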