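#' Cardiac timing annotation
#'
#' Bundles the valve events that bound systole for one cardiac cycle: mitral
#' valve closure (MVC, the strain reference frame) and aortic valve closure
#' (AVC, end of ejection), together with heart rate and cycle length.
#'
#' @param heart_rate Heart rate in beats per minute.
#' @param mvc_time Time of mitral valve closure in seconds (usually 0: strain
#'   curves are referenced to MVC).
#' @param avc_time Time of aortic valve closure in seconds.
#' @param cycle_length Cycle length in seconds; defaults to `60 / heart_rate`.
#' @param source How the timing was obtained: `"doppler"` or `"visual"` for
#'   resting measurements, `"scaled"` for timings derived by
#'   [scale_timing()].
#'
#' @return An object of class `cardiac_timing`.
#' @export
cardiac_timing <- function(heart_rate, mvc_time, avc_time,
                           cycle_length = 60 / heart_rate,
                           source = c("doppler", "visual", "scaled")) {
  source <- match.arg(source)
  stopifnot(is.numeric(heart_rate), heart_rate > 0,
            is.numeric(mvc_time), is.numeric(avc_time),
            is.numeric(cycle_length), cycle_length > 0)
  if (!(mvc_time >= 0 && mvc_time < avc_time && avc_time < cycle_length)) {
    stop("invalid timing: need 0 <= mvc_time < avc_time < cycle_length",
         call. = FALSE)
  }
  if (abs(cycle_length - 60 / heart_rate) > 0.02 * (60 / heart_rate)) {
    stop("cycle_length inconsistent with heart_rate (beyond 2%)",
         call. = FALSE)
  }
  structure(list(heart_rate = heart_rate, cycle_length = cycle_length,
                 mvc_time = mvc_time, avc_time = avc_time, source = source),
            class = "cardiac_timing")
}

#' @export
print.cardiac_timing <- function(x, ...) {
  cat(sprintf(
    "<cardiac_timing> HR %.1f bpm, cycle %.3f s, MVC %.3f s, AVC %.3f s (%s)\n",
    x$heart_rate, x$cycle_length, x$mvc_time, x$avc_time, x$source))
  invisible(x)
}

#' Default systolic/diastolic phase-duration reference table
#'
#' Builds a reference table of systolic and diastolic durations versus heart
#' rate from the classic linear relation between total electromechanical
#' systole and heart rate (Weissler's regression, QS2 = 0.546 - 0.0021 HR
#' seconds in men); diastolic time is the remainder of the cycle. Any table
#' with the same columns can be supplied to [fit_phase_duration_splines()]
#' instead, e.g. stress-specific reference values.
#'
#' @param heart_rates Heart rates (bpm) at which to tabulate.
#' @param intercept,slope Coefficients of the linear systolic-time relation
#'   `systolic_s = intercept + slope * hr`.
#'
#' @return A data.frame with columns `hr_bpm`, `systolic_s`, `diastolic_s`.
#' @export
phase_duration_reference <- function(heart_rates = seq(40, 140, by = 5),
                                     intercept = 0.546, slope = -0.0021) {
  hr <- sort(unique(heart_rates))
  sys <- intercept + slope * hr
  dia <- 60 / hr - sys
  if (any(sys <= 0) || any(dia <= 0)) {
    stop("reference relation yields non-positive phase durations in range",
         call. = FALSE)
  }
  data.frame(hr_bpm = hr, systolic_s = sys, diastolic_s = dia)
}

#' Fit smoothing splines to a phase-duration reference table
#'
#' Systolic and diastolic times vary non-linearly with heart rate; resting
#' valve timings are carried to exercise heart rates by evaluating smoothing
#' splines fitted to a reference table of phase durations.
#'
#' @param reference_table Data.frame with columns `hr_bpm`, `systolic_s`,
#'   `diastolic_s`; at least 4 distinct heart rates, positive durations.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; the default `NULL` selects it by generalized
#'   cross-validation. `spar = 0` gives a near-interpolating fit.
#'
#' @return An object of class `phase_duration_model` with evaluable
#'   `systolic_time(hr)` and `diastolic_time(hr)` functions; evaluation
#'   outside the table's heart-rate range is clamped to the range endpoints
#'   with a warning.
#' @export
fit_phase_duration_splines <- function(reference_table, spar = NULL) {
  req <- c("hr_bpm", "systolic_s", "diastolic_s")
  if (!all(req %in% names(reference_table))) {
    stop("reference_table must have columns hr_bpm, systolic_s, diastolic_s",
         call. = FALSE)
  }
  tab <- reference_table[order(reference_table$hr_bpm), req]
  if (length(unique(tab$hr_bpm)) < 4) {
    stop("insufficient reference data: need >= 4 distinct heart rates",
         call. = FALSE)
  }
  if (any(tab$systolic_s <= 0) || any(tab$diastolic_s <= 0)) {
    stop("phase durations must be positive", call. = FALSE)
  }
  fit1 <- if (is.null(spar)) {
    stats::smooth.spline(tab$hr_bpm, tab$systolic_s)
  } else {
    stats::smooth.spline(tab$hr_bpm, tab$systolic_s, spar = spar)
  }
  fit2 <- if (is.null(spar)) {
    stats::smooth.spline(tab$hr_bpm, tab$diastolic_s)
  } else {
    stats::smooth.spline(tab$hr_bpm, tab$diastolic_s, spar = spar)
  }
  rng <- range(tab$hr_bpm)
  structure(list(reference_table = tab, systolic_fit = fit1,
                 diastolic_fit = fit2, hr_range = rng),
            class = "phase_duration_model")
}

clamp_hr <- function(model, hr) {
  if (hr < model$hr_range[1] || hr > model$hr_range[2]) {
    warning(sprintf(
      "heart rate %.1f bpm outside reference range [%.0f, %.0f]; clamped",
      hr, model$hr_range[1], model$hr_range[2]), call. = FALSE)
    hr <- min(max(hr, model$hr_range[1]), model$hr_range[2])
  }
  hr
}

#' Evaluate fitted phase durations at a heart rate
#'
#' @param model A `phase_duration_model` from [fit_phase_duration_splines()].
#' @param heart_rate Heart rate in bpm; clamped to the model range with a
#'   warning if outside.
#' @return Named numeric vector with `systolic_s` and `diastolic_s`.
#' @export
phase_durations <- function(model, heart_rate) {
  stopifnot(inherits(model, "phase_duration_model"))
  hr <- clamp_hr(model, heart_rate)
  c(systolic_s = stats::predict(model$systolic_fit, hr)$y,
    diastolic_s = stats::predict(model$diastolic_fit, hr)$y)
}

#' Scale resting valve timing to an exercise heart rate
#'
#' Exercise Doppler is rarely available, so the resting systolic duration is
#' scaled by the ratio of the reference systolic time at the exercise heart
#' rate to that at rest, and the cycle length is set by the exercise heart
#' rate; AVC follows MVC by the scaled systolic duration.
#'
#' @param rest A `cardiac_timing` measured at rest (source `"doppler"` or
#'   `"visual"`).
#' @param exercise_hr Exercise (or recovery) heart rate in bpm.
#' @param model A `phase_duration_model`.
#'
#' @return A `cardiac_timing` with `source = "scaled"`.
#' @export
scale_timing <- function(rest, exercise_hr, model) {
  stopifnot(inherits(rest, "cardiac_timing"),
            inherits(model, "phase_duration_model"))
  if (!rest$source %in% c("doppler", "visual")) {
    stop("rest timing must come from doppler or visual measurement",
         call. = FALSE)
  }
  hr_ex <- clamp_hr(model, exercise_hr)
  hr_rest <- clamp_hr(model, rest$heart_rate)
  sys_rest <- rest$avc_time - rest$mvc_time
  ratio <- stats::predict(model$systolic_fit, hr_ex)$y /
    stats::predict(model$systolic_fit, hr_rest)$y
  cycle <- 60 / exercise_hr
  sys_new <- sys_rest * ratio
  avc <- rest$mvc_time + sys_new
  if (avc >= cycle) {
    stop("timing infeasible: scaled AVC reaches or exceeds cycle length",
         call. = FALSE)
  }
  cardiac_timing(heart_rate = exercise_hr, mvc_time = rest$mvc_time,
                 avc_time = avc, cycle_length = cycle, source = "scaled")
}

#' Number of frames falling inside the ejection window
#'
#' Counts frame samples (at times `k / frame_rate`, k = 0, 1, ...) whose
#' timestamps lie in the half-open window `[mvc_time, avc_time)`: the MVC
#' sample is included and the AVC endpoint is exclusive, so a window of
#' exactly n frame intervals counts n frames. A zero-length window therefore
#' counts 0 frames. (Strain segmentation, by contrast, includes the AVC
#' sample in systole; see [segment_systole()].)
#'
#' @param timing A `cardiac_timing`.
#' @param frame_rate Acquisition frame rate in Hz.
#' @return Integer frame count.
#' @export
ejection_frame_count <- function(timing, frame_rate) {
  stopifnot(inherits(timing, "cardiac_timing"), frame_rate > 0)
  k <- seq(0, floor(timing$cycle_length * frame_rate))
  t <- k / frame_rate
  sum(t >= timing$mvc_time & t < timing$avc_time)
}
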