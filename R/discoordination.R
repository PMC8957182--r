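#' Septal strain curve
#'
#' A uniformly sampled curve of septal longitudinal strain over one cardiac
#' cycle, referenced to mitral valve closure (strain = 0 at MVC; negative
#' values are shortening), with the valve timing needed to delimit systole.
#'
#' @param time Sample times in seconds, uniformly spaced at the frame rate.
#' @param strain Strain in percent at each sample (negative = shortening).
#' @param timing A [cardiac_timing()] for the cycle.
#' @param frame_rate Frame rate in Hz; defaults to the reciprocal of the
#'   sampling interval.
#'
#' @return An object of class `strain_curve`.
#' @export
strain_curve <- function(time, strain, timing,
                         frame_rate = 1 / stats::median(diff(time))) {
  stopifnot(is.numeric(time), is.numeric(strain),
            length(time) == length(strain), length(time) >= 3,
            inherits(timing, "cardiac_timing"))
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6)) {
    stop("strain curve must be uniformly sampled", call. = FALSE)
  }
  mvc_idx <- which.min(abs(time - timing$mvc_time))
  if (abs(strain[mvc_idx]) > 1e-6) {
    stop("strain must be 0 at the MVC reference sample", call. = FALSE)
  }
  structure(list(time = as.numeric(time), strain = as.numeric(strain),
                 timing = timing, heart_rate = timing$heart_rate,
                 frame_rate = frame_rate),
            class = "strain_curve")
}

#' @export
print.strain_curve <- function(x, ...) {
  cat(sprintf(
    "<strain_curve> %d samples @ %.1f Hz, HR %.1f bpm, peak %.2f%%\n",
    length(x$time), x$frame_rate, x$heart_rate, min(x$strain)))
  invisible(x)
}

systolic_indices <- function(curve) {
  which(curve$time >= curve$timing$mvc_time - 1e-9 &
          curve$time <= curve$timing$avc_time + 1e-9)
}

#' Decompose systolic strain into shortening and stretch segments
#'
#' Groups the systolic portion of a strain curve (closed window from MVC to
#' AVC) into alternating runs of shortening (negative strain increments) and
#' stretch (positive increments). Zero increments are merged into the
#' preceding segment. Stretch occurring before any shortening has begun is
#' flagged `pre_shortening_stretch`: it does not count towards systolic
#' rebound stretch, which by definition follows premature termination of
#' shortening.
#'
#' @param curve A [strain_curve()].
#' @param noise_floor Increments with absolute value at or below this
#'   threshold (percent strain) are treated as zero. The default 0 applies
#'   the literal segment definition; raise it for sensitivity analyses.
#'
#' @return An object of class `systolic_segments`: a data.frame with columns
#'   `type` ("shortening"/"stretch"), `start`, `end` (sample indices into the
#'   curve), `change` (signed strain change, percent) and
#'   `pre_shortening_stretch`.
#' @export
segment_systole <- function(curve, noise_floor = 0) {
  stopifnot(inherits(curve, "strain_curve"), noise_floor >= 0)
  idx <- systolic_indices(curve)
  if (length(idx) < 3) {
    stop("systolic window too short: fewer than 3 samples", call. = FALSE)
  }
  s <- curve$strain[idx]
  d <- diff(s)
  d[abs(d) <= noise_floor] <- 0
  sgn <- sign(d)
  # propagate: zero increments join the preceding segment
  for (i in seq_along(sgn)) {
    if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  }
  keep <- sgn != 0
  segs <- data.frame(type = character(0), start = integer(0),
                     end = integer(0), change = numeric(0),
                     pre_shortening_stretch = logical(0),
                     stringsAsFactors = FALSE)
  if (any(keep)) {
    r <- rle(sgn[keep])
    pos <- which(keep)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    seen_shortening <- FALSE
    for (j in seq_along(r$values)) {
      ii <- pos[starts[j]:ends[j]]
      change <- sum(d[ii])
      type <- if (r$values[j] < 0) "shortening" else "stretch"
      pre <- type == "stretch" && !seen_shortening
      if (type == "shortening") seen_shortening <- TRUE
      segs <- rbind(segs, data.frame(
        type = type, start = idx[min(ii)], end = idx[max(ii) + 1L],
        change = change, pre_shortening_stretch = pre,
        stringsAsFactors = FALSE))
    }
  }
  structure(segs, class = c("systolic_segments", "data.frame"),
            window = range(idx), delta = sum(d))
}

#' Systolic rebound stretch
#'
#' Sum of positive systolic strain changes over stretch segments that occur
#' after shortening has begun (pre-shortening stretch is excluded). This is
#' the wasted-work component of systolic septal deformation.
#'
#' @param segments A `systolic_segments` object from [segment_systole()].
#' @return Rebound stretch in percent strain (>= 0).
#' @export
compute_srs <- function(segments) {
  stopifnot(inherits(segments, "systolic_segments"))
  sel <- segments$type == "stretch" & !segments$pre_shortening_stretch
  sum(segments$change[sel])
}

#' Systolic shortening
#'
#' Absolute sum of negative systolic strain changes over shortening
#' segments: the effective-work component of septal deformation.
#'
#' @param segments A `systolic_segments` object from [segment_systole()].
#' @return Systolic shortening in percent strain (>= 0).
#' @export
compute_ss <- function(segments) {
  stopifnot(inherits(segments, "systolic_segments"))
  sel <- segments$type == "shortening"
  sum(abs(segments$change[sel]))
}

#' Septal discoordination index
#'
#' Ratio of systolic rebound stretch to systolic shortening. Unlike the raw
#' stretch magnitude, the ratio is invariant to the overall strain amplitude
#' and therefore comparable across loading conditions (exercise raises blood
#' pressure and depresses strain magnitudes globally).
#'
#' @param srs Systolic rebound stretch in percent (>= 0).
#' @param ss Systolic shortening in percent (> 0).
#' @return Dimensionless ratio `srs / ss`.
#' @export
compute_sdi <- function(srs, ss) {
  stopifnot(is.numeric(srs), is.numeric(ss), srs >= 0, ss >= 0)
  if (ss == 0) {
    stop("SDI undefined: systolic shortening is zero", call. = FALSE)
  }
  srs / ss
}

#' All discoordination indices for one strain curve
#'
#' Convenience wrapper running [segment_systole()], [compute_srs()],
#' [compute_ss()] and [compute_sdi()].
#'
#' @inheritParams segment_systole
#' @return An object of class `discoordination_result`: list with `srs_sept`,
#'   `ss`, `sdi`, `n_rebound_segments` and the `segments` table.
#' @export
discoordination_indices <- function(curve, noise_floor = 0) {
  segs <- segment_systole(curve, noise_floor = noise_floor)
  srs <- compute_srs(segs)
  ss <- compute_ss(segs)
  sdi <- if (ss > 0) srs / ss else NA_real_
  structure(list(
    srs_sept = srs, ss = ss, sdi = sdi,
    n_rebound_segments = sum(segs$type == "stretch" &
                               !segs$pre_shortening_stretch),
    segments = segs), class = "discoordination_result")
}

#' @export
print.discoordination_result <- function(x, ...) {
  cat(sprintf(
    "<discoordination> SRSsept %.2f%%, SS %.2f%%, SDI %s (%d rebound segment%s)\n",
    x$srs_sept, x$ss,
    if (is.na(x$sdi)) "undefined" else sprintf("%.3f", x$sdi),
    x$n_rebound_segments, if (x$n_rebound_segments == 1) "" else "s"))
  invisible(x)
}

#' Classify the exercise-induced SDI response
#'
#' Compares SDI at two submaximal exercise intensities against the resting
#' value. Improvement at an intensity means a lower SDI than at rest.
#'
#' @param rest_sdi,sdi_30,sdi_60 SDI at rest and at the two exercise
#'   intensities (30% and 60% of the ventilatory threshold).
#' @return One of `"consistent_improvement"`, `"consistent_worsening"`,
#'   `"reciprocal"`.
#' @export
classify_sdi_response <- function(rest_sdi, sdi_30, sdi_60) {
  vals <- c(rest_sdi, sdi_30, sdi_60)
  if (any(!is.finite(vals))) {
    stop("undefined SDI value: cannot classify response", call. = FALSE)
  }
  imp30 <- sdi_30 < rest_sdi
  imp60 <- sdi_60 < rest_sdi
  if (imp30 && imp60) "consistent_improvement"
  else if (!imp30 && !imp60) "consistent_worsening"
  else "reciprocal"
}
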