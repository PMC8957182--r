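#' Pipeline configuration
#'
#' Collects every knob of an end-to-end simulation run; together with its
#' seed it fully determines all outputs.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size.
#' @param conditions Condition table ([default_conditions()] rows).
#' @param visit_noise_sd,observer_noise_sd Cohort noise SDs, percent strain.
#' @param lbbb_fraction Probability of the LBBB-type pattern per subject.
#' @param use_images If TRUE, loops are synthesised and tracked (slow,
#'   memory-heavy: keep the cohort small); if FALSE the analytic indices
#'   are analysed directly (tracking-free).
#' @param image_size,geometry Imaging geometry for synthesised loops.
#' @param block_size,search_radius,min_correlation Tracking parameters.
#' @param output_dir Optional directory for the report and tables.
#' @param verbose Print per-loop progress.
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 6,
                            conditions = default_conditions(),
                            visit_noise_sd = 0, observer_noise_sd = 0,
                            lbbb_fraction = 0.44, use_images = FALSE,
                            image_size = c(800, 600),
                            geometry = septal_band_geometry(),
                            block_size = 21, search_radius = 6,
                            min_correlation = 0.4,
                            output_dir = NULL, verbose = FALSE) {
  structure(list(seed = seed, n_subjects = n_subjects,
                 conditions = conditions, visit_noise_sd = visit_noise_sd,
                 observer_noise_sd = observer_noise_sd,
                 lbbb_fraction = lbbb_fraction, use_images = use_images,
                 image_size = image_size, geometry = geometry,
                 block_size = block_size, search_radius = search_radius,
                 min_correlation = min_correlation,
                 output_dir = output_dir, verbose = verbose),
            class = "run_config")
}

agreement_block <- function(a, b) {
  ba <- bland_altman(a, b)
  icc <- tryCatch(icc_absolute_single(cbind(a, b)),
                  error = function(e) list(icc = NA_real_,
                                           ci = c(NA_real_, NA_real_)))
  tt <- tryCatch(paired_ttest(a, b),
                 error = function(e) list(t = NA_real_, p_value = NA_real_))
  r <- tryCatch(stats::cor(a, b), error = function(e) NA_real_)
  list(bias = ba$bias, sd_of_differences = ba$sd,
       loa_low = ba$loa_low, loa_high = ba$loa_high,
       icc = icc$icc, icc_ci = icc$ci, pearson_r = r,
       t_stat = tt$t, p_value = tt$p_value, n_pairs = ba$n_pairs)
}

#' Run the full simulation pipeline
#'
#' Simulates a two-visit cohort, optionally synthesises and tracks speckle
#' loops (quality grading and exclusion included), computes
#' discoordination indices per loop, and assembles the study report:
#' feasibility accounting, per-condition test-retest / intra- / inter-
#' observer agreement for SRSsept and SDI, and the classification of
#' exercise-induced SDI responses.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `study_report` (a nested list; written as
#'   JSON when `config$output_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(
    n_subjects = config$n_subjects, conditions = config$conditions,
    visit_noise_sd = config$visit_noise_sd,
    observer_noise_sd = config$observer_noise_sd, seed = config$seed,
    lbbb_fraction = config$lbbb_fraction,
    generate_images = config$use_images, geometry = config$geometry,
    image_size = config$image_size)
  man <- cohort$manifest
  man$acquired <- TRUE
  man$attended_both_visits <- TRUE
  man$excluded <- FALSE
  man$exclusion_reason <- NA_character_
  man$grade <- NA_character_
  man$srs_meas <- man$srs_true
  man$ss_meas <- man$ss_true
  man$sdi_meas <- man$sdi_true

  if (config$use_images) {
    for (i in seq_len(nrow(man))) {
      if (config$verbose) {
        message(sprintf("tracking loop %d/%d", i, nrow(man)))
      }
      loop <- cohort$loops[[i]]
      res <- tryCatch(
        track_strain(loop$sequence, loop$truth$mesh,
                     loop$truth$timing,
                     block_size = config$block_size,
                     search_radius = config$search_radius,
                     min_correlation = config$min_correlation),
        error = function(e) e)
      if (inherits(res, "error")) {
        man$excluded[i] <- TRUE
        man$exclusion_reason[i] <- conditionMessage(res)
        next
      }
      man$grade[i] <- res$quality$grade
      if (res$quality$excluded || is.null(res$curve)) {
        man$excluded[i] <- TRUE
        man$exclusion_reason[i] <- if (res$quality$excluded) {
          "incomplete view of the septum (invalid-match rule)"
        } else "strain undefined"
        next
      }
      idx <- discoordination_indices(res$curve)
      man$srs_meas[i] <- idx$srs_sept
      man$ss_meas[i] <- idx$ss
      man$sdi_meas[i] <- idx$sdi
    }
  } else {
    man$grade <- "good"
  }

  man$sufficient_quality <- !man$excluded
  feas <- feasibility_tally(man)

  conds <- unique(man$condition)
  agreement <- list()
  for (cd in conds) {
    d <- man[man$condition == cd & !man$excluded, ]
    v1 <- d[d$visit == 1, ]; v2 <- d[d$visit == 2, ]
    common <- intersect(v1$subject, v2$subject)
    v1 <- v1[match(common, v1$subject), ]
    v2 <- v2[match(common, v2$subject), ]
    blk <- function(a, b) {
      if (length(a) >= 3) agreement_block(a, b) else NULL
    }
    agreement[[cd]] <- list(
      test_retest = list(srs = blk(v1$srs_meas, v2$srs_meas),
                         sdi = blk(v1$sdi_meas, v2$sdi_meas)),
      intra_observer = list(
        srs = blk(d$srs_obs1, d$srs_obs1b),
        sdi = blk(d$sdi_obs1, d$sdi_obs1b)),
      inter_observer = list(
        srs = blk(d$srs_obs1, d$srs_obs2),
        sdi = blk(d$sdi_obs1, d$sdi_obs2)))
  }

  # exercise-induced SDI response, visit 1, rest vs the two reproducible
  # submaximal intensities
  response <- NULL
  need <- c("baseline", "vt30", "vt60")
  if (all(need %in% conds)) {
    d <- man[man$visit == 1 & !man$excluded &
               man$condition %in% need, ]
    wide <- stats::reshape(
      d[, c("subject", "condition", "sdi_meas")],
      idvar = "subject", timevar = "condition", direction = "wide")
    wide <- wide[stats::complete.cases(wide), ]
    if (nrow(wide) > 0) {
      cls <- vapply(seq_len(nrow(wide)), function(i) {
        classify_sdi_response(wide$sdi_meas.baseline[i],
                              wide$sdi_meas.vt30[i],
                              wide$sdi_meas.vt60[i])
      }, character(1))
      d30 <- ifelse(wide$sdi_meas.vt30 < wide$sdi_meas.baseline,
                    "improvement", "worsening")
      d60 <- ifelse(wide$sdi_meas.vt60 < wide$sdi_meas.baseline,
                    "improvement", "worsening")
      kap <- tryCatch(cohen_kappa(d30, d60), error = function(e) NA_real_)
      response <- list(
        n = nrow(wide),
        consistent_improvement = sum(cls == "consistent_improvement"),
        consistent_worsening = sum(cls == "consistent_worsening"),
        reciprocal = sum(cls == "reciprocal"),
        kappa_vt30_vs_vt60 = kap)
    }
  }

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  report <- structure(list(
    provenance = list(config_hash = object_hash(cfg_for_hash),
                      seed = config$seed,
                      n_loops = nrow(man),
                      use_images = config$use_images),
    feasibility = feas,
    agreement = agreement,
    sdi_response = response,
    manifest = man), class = "study_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- report
    jsonlite::write_json(
      out[c("provenance", "feasibility", "agreement", "sdi_response")],
      file.path(config$output_dir, "study_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
    utils::write.csv(man, file.path(config$output_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d loops (%s), %d condition(s)\n",
              x$provenance$n_loops,
              if (x$provenance$use_images) "tracked" else "analytic",
              length(x$agreement)))
  if (!is.null(x$sdi_response)) {
    cat(sprintf(
      "  SDI response: %d improvement / %d worsening / %d reciprocal (kappa %.2f)\n",
      x$sdi_response$consistent_improvement,
      x$sdi_response$consistent_worsening, x$sdi_response$reciprocal,
      x$sdi_response$kappa_vt30_vs_vt60))
  }
  invisible(x)
}

#' Analyse existing cine-loops (no simulation)
#'
#' Runs the tracking half of the pipeline on user-supplied loops: each
#' entry needs an image sequence (object or path readable by
#' [read_image_sequence()]), a segmentation polygon (matrix or JSON path)
#' and a resting timing annotation ([cardiac_timing()] or JSON path).
#' Entries missing a segmentation or timing are skipped with a logged
#' reason. Ground-truth comparisons are (necessarily) omitted.
#'
#' @param loops List of lists with elements `sequence`, `segmentation`,
#'   `timing` and optionally `id`.
#' @param config A [pipeline_config()] (tracking parameters are used).
#' @return List with `results` (per-loop indices data.frame), `excluded`
#'   (id + reason) and `skipped` (id + reason).
#' @export
analyze_existing <- function(loops, config = pipeline_config()) {
  results <- list(); excluded <- list(); skipped <- list()
  for (i in seq_along(loops)) {
    entry <- loops[[i]]
    id <- if (!is.null(entry$id)) entry$id else sprintf("loop_%03d", i)
    if (is.null(entry$segmentation)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(id = id, reason = "missing segmentation")
      next
    }
    if (is.null(entry$timing)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(id = id, reason = "missing timing")
      next
    }
    seq <- if (inherits(entry$sequence, "image_sequence")) entry$sequence
    else read_image_sequence(entry$sequence)
    segm <- if (is.character(entry$segmentation)) {
      read_segmentation(entry$segmentation)
    } else entry$segmentation
    timing <- if (inherits(entry$timing, "cardiac_timing")) entry$timing
    else read_timing(entry$timing)
    res <- tryCatch(
      track_strain(seq, segm, timing, block_size = config$block_size,
                   search_radius = config$search_radius,
                   min_correlation = config$min_correlation),
      error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1]] <-
        data.frame(id = id, reason = conditionMessage(res))
      next
    }
    if (res$quality$excluded || is.null(res$indices)) {
      excluded[[length(excluded) + 1]] <- data.frame(
        id = id,
        reason = "incomplete view of the septum (invalid-match rule)")
      next
    }
    results[[length(results) + 1]] <- data.frame(
      id = id, grade = res$quality$grade,
      srs_sept = res$indices$srs_sept, ss = res$indices$ss,
      sdi = res$indices$sdi, stringsAsFactors = FALSE)
  }
  bindr <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(id = character(0), reason = character(0))
  out <- list(results = if (length(results)) do.call(rbind, results) else
                data.frame(),
              excluded = bindr(excluded), skipped = bindr(skipped))
  if (length(loops) == 0) {
    warning("empty loop list: nothing to analyse", call. = FALSE)
  }
  out
}
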