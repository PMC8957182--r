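# box-mean smoothing of a mesh-grid field; the window shrinks
# symmetrically at the grid edges so any locally linear field is preserved
# exactly (an asymmetric window would bias the field, and hence strain,
# toward interior values at the band ends)
smooth_grid <- function(m, hw) {
  nr <- nrow(m); nl <- ncol(m)
  out <- m
  for (r in seq_len(nr)) {
    hr_ <- min(hw, r - 1, nr - r)
    rs <- (r - hr_):(r + hr_)
    for (l in seq_len(nl)) {
      hl <- min(hw, l - 1, nl - l)
      out[r, l] <- mean(m[rs, (l - hl):(l + hl)])
    }
  }
  out
}

#' Estimate inter-frame mesh displacements by block matching
#'
#' Tracks every mesh point through the cine-loop: for each consecutive frame
#' pair, the displacement maximising normalised cross-correlation of a block
#' around the point's current position is found by exhaustive search and
#' refined to sub-pixel precision by a separable parabolic fit of the
#' correlation peak. Matches with a peak correlation below
#' `min_correlation`, or whose block leaves the image, are flagged invalid
#' and in-filled with the median displacement of their valid grid
#' neighbours (never silently zeroed).
#'
#' Two standard regularisations suppress tracking drift (each mesh point's
#' local speckle realisation induces a small persistent matching bias that
#' would otherwise accumulate over the cycle): forward-backward symmetric
#' matching (the backward estimate cancels the first-order bias) and box
#' smoothing of each frame pair's displacement field over the mesh grid
#' (the true inter-frame field is nearly affine, so smoothing removes
#' independent per-point bias without distorting it). Both can be disabled.
#'
#' @param seq An [image_sequence()].
#' @param mesh A [build_mesh()] result positioned on the first frame.
#' @param block_size Odd block edge length in pixels (default 21).
#' @param search_radius Search radius in pixels; must cover the expected
#'   per-frame motion (default 10).
#' @param min_correlation Validity threshold on the correlation peak.
#' @param symmetric Use forward-backward symmetric matching.
#' @param smooth_halfwidth Half-width (grid steps) of the box smoother
#'   applied to each frame pair's displacement field; 0 disables.
#'
#' @return An object of class `displacement_field`: arrays `dx`, `dy`,
#'   `correlation`, `valid` of dimension (n_pairs x n_radial x
#'   n_longitudinal), integer-peak arrays `ix`, `iy`, the per-frame tracked
#'   `positions` (n_frames x n_radial x n_longitudinal x 2), the mesh and
#'   the frame rate.
#' @export
estimate_displacements <- function(seq, mesh, block_size = 21,
                                   search_radius = 10,
                                   min_correlation = 0.4,
                                   symmetric = TRUE,
                                   smooth_halfwidth = 2) {
  stopifnot(inherits(seq, "image_sequence"), inherits(mesh, "septal_mesh"))
  if (block_size %% 2 != 1 || block_size < 3) {
    stop("block_size must be odd and >= 3", call. = FALSE)
  }
  bh <- (block_size - 1) %/% 2
  nr <- mesh$n_radial; nl <- mesh$n_longitudinal
  np <- nr * nl
  n_pairs <- length(seq$frames) - 1
  dx <- array(NA_real_, c(n_pairs, nr, nl))
  dy <- array(NA_real_, c(n_pairs, nr, nl))
  ix <- array(NA_real_, c(n_pairs, nr, nl))
  iy <- array(NA_real_, c(n_pairs, nr, nl))
  cor_arr <- array(NA_real_, c(n_pairs, nr, nl))
  valid <- array(FALSE, c(n_pairs, nr, nl))
  positions <- array(NA_real_, c(n_pairs + 1, nr, nl, 2))
  pos <- mesh_point_matrix(mesh)  # np x 2, (x, y)
  positions[1, , , 1] <- matrix(pos[, 1], nr, nl)
  positions[1, , , 2] <- matrix(pos[, 2], nr, nl)

  # grid neighbourhood (8-connected) for median in-fill
  ridx <- matrix(rep(seq_len(nr), nl), nr, nl)
  lidx <- matrix(rep(seq_len(nl), each = nr), nr, nl)

  for (k in seq_len(n_pairs)) {
    m <- cpp_block_match(seq$frames[[k]], seq$frames[[k + 1]],
                         pos[, 1], pos[, 2], bh, search_radius)
    ok <- m[, 4] == 1 & !is.na(m[, 3]) & m[, 3] >= min_correlation
    if (!any(ok)) {
      stop("tracking failure: no valid matches in a frame pair",
           call. = FALSE)
    }
    ddx <- m[, 1]; ddy <- m[, 2]
    if (symmetric && any(ok)) {
      p2 <- pos + cbind(ifelse(ok, ddx, 0), ifelse(ok, ddy, 0))
      mb <- cpp_block_match(seq$frames[[k + 1]], seq$frames[[k]],
                            p2[, 1], p2[, 2], bh, search_radius)
      okb <- ok & mb[, 4] == 1 & !is.na(mb[, 3]) &
        mb[, 3] >= min_correlation
      ddx[okb] <- (ddx[okb] - mb[okb, 1]) / 2
      ddy[okb] <- (ddy[okb] - mb[okb, 2]) / 2
    }
    if (any(!ok)) {
      okm <- matrix(ok, nr, nl)
      dxm <- matrix(ddx, nr, nl); dym <- matrix(ddy, nr, nl)
      for (p in which(!ok)) {
        r <- ridx[p]; l <- lidx[p]
        rs <- max(1, r - 1):min(nr, r + 1)
        ls <- max(1, l - 1):min(nl, l + 1)
        nb <- okm[rs, ls]
        if (any(nb)) {
          ddx[p] <- stats::median(dxm[rs, ls][nb])
          ddy[p] <- stats::median(dym[rs, ls][nb])
        } else {
          ddx[p] <- stats::median(dxm[okm])
          ddy[p] <- stats::median(dym[okm])
        }
      }
    }
    if (smooth_halfwidth > 0) {
      ddx <- as.vector(smooth_grid(matrix(ddx, nr, nl), smooth_halfwidth))
      ddy <- as.vector(smooth_grid(matrix(ddy, nr, nl), smooth_halfwidth))
    }
    dx[k, , ] <- matrix(ddx, nr, nl)
    dy[k, , ] <- matrix(ddy, nr, nl)
    ix[k, , ] <- matrix(m[, 5], nr, nl)
    iy[k, , ] <- matrix(m[, 6], nr, nl)
    cor_arr[k, , ] <- matrix(m[, 3], nr, nl)
    valid[k, , ] <- matrix(ok, nr, nl)
    pos <- pos + cbind(ddx, ddy)
    positions[k + 1, , , 1] <- matrix(pos[, 1], nr, nl)
    positions[k + 1, , , 2] <- matrix(pos[, 2], nr, nl)
  }
  structure(list(dx = dx, dy = dy, ix = ix, iy = iy,
                 correlation = cor_arr, valid = valid,
                 positions = positions, mesh = mesh,
                 frame_rate = seq$frame_rate,
                 block_size = block_size, search_radius = search_radius,
                 min_correlation = min_correlation,
                 symmetric = symmetric,
                 smooth_halfwidth = smooth_halfwidth),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d frame pairs, %d x %d points, %.1f%% valid\n",
    dim(x$dx)[1], dim(x$dx)[2], dim(x$dx)[3], 100 * mean(x$valid)))
  invisible(x)
}

#' Cumulative longitudinal strain from a displacement field
#'
#' Implements the least-squares strain estimator: per frame, mesh positions
#' are the initial mesh plus the accumulated displacements; at each mesh
#' point, longitudinal strain is the slope of a least-squares line relating
#' the cumulative longitudinal position change (displacement projected onto
#' the point's initial longitudinal direction) to the initial longitudinal
#' arc-length coordinate, over a sliding kernel of neighbouring stations
#' (shrunk at the band ends). The curve is the mean over all mesh points,
#' in percent, 0 at the reference (first) frame.
#'
#' @param field A [estimate_displacements()] result.
#' @param timing A [cardiac_timing()] for the cycle (needed to delimit
#'   systole downstream).
#' @param kernel Odd number of longitudinal stations in the regression
#'   kernel (default 7).
#' @param max_invalid_fraction If more than this fraction of matches is
#'   invalid in any frame pair, strain is declared undefined for the loop.
#'
#' @return A [strain_curve()].
#' @export
accumulate_strain <- function(field, timing, kernel = 7,
                              max_invalid_fraction = 0.5) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(timing, "cardiac_timing"),
            kernel %% 2 == 1, kernel >= 3)
  inv_frac <- apply(!field$valid, 1, mean)
  if (any(inv_frac > max_invalid_fraction)) {
    stop("strain undefined: more than half of the mesh lost in a frame pair",
         call. = FALSE)
  }
  nr <- field$mesh$n_radial; nl <- field$mesh$n_longitudinal
  n_frames <- dim(field$positions)[1]
  hw <- (kernel - 1) %/% 2
  s0 <- field$mesh$s0
  lvx <- field$mesh$long_vec[, , 1]
  lvy <- field$mesh$long_vec[, , 2]
  p0x <- field$mesh$points[, , 1]
  p0y <- field$mesh$points[, , 2]
  windows <- lapply(seq_len(nl), function(j) {
    max(1, j - hw):min(nl, j + hw)
  })
  strain <- numeric(n_frames)
  for (k in 2:n_frames) {
    ux <- field$positions[k, , , 1] - p0x
    uy <- field$positions[k, , , 2] - p0y
    ul <- ux * lvx + uy * lvy  # longitudinal component of displacement
    eps <- matrix(NA_real_, nr, nl)
    for (j in seq_len(nl)) {
      W <- windows[[j]]
      S <- s0[, W, drop = FALSE]
      U <- ul[, W, drop = FALSE]
      Sc <- S - rowMeans(S)
      Uc <- U - rowMeans(U)
      eps[, j] <- rowSums(Sc * Uc) / rowSums(Sc * Sc)
    }
    strain[k] <- mean(eps) * 100
  }
  n <- min(n_frames, floor(timing$cycle_length * field$frame_rate) + 1)
  strain_curve(time = (seq_len(n) - 1) / field$frame_rate,
               strain = strain[seq_len(n)], timing = timing,
               frame_rate = field$frame_rate)
}

#' Grade cine-loop image quality and apply the exclusion rule
#'
#' Scores four components on a 0-1 scale: image contrast between the septum
#' and background, definition of tissue structure (coherent gradient energy
#' inside the band relative to background gradient energy), image-plane
#' stability (magnitude of global frame-to-frame shifts) and artefact
#' burden (fraction of invalid matches). The grade thresholds the composite
#' (mean) score. A loop is excluded when any frame pair loses more than
#' `exclusion_invalid_fraction` of its mesh points, the operational proxy
#' for an incomplete view of the septum during the cycle.
#'
#' @param seq An [image_sequence()].
#' @param field The [estimate_displacements()] result for `seq`.
#' @param good_threshold,poor_threshold Composite-score thresholds: `good`
#'   at or above `good_threshold`, `poor` below `poor_threshold`.
#' @param exclusion_invalid_fraction Invalid-match fraction in any single
#'   frame pair that triggers exclusion (default 0.3).
#'
#' @return An object of class `quality_grade`: `grade` ("good", "moderate",
#'   "poor"), `excluded`, and the `component_scores`.
#' @export
grade_quality <- function(seq, field, good_threshold = 0.92,
                          poor_threshold = 0.84,
                          exclusion_invalid_fraction = 0.3) {
  stopifnot(inherits(seq, "image_sequence"),
            inherits(field, "displacement_field"))
  mesh <- field$mesh
  pts <- mesh_point_matrix(mesh)
  h <- nrow(seq$frames[[1]]); w <- ncol(seq$frames[[1]])
  rr <- clamp(round(pts[, 2]) + 1, 1, h)
  cc <- clamp(round(pts[, 1]) + 1, 1, w)
  lin <- (cc - 1) * h + rr
  # background probe: a coarse pixel lattice outside the segmentation
  gx <- round(seq(1, w, length.out = 40))
  gy <- round(seq(1, h, length.out = 30))
  grid <- expand.grid(col = gx, row = gy)
  out_mask <- !points_in_polygon(grid$col - 1, grid$row - 1,
                                 mesh$segmentation)
  lin_out <- (grid$col[out_mask] - 1) * h + grid$row[out_mask]
  probe <- round(seq(1, length(seq$frames),
                     length.out = min(5, length(seq$frames))))
  contrast <- struct_def <- numeric(length(probe))
  for (i in seq_along(probe)) {
    f <- seq$frames[[probe[i]]]
    mu_in <- mean(f[lin]); mu_out <- mean(f[lin_out])
    contrast[i] <- clamp((mu_in - mu_out) / (mu_in + mu_out + 1e-9), 0, 1)
    gin <- mean(abs(f[pmin(lin + 1, h * w)] - f[lin]))
    gout <- mean(abs(f[pmin(lin_out + 1, h * w)] - f[lin_out]))
    struct_def[i] <- clamp(gin / (gin + gout + 1e-9), 0, 1)
  }
  shift <- mean(sqrt(apply(field$dx, 1, stats::median)^2 +
                       apply(field$dy, 1, stats::median)^2))
  stability <- exp(-shift / 3)
  worst_invalid <- max(apply(!field$valid, 1, mean))
  artefact <- 1 - mean(!field$valid)
  scores <- c(contrast = mean(contrast),
              structure_definition = mean(struct_def),
              plane_stability = stability,
              artefact_burden = artefact)
  composite <- mean(scores)
  grade <- if (composite >= good_threshold) "good"
  else if (composite >= poor_threshold) "moderate"
  else "poor"
  structure(list(grade = grade,
                 excluded = worst_invalid > exclusion_invalid_fraction,
                 component_scores = scores, composite = composite,
                 worst_invalid_fraction = worst_invalid),
            class = "quality_grade")
}

#' @export
print.quality_grade <- function(x, ...) {
  cat(sprintf("<quality_grade> %s (composite %.2f)%s\n", x$grade,
              x$composite, if (x$excluded) ", EXCLUDED" else ""))
  invisible(x)
}

#' Track a loop end to end
#'
#' Convenience wrapper: build the mesh from a segmentation, estimate
#' displacements, grade quality and accumulate the strain curve.
#'
#' @param seq An [image_sequence()].
#' @param segmentation Polygon matrix, or a `septal_mesh`.
#' @param timing A [cardiac_timing()].
#' @param ... Passed to [estimate_displacements()].
#' @return List with `mesh`, `field`, `quality`, `curve` (NULL if strain
#'   was undefined), and `indices` (NULL when excluded or undefined).
#' @export
track_strain <- function(seq, segmentation, timing, ...) {
  mesh <- if (inherits(segmentation, "septal_mesh")) segmentation
  else build_mesh(segmentation)
  field <- estimate_displacements(seq, mesh, ...)
  quality <- grade_quality(seq, field)
  curve <- tryCatch(accumulate_strain(field, timing),
                    error = function(e) NULL)
  indices <- if (!is.null(curve) && !quality$excluded) {
    discoordination_indices(curve)
  } else NULL
  list(mesh = mesh, field = field, quality = quality, curve = curve,
       indices = indices)
}
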