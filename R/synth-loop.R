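#' Septal band geometry for the synthetic-image generator
#'
#' The simulated septum is a curved band: an annular segment around a circle
#' centre placed below the field of view. Material coordinates are the
#' angular position along the centerline and the radial offset from it.
#'
#' @param center Circle centre (x, y) in pixels (may lie outside the image).
#' @param radius Centerline radius in pixels.
#' @param theta_mid Direction (radians) from the centre to the band
#'   mid-point.
#' @param half_span Angular half-extent of the band (radians).
#' @param thickness Band thickness in pixels.
#'
#' @return An object of class `band_geometry`.
#' @export
septal_band_geometry <- function(center = c(400, 850), radius = 560,
                                 theta_mid = -pi / 2, half_span = 0.32,
                                 thickness = 56) {
  stopifnot(radius > 0, half_span > 0, thickness > 0,
            thickness < radius)
  structure(list(center = center, radius = radius, theta_mid = theta_mid,
                 half_span = half_span, thickness = thickness),
            class = "band_geometry")
}

#' Segmentation polygon outlining a band geometry
#'
#' @param geometry A [septal_band_geometry()].
#' @param n_arc Number of vertices along each arc edge.
#' @return An n x 2 matrix tracing the outer arc then the inner arc back.
#' @export
band_polygon <- function(geometry, n_arc = 24) {
  g <- geometry
  th <- g$theta_mid + seq(-g$half_span, g$half_span, length.out = n_arc)
  r_out <- g$radius + g$thickness / 2
  r_in <- g$radius - g$thickness / 2
  outer <- cbind(g$center[1] + r_out * cos(th), g$center[2] + r_out * sin(th))
  inner <- cbind(g$center[1] + r_in * cos(rev(th)),
                 g$center[2] + r_in * sin(rev(th)))
  rbind(outer, inner)
}

# Deform material coordinates (dth = angle from theta_mid, t = radial offset
# from the centerline) under longitudinal stretch ratio lambda about the
# band mid-point. Each radial layer stretches by exactly lambda along its own
# arc; thickness scales by 1/lambda (incompressibility).
band_deform <- function(geometry, dth, t, lambda) {
  g <- geometry
  t_new <- t / lambda
  dth_new <- lambda * (g$radius + t) / (g$radius + t_new) * dth
  r <- g$radius + t_new
  th <- g$theta_mid + dth_new
  cbind(g$center[1] + r * cos(th), g$center[2] + r * sin(th))
}

# The tracking mesh over a band geometry depends only on the geometry, so
# cohort simulation caches it (building it means polygon slicing at every
# station, which dominates the cost of analytic-only cohorts otherwise)
.band_mesh_cache <- new.env(parent = emptyenv())

band_mesh_cached <- function(geometry) {
  key <- paste(format(unlist(geometry[c("center", "radius", "theta_mid",
                                        "half_span", "thickness")]),
                      digits = 15), collapse = "|")
  hit <- .band_mesh_cache[[key]]
  if (!is.null(hit)) return(hit)
  mesh <- build_mesh(band_polygon(geometry))
  mat <- band_material_coords(geometry, mesh_point_matrix(mesh))
  out <- list(mesh = mesh, mat = mat)
  .band_mesh_cache[[key]] <- out
  out
}

# Material coordinates of world points relative to a band geometry
band_material_coords <- function(geometry, xy) {
  g <- geometry
  dx <- xy[, 1] - g$center[1]
  dy <- xy[, 2] - g$center[2]
  th <- atan2(dy, dx)
  dth <- (th - g$theta_mid + pi) %% (2 * pi) - pi
  t <- sqrt(dx^2 + dy^2) - g$radius
  cbind(dth = dth, t = t)
}

#' Ground-truth cardiac cycle for synthetic loops
#'
#' Couples a prescribed strain curve to the band deformation model: the
#' tracking mesh is built over the band's segmentation polygon and every
#' mesh point's position is computed analytically at every frame, so that
#' longitudinal strain of the deforming band equals the prescribed curve.
#' Analytic discoordination indices of the curve are stored alongside.
#'
#' @param curve A [strain_curve()] (percent strain per frame sample).
#' @param geometry A [septal_band_geometry()].
#'
#' @return An object of class `ground_truth_cycle` with the curve, the mesh,
#'   the per-frame `mesh_trajectory` (frames x radial x longitudinal x 2),
#'   the timing and `analytic_indices`.
#' @export
ground_truth_cycle <- function(curve, geometry = septal_band_geometry()) {
  stopifnot(inherits(curve, "strain_curve"),
            inherits(geometry, "band_geometry"))
  cached <- band_mesh_cached(geometry)
  mesh <- cached$mesh
  mat <- cached$mat
  n_frames <- length(curve$time)
  nr <- mesh$n_radial; nl <- mesh$n_longitudinal
  # all frames at once: points x frames matrices of deformed coordinates
  g <- geometry
  lam <- 1 + curve$strain / 100
  dth <- mat[, "dth"]; t <- mat[, "t"]
  t_new <- outer(t, 1 / lam)
  dth_new <- outer(dth * (g$radius + t), lam) / (g$radius + t_new)
  r <- g$radius + t_new
  th <- g$theta_mid + dth_new
  traj <- array(NA_real_, c(n_frames, nr, nl, 2))
  traj[, , , 1] <- aperm(array(g$center[1] + r * cos(th),
                               c(nr, nl, n_frames)), c(3, 1, 2))
  traj[, , , 2] <- aperm(array(g$center[2] + r * sin(th),
                               c(nr, nl, n_frames)), c(3, 1, 2))
  structure(list(strain_curve = curve, mesh = mesh, geometry = geometry,
                 mesh_trajectory = traj, timing = curve$timing,
                 analytic_indices = discoordination_indices(curve)),
            class = "ground_truth_cycle")
}

#' Acquisition condition for simulated loops
#'
#' Maps an exercise intensity level to acquisition parameters: heart rate,
#' frame rate, additive image noise and the per-frame probability of an
#' occlusion (shadowing / out-of-plane signal loss).
#'
#' @param intensity One of `"baseline"`, `"vt30"`, `"vt60"`, `"vt90"`,
#'   `"recovery"` (percent of the ventilatory threshold).
#' @param heart_rate Heart rate in bpm.
#' @param frame_rate Frame rate in Hz, in \[50, 90\].
#' @param noise_level Additive Gaussian image noise SD (image intensities
#'   are O(1)).
#' @param dropout_fraction Expected fraction of frames carrying an occlusion
#'   mask, in \[0, 1\].
#'
#' @return An object of class `acquisition_condition`.
#' @export
acquisition_condition <- function(intensity = c("baseline", "vt30", "vt60",
                                                "vt90", "recovery"),
                                  heart_rate = 60, frame_rate = 90,
                                  noise_level = 0, dropout_fraction = 0) {
  intensity <- match.arg(intensity)
  stopifnot(heart_rate > 0, frame_rate >= 50, frame_rate <= 90,
            noise_level >= 0,
            dropout_fraction >= 0, dropout_fraction <= 1)
  structure(list(intensity = intensity, heart_rate = heart_rate,
                 frame_rate = frame_rate, noise_level = noise_level,
                 dropout_fraction = dropout_fraction),
            class = "acquisition_condition")
}

#' Image sequence (cine-loop)
#'
#' @param frames List of intensity matrices (height x width), one per frame.
#' @param frame_rate Frame rate in Hz.
#' @param pixel_spacing Pixel size in mm (isotropic).
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, frame_rate, pixel_spacing = 0.3) {
  stopifnot(is.list(frames), length(frames) >= 2, frame_rate > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share dimensions", call. = FALSE)
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_spacing = pixel_spacing,
                 frame_times = (seq_along(frames) - 1) / frame_rate),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> %d frames of %d x %d px @ %.1f Hz\n",
              length(x$frames), d[1], d[2], x$frame_rate))
  invisible(x)
}

#' Synthesize a speckle cine-loop from a ground-truth cycle
#'
#' Scatters point reflectors uniformly over the septal band, convolves them
#' with a band-limited Gaussian point-spread function, and advects the
#' scatterer field frame by frame with the ground-truth deformation.
#' Acquisition degradation is additive Gaussian noise (scaled by the
#' condition's `noise_level`, images clipped at 0) and, for a
#' `dropout_fraction` of frames, a randomly placed occlusion disc zeroing
#' part of the septum.
#'
#' @param truth A [ground_truth_cycle()].
#' @param condition An [acquisition_condition()].
#' @param image_size `c(width, height)` in pixels (default 800 x 600).
#' @param seed Integer seed for scatterers, noise and dropout placement.
#' @param n_scatterers Number of point reflectors in the band.
#' @param psf_sigma Gaussian point-spread-function SD in pixels.
#'
#' @return An [image_sequence()] with attributes recording the condition and
#'   the indices of occluded frames.
#' @export
synthesize_cine_loop <- function(truth, condition = acquisition_condition(),
                                 image_size = c(800, 600), seed = 1,
                                 n_scatterers = 2000, psf_sigma = 2) {
  stopifnot(inherits(truth, "ground_truth_cycle"),
            inherits(condition, "acquisition_condition"))
  w <- image_size[1]; h <- image_size[2]
  traj <- truth$mesh_trajectory
  if (min(traj[, , , 1]) < 0 || max(traj[, , , 1]) > w - 1 ||
      min(traj[, , , 2]) < 0 || max(traj[, , , 2]) > h - 1) {
    stop("out of field: mesh trajectory leaves the image", call. = FALSE)
  }
  g <- truth$geometry
  curve <- truth$strain_curve
  n_frames <- length(curve$time)
  with_seed(seed, {
    dth <- stats::runif(n_scatterers, -g$half_span, g$half_span)
    t <- stats::runif(n_scatterers, -g$thickness / 2, g$thickness / 2)
    amp <- stats::runif(n_scatterers, 0.2, 1)
    occluded <- which(stats::runif(n_frames) < condition$dropout_fraction)
    ctr_line <- band_deform(g, stats::runif(length(occluded),
                                            -0.8 * g$half_span,
                                            0.8 * g$half_span),
                            rep(0, length(occluded)), 1)
    occ_radius <- stats::runif(length(occluded), 0.12, 0.30) *
      (2 * g$half_span * g$radius)
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      lambda <- 1 + curve$strain[k] / 100
      p <- band_deform(g, dth, t, lambda)
      img <- cpp_render_speckle(p[, 1], p[, 2], amp, h, w, psf_sigma)
      if (condition$noise_level > 0) {
        img <- img + matrix(stats::rnorm(h * w, sd = condition$noise_level),
                            h, w)
        img[img < 0] <- 0
      }
      oi <- match(k, occluded)
      if (!is.na(oi)) {
        cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
        rr <- matrix(0:(h - 1), h, w)
        msk <- (cc - ctr_line[oi, 1])^2 + (rr - ctr_line[oi, 2])^2 <=
          occ_radius[oi]^2
        img[msk] <- 0
      }
      frames[[k]] <- img
    }
    seq <- image_sequence(frames, curve$frame_rate)
    attr(seq, "condition") <- condition
    attr(seq, "occluded_frames") <- occluded
    seq
  })
}
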