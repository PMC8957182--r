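#' Build the septal tracking mesh from a segmentation polygon
#'
#' Lays an 11 (radial) by 31 (longitudinal) grid of tracking points over a
#' segmented septal band, with a local coordinate frame at every point:
#' the longitudinal unit vector follows the band's long axis (the medial
#' axis tangent) and the radial unit vector is perpendicular to it. The
#' segmentation may be a nearly straight band or a curved (C-shaped) annular
#' segment; curvature is detected by an algebraic circle fit to the polygon
#' vertices.
#'
#' @param segmentation Closed simple polygon as an n x 2 matrix of (x, y)
#'   image coordinates (0-based pixels), vertices in order.
#' @param n_radial,n_longitudinal Grid dimensions (defaults 11 x 31).
#' @param min_area Minimum polygon area in px^2 below which the segmentation
#'   is rejected as degenerate.
#'
#' @return An object of class `septal_mesh`: arrays `points` (n_radial x
#'   n_longitudinal x 2, image coordinates), `long_vec` and `rad_vec` (unit
#'   vectors, same layout), `s0` (initial longitudinal arc-length coordinate
#'   per point, px), plus the segmentation polygon and band shape metadata.
#' @export
build_mesh <- function(segmentation, n_radial = 11, n_longitudinal = 31,
                       min_area = 50) {
  poly <- as.matrix(segmentation)
  if (ncol(poly) != 2 || nrow(poly) < 3 || !is.numeric(poly)) {
    stop("segmentation must be an n x 2 numeric matrix of vertices",
         call. = FALSE)
  }
  if (polygon_self_intersects(poly)) {
    stop("segmentation error: polygon self-intersects", call. = FALSE)
  }
  if (polygon_area(poly) < min_area) {
    stop("segmentation error: polygon area is degenerate", call. = FALSE)
  }

  # approximate the medial axis by slicing along the principal axis, then
  # decide curved vs. straight from the centerline's deviation off the chord
  axis_mesh <- mesh_from_axis(poly, n_radial, n_longitudinal)
  mid <- axis_mesh$midline          # n_longitudinal x 2 centerline samples
  chord_dev <- midline_deviation(mid)
  mesh <- axis_mesh
  if (chord_dev > 0.02 * axis_mesh$length) {
    # curved band: fit a circle to the centerline and re-slice radially
    # around its centre. The axis-sliced midline is chord-biased near the
    # band ends, so the fit-and-slice step is iterated once on the radially
    # sliced midline, which is unbiased.
    for (pass in 1:2) {
      fit <- kasa_circle(mid)
      if (is.null(fit) || !is.finite(fit$R) ||
          fit$R >= 100 * axis_mesh$length) break
      mesh <- mesh_from_arc(poly, fit$cx, fit$cy, mid, n_radial,
                            n_longitudinal)
      mid <- mesh$midline
    }
  }

  # band must be elongated: centerline length vs. mean thickness
  if (mesh$length / max(mesh$thickness, 1e-9) < 1.5) {
    stop("segmentation error: band not elongated (aspect ratio <= 1.5)",
         call. = FALSE)
  }
  mesh$segmentation <- poly
  mesh$n_radial <- n_radial
  mesh$n_longitudinal <- n_longitudinal
  class(mesh) <- "septal_mesh"
  mesh
}

#' @export
print.septal_mesh <- function(x, ...) {
  cat(sprintf(
    "<septal_mesh> %d x %d points, %s band, centerline %.0f px, thickness %.0f px\n",
    x$n_radial, x$n_longitudinal, x$mode, x$length, x$thickness))
  invisible(x)
}

# algebraic (Kasa) circle fit through 2-D points
kasa_circle <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(cx = fit[1], cy = fit[2],
       R = sqrt(fit[3] + fit[1]^2 + fit[2]^2))
}

# maximum perpendicular distance of centerline samples from the straight
# line joining their endpoints
midline_deviation <- function(mid) {
  p0 <- mid[1, ]; p1 <- mid[nrow(mid), ]
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-9) return(0)
  nrm <- c(-d[2], d[1]) / len
  max(abs((mid[, 1] - p0[1]) * nrm[1] + (mid[, 2] - p0[2]) * nrm[2]))
}

# intersect a ray (origin o, unit direction d) with polygon edges; returns
# sorted positive ray parameters of all crossings
ray_polygon_crossings <- function(o, d, poly) {
  n <- nrow(poly)
  ts <- numeric(0)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
    e <- q - p
    denom <- d[1] * e[2] - d[2] * e[1]
    if (abs(denom) < 1e-12) next
    t <- ((p[1] - o[1]) * e[2] - (p[2] - o[2]) * e[1]) / denom
    u <- ((p[1] - o[1]) * d[2] - (p[2] - o[2]) * d[1]) / denom
    if (u >= -1e-9 && u <= 1 + 1e-9 && t > 0) ts <- c(ts, t)
  }
  sort(ts)
}

mesh_from_arc <- function(poly, cx, cy, mid, n_radial, n_longitudinal) {
  # station angles span the centerline's angular extent about the fitted
  # centre (endpoints of the axis-sliced midline are interior, so radial
  # rays there reliably cross both band boundaries)
  ang <- atan2(mid[, 2] - cy, mid[, 1] - cx)
  mu <- atan2(mean(sin(ang)), mean(cos(ang)))
  dev <- (ang - mu + pi) %% (2 * pi) - pi
  stations <- mu + seq(min(dev), max(dev), length.out = n_longitudinal)
  pts <- array(NA_real_, c(n_radial, n_longitudinal, 2))
  lv <- array(NA_real_, c(n_radial, n_longitudinal, 2))
  rv <- array(NA_real_, c(n_radial, n_longitudinal, 2))
  s0 <- matrix(NA_real_, n_radial, n_longitudinal)
  thick <- numeric(n_longitudinal)
  rmid <- numeric(n_longitudinal)
  for (j in seq_len(n_longitudinal)) {
    th <- stations[j]
    d <- c(cos(th), sin(th))
    cr <- ray_polygon_crossings(c(cx, cy), d, poly)
    if (length(cr) < 2) {
      stop("segmentation error: band cross-section not found at a station",
           call. = FALSE)
    }
    r0 <- min(cr); r1 <- max(cr)
    rr <- seq(r0, r1, length.out = n_radial)
    pts[, j, 1] <- cx + rr * d[1]
    pts[, j, 2] <- cy + rr * d[2]
    tangent <- c(-sin(th), cos(th))
    lv[, j, 1] <- tangent[1]; lv[, j, 2] <- tangent[2]
    rv[, j, 1] <- d[1]; rv[, j, 2] <- d[2]
    s0[, j] <- rr * th  # arc-length coordinate at each point's own radius
    thick[j] <- r1 - r0
    rmid[j] <- (r0 + r1) / 2
  }
  # orient longitudinal vectors along increasing station angle
  if (stations[n_longitudinal] < stations[1]) {
    lv <- -lv
    s0 <- -s0
  }
  list(points = pts, long_vec = lv, rad_vec = rv, s0 = s0,
       mode = "curved", center = c(cx, cy),
       midline = cbind(cx + rmid * cos(stations), cy + rmid * sin(stations)),
       length = mean(rmid) * (max(stations) - min(stations)),
       thickness = mean(thick), stations = stations)
}

mesh_from_axis <- function(poly, n_radial, n_longitudinal) {
  ctr <- colMeans(poly)
  cc <- sweep(poly, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(poly), symmetric = TRUE)
  u <- ev$vectors[, 1]          # long axis
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u  # canonical orientation
  v <- c(-u[2], u[1])           # cross axis
  proj <- cc %*% u
  eps <- 1e-6 * (max(proj) - min(proj))
  stations <- seq(min(proj) + eps, max(proj) - eps,
                  length.out = n_longitudinal)
  pts <- array(NA_real_, c(n_radial, n_longitudinal, 2))
  lv <- array(NA_real_, c(n_radial, n_longitudinal, 2))
  rv <- array(NA_real_, c(n_radial, n_longitudinal, 2))
  s0 <- matrix(NA_real_, n_radial, n_longitudinal)
  thick <- numeric(n_longitudinal)
  midline <- matrix(NA_real_, n_longitudinal, 2)
  for (j in seq_len(n_longitudinal)) {
    o <- ctr + stations[j] * u
    # signed crossings of the full cross-section line through this station
    # (the axis line itself may run outside a curved band near its ends)
    ts <- c(ray_polygon_crossings(o, v, poly),
            -ray_polygon_crossings(o, -v, poly))
    if (length(ts) < 2) {
      stop("segmentation error: band cross-section not found at a station",
           call. = FALSE)
    }
    t1 <- -min(ts); t2 <- max(ts)
    tt <- seq(-t1, t2, length.out = n_radial)
    pts[, j, 1] <- o[1] + tt * v[1]
    pts[, j, 2] <- o[2] + tt * v[2]
    lv[, j, 1] <- u[1]; lv[, j, 2] <- u[2]
    rv[, j, 1] <- v[1]; rv[, j, 2] <- v[2]
    s0[, j] <- stations[j]
    thick[j] <- t1 + t2
    midline[j, ] <- o + (t2 - t1) / 2 * v
  }
  list(points = pts, long_vec = lv, rad_vec = rv, s0 = s0,
       mode = "straight", center = ctr, midline = midline,
       length = max(stations) - min(stations),
       thickness = mean(thick), stations = stations)
}

# flatten mesh points to an n x 2 matrix in (radial, longitudinal) order
mesh_point_matrix <- function(mesh) {
  cbind(as.vector(mesh$points[, , 1]), as.vector(mesh$points[, , 2]))
}
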