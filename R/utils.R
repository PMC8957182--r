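# internal helpers shared across modules

# Evaluate expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-item seed derivation, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# md5 of a serialized R object, reported as hex (provenance records)
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

# Shoelace area of a closed polygon given as an n x 2 matrix (x, y)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Even-odd point-in-polygon test; points on an edge count as inside
# (tolerance in the same units as the coordinates)
points_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xj <- x[c(2:n, 1)]; yj <- y[c(2:n, 1)]
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    cx <- px[k]; cy <- py[k]
    cross <- ((y > cy) != (yj > cy)) &
      (cx < (xj - x) * (cy - y) / (yj - y) + x)
    inn <- (sum(cross) %% 2) == 1
    if (!inn) {
      # boundary tolerance: distance to each edge
      dx <- xj - x; dy <- yj - y
      len2 <- dx * dx + dy * dy
      t <- pmin(1, pmax(0, ((cx - x) * dx + (cy - y) * dy) / pmax(len2, 1e-30)))
      ex <- x + t * dx - cx; ey <- y + t * dy - cy
      inn <- min(ex * ex + ey * ey) <= tol * tol
    }
    inside[k] <- inn
  }
  inside
}

seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-12) return(FALSE)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / denom
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / denom
  t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
}

# TRUE if the closed polygon has a proper self-intersection
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (sharing a vertex)
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (seg_intersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                        poly[idx[j, 1], ], poly[idx[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

# x first so matrix dimensions survive (pmax/pmin keep the attributes of
# their first argument)
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Monotone piecewise-cubic Hermite interpolation (Fritsch-Carlson style):
# interior knot slopes are the harmonic mean of neighbouring secants where
# those share a sign and zero otherwise (local extrema), so the interpolant
# is monotone on every inter-knot interval and attains extrema exactly at
# knots. stats::splinefun's "monoH.FC" does not zero slopes at
# direction-change knots and can overshoot there, which would corrupt the
# segment decomposition targets.
mono_hermite <- function(xk, yk, x) {
  n <- length(xk)
  stopifnot(n >= 2, length(yk) == n, all(diff(xk) > 0))
  h <- diff(xk)
  s <- diff(yk) / h
  m <- numeric(n)
  m[1] <- s[1]; m[n] <- s[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m[i] <- if (s[i - 1] * s[i] > 0) {
        2 * s[i - 1] * s[i] / (s[i - 1] + s[i])
      } else 0
    }
  }
  i <- findInterval(x, xk, rightmost.closed = TRUE)
  i <- clamp(i, 1L, n - 1L)
  t <- (x - xk[i]) / h[i]
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * yk[i] + h10 * h[i] * m[i] + h01 * yk[i + 1] + h11 * h[i] * m[i + 1]
}
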