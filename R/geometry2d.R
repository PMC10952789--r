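# Internal 2-D polygon utilities used by the substrate generator.
# Polygons are n x 2 matrices of vertices (mu-m), stored open (no repeated
# first vertex) and oriented counter-clockwise.

shoelace <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(poly) abs(shoelace(poly))

ensure_ccw <- function(poly) {
  if (shoelace(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# Sutherland-Hodgman clip of a convex polygon against half-plane n . x <= c.
# `nvec` need not be unit length.
clip_halfplane <- function(poly, nvec, cval) {
  if (is.null(poly) || nrow(poly) < 3) return(NULL)
  d <- poly %*% nvec - cval
  n <- nrow(poly)
  out <- matrix(0, n + 4, 2)
  k <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 0
    djn <- d[j] <= 0
    if (din) {
      k <- k + 1; out[k, ] <- poly[i, ]
    }
    if (din != djn) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1; out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k < 3) return(NULL)
  dedup_vertices(out[seq_len(k), , drop = FALSE])
}

dedup_vertices <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 2) return(poly)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i] && sum(abs(poly[i, ] - poly[j, ])) < tol) keep[j] <- FALSE
  }
  out <- poly[keep, , drop = FALSE]
  if (nrow(out) < 3) NULL else out
}

# Outward edge half-planes (unit normals) of a CCW convex polygon.
# Returns list(n = k x 2 matrix, c = k offsets) with n_i . x <= c_i inside.
edge_halfplanes <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  len <- sqrt(dx^2 + dy^2)
  ok <- len > 1e-12
  nx <- dy[ok] / len[ok]; ny <- -dx[ok] / len[ok]
  nv <- cbind(nx, ny)
  list(n = nv, c = rowSums(nv * a[ok, , drop = FALSE]))
}

# Uniform offset of a convex polygon: positive t shrinks, negative t grows
# (miter joins).  Returns NULL when the polygon vanishes.
convex_offset <- function(poly, t) {
  hp <- edge_halfplanes(poly)
  pad <- abs(t) + 1
  x0 <- min(poly[, 1]) - pad; x1 <- max(poly[, 1]) + pad
  y0 <- min(poly[, 2]) - pad; y1 <- max(poly[, 2]) + pad
  out <- matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), 4, 2, byrow = TRUE)
  for (i in seq_len(nrow(hp$n))) {
    out <- clip_halfplane(out, hp$n[i, ], hp$c[i] - t)
    if (is.null(out)) return(NULL)
  }
  out
}

convex_intersection_area <- function(a, b) {
  hp <- edge_halfplanes(b)
  out <- a
  for (i in seq_len(nrow(hp$n))) {
    out <- clip_halfplane(out, hp$n[i, ], hp$c[i])
    if (is.null(out)) return(0)
  }
  polygon_area(out)
}

# Even-odd point-in-polygon (R reference used by tests and small queries;
# the walker engine has its own C++ version).  Points on an edge count as
# outside, matching the extracellular boundary convention.
point_in_poly_r <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xc <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xc) inside <- !inside
    }
    j <- i
  }
  inside
}
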