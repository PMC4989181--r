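# Rasterisation helpers shared by the scene renderer.
# All masks are logical matrices indexed [row, col]; pixel centres sit at
# integer coordinates (row i, col j), and physical positions are
# (j - 0.5) * pixel_size, (i - 0.5) * pixel_size.

# Shoelace area of a polygon given vertex coordinates (closed implicitly).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Random convex polygon with `nv` vertices and exact target area (pixel
# units), centred at the origin.  Vertices are sorted angles with jittered
# radii; the hull of such points is convex by construction.
random_convex_polygon <- function(target_area, nv = sample(5:8, 1L)) {
  repeat {
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    if (min(diff(c(ang, ang[1] + 2 * pi))) > 0.15) break  # avoid slivers
  }
  rad <- stats::runif(nv, 0.7, 1.3)
  x <- rad * cos(ang)
  y <- rad * sin(ang)
  s <- sqrt(target_area / polygon_area(x, y))
  list(x = x * s, y = y * s)
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterise a polygon centred at (crow, ccol) into a logical mask of the
# frame dimensions; pixels whose centres fall inside are set.
rasterize_polygon <- function(dim, crow, ccol, poly) {
  rows <- max(1L, floor(crow + min(poly$y)) - 1L):min(dim[1], ceiling(crow + max(poly$y)) + 1L)
  cols <- max(1L, floor(ccol + min(poly$x)) - 1L):min(dim[2], ceiling(ccol + max(poly$x)) + 1L)
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  hit <- points_in_polygon(pc - ccol, pr - crow, poly$x, poly$y)
  m <- matrix(FALSE, dim[1], dim[2])
  m[cbind(pr[hit], pc[hit])] <- TRUE
  m
}

# Axis-aligned ellipse mask: semi-axes (a cols, b rows) in pixels.
ellipse_mask <- function(dim, crow, ccol, a, b) {
  rows <- max(1L, floor(crow - b)):min(dim[1], ceiling(crow + b))
  cols <- max(1L, floor(ccol - a)):min(dim[2], ceiling(ccol + a))
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  hit <- ((pc - ccol) / a)^2 + ((pr - crow) / b)^2 <= 1
  m <- matrix(FALSE, dim[1], dim[2])
  m[cbind(pr[hit], pc[hit])] <- TRUE
  m
}

disk_mask <- function(dim, crow, ccol, r) ellipse_mask(dim, crow, ccol, r, r)

# Smooth zero-mean unit-SD random field over the bounding box of `mask`,
# returned as a vector aligned with which(mask).  Used to give blobs a
# shared internal texture across Raman bands.
smooth_texture <- function(mask, smooth = 5L) {
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  g <- matrix(stats::rnorm((r1 - r0 + 1 + 2 * smooth) * (c1 - c0 + 1 + 2 * smooth)),
              r1 - r0 + 1 + 2 * smooth)
  k <- rep(1, smooth) / smooth
  g <- apply(g, 2, function(v) stats::filter(v, k, sides = 2))
  g <- t(apply(g, 1, function(v) stats::filter(v, k, sides = 2)))
  g <- g[smooth + (0:(r1 - r0)), smooth + (0:(c1 - c0)), drop = FALSE]
  v <- g[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)]
  v[is.na(v)] <- 0
  s <- stats::sd(v)
  if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}
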