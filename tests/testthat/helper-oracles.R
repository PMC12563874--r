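# Independent reference implementations used to check the production code.
# These deliberately use different algorithms from the package internals.

# mirror an out-of-range index back into [1, n] (edge pixel repeated)
.mirror_idx <- function(k, n) {
  if (k < 1) return(1 - k)
  if (k > n) return(2 * n + 1 - k)
  k
}

# brute-force bilateral filter: per-pixel double loop over the window
brute_bilateral <- function(img, sigma_spatial, sigma_range) {
  h <- nrow(img); w <- ncol(img)
  r <- min(ceiling(3 * sigma_spatial), h, w)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    fij <- img[i, j]
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      v <- img[.mirror_idx(i + di, h), .mirror_idx(j + dj, w)]
      wt <- exp(-(di^2 + dj^2) / (2 * sigma_spatial^2)) *
            exp(-(v - fij)^2 / (2 * sigma_range^2))
      num <- num + wt * v
      den <- den + wt
    }
    x <- num / den
    out[i, j] <- min(max(floor(x + 0.5), 0), 255)
  }
  out
}

# plain truncated-Gaussian blur with the same window/padding conventions
gaussian_blur_ref <- function(img, sigma_spatial) {
  h <- nrow(img); w <- ncol(img)
  r <- min(ceiling(3 * sigma_spatial), h, w)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      v <- img[.mirror_idx(i + di, h), .mirror_idx(j + dj, w)]
      wt <- exp(-(di^2 + dj^2) / (2 * sigma_spatial^2))
      num <- num + wt * v
      den <- den + wt
    }
    out[i, j] <- min(max(floor(num / den + 0.5), 0), 255)
  }
  out
}

# convex polygon intersection by vertex enumeration + convex hull (a different
# algorithm from the package's Sutherland-Hodgman clipping)
point_in_convex <- function(p, poly, tol = 1e-9) {
  n <- nrow(poly)
  s <- numeric(n)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    s[i] <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }
  all(s >= -tol) || all(s <= tol)
}

segment_intersections <- function(p1, p2, q1, q2, tol = 1e-12) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < tol) return(NULL)
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  if (t < -1e-9 || t > 1 + 1e-9 || u < -1e-9 || u > 1 + 1e-9) return(NULL)
  p1 + t * d1
}

poly_intersection_area_oracle <- function(pa, pb) {
  pts <- matrix(0, 0, 2)
  for (i in seq_len(nrow(pa)))
    if (point_in_convex(pa[i, ], pb)) pts <- rbind(pts, pa[i, ])
  for (i in seq_len(nrow(pb)))
    if (point_in_convex(pb[i, ], pa)) pts <- rbind(pts, pb[i, ])
  na <- nrow(pa); nb <- nrow(pb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    x <- segment_intersections(pa[i, ], pa[if (i == na) 1 else i + 1, ],
                               pb[j, ], pb[if (j == nb) 1 else j + 1, ])
    if (!is.null(x)) pts <- rbind(pts, x)
  }
  if (nrow(pts) < 3) return(0)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3) return(0)
  x <- hull[, 1]; y <- hull[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

rotated_iou_oracle <- function(a, b) {
  ca <- obb_corners(a); cb <- obb_corners(b)
  inter <- poly_intersection_area_oracle(ca, cb)
  inter / (a$w * a$h + b$w * b$h - inter)
}

# axis-aligned IoU closed form
aabb_iou <- function(a, b) {
  ix <- max(0, min(a$cx + a$w / 2, b$cx + b$w / 2) -
               max(a$cx - a$w / 2, b$cx - b$w / 2))
  iy <- max(0, min(a$cy + a$h / 2, b$cy + b$h / 2) -
               max(a$cy - a$h / 2, b$cy - b$h / 2))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

# random helpers (callers control the seed)
rand_line <- function() {
  repeat {
    v <- stats::runif(3, -10, 10)
    if (sqrt(v[1]^2 + v[2]^2) > 1e-3) return(ipath_line(v[1], v[2], v[3]))
  }
}

rand_obb <- function(span = 10) {
  oriented_box(stats::runif(1, -span, span), stats::runif(1, -span, span),
               stats::runif(1, 0.5, 6), stats::runif(1, 0.5, 6),
               stats::runif(1, 0, 180))
}

rand_gray <- function(h, w) {
  matrix(sample.int(256, h * w, replace = TRUE) - 1L, h, w)
}

expect_line_equal <- function(l1, l2, tol = 1e-9) {
  l1 <- canonicalize_line(l1); l2 <- canonicalize_line(l2)
  expect_lt(max(abs(c(l1$A - l2$A, l1$B - l2$B, l1$C - l2$C))), tol)
}
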