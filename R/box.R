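#' Oriented bounding box (OBB)
#'
#' A rectangle with center `(cx, cy)`, side lengths `w` and `h` (pixels) and
#' rotation `theta` in degrees, measured from the image +x axis towards +y
#' (y grows downwards), in `[0, 180)`.  At `theta = 0` the side of length `w`
#' runs along x and the side of length `h` along y.
#'
#' The (w, h, theta) parametrization is two-to-one: (w, h, theta) and
#' (h, w, theta + 90) describe the same rectangle.  The constructor stores the
#' canonical representative with `h >= w`, so that the long axis is always the
#' `h` axis and a box refitted from its corners reproduces the stored
#' parameters.  Squares keep the user's theta reduced mod 180.
#'
#' @param cx,cy center, pixels. @param w,h side lengths, pixels, `> 0`.
#' @param theta rotation in degrees; reduced mod 180.
#' @return An object of class `oriented_box`.
#' @export
oriented_box <- function(cx, cy, w, h, theta = 0) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(w), is.finite(h),
            is.finite(theta), w > 0, h > 0)
  theta <- theta %% 180
  if (w > h) {  # canonical representative: long side along the h axis
    tmp <- w; w <- h; h <- tmp
    theta <- (theta + 90) %% 180
  }
  structure(list(cx = cx, cy = cy, w = w, h = h, theta = theta),
            class = "oriented_box")
}

#' Horizontal (axis-aligned) bounding box
#'
#' @param cx,cy center; `w,h` side lengths, pixels, `> 0`.
#' @return An object of class `horizontal_box`.
#' @export
horizontal_box <- function(cx, cy, w, h) {
  stopifnot(is.finite(cx), is.finite(cy), w > 0, h > 0)
  structure(list(cx = cx, cy = cy, w = w, h = h), class = "horizontal_box")
}

#' @export
print.oriented_box <- function(x, ...) {
  cat(sprintf("<obb> center (%.2f, %.2f)  w %.2f  h %.2f  theta %.2f deg\n",
              x$cx, x$cy, x$w, x$h, x$theta))
  invisible(x)
}

#' @export
print.horizontal_box <- function(x, ...) {
  cat(sprintf("<hbb> center (%.2f, %.2f)  w %.2f  h %.2f\n",
              x$cx, x$cy, x$w, x$h))
  invisible(x)
}

.rotmat <- function(theta_deg) {
  t <- .deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

#' Corners of an oriented box
#'
#' Fixed convention: starting at the (-w/2, -h/2) corner of the unrotated box
#' and winding (-w/2,-h/2), (w/2,-h/2), (w/2,h/2), (-w/2,h/2), then rotated by
#' theta and translated to the center.
#'
#' @param b an `oriented_box` (or `horizontal_box`).
#' @return 4 x 2 matrix of corner coordinates (columns x, y).
#' @export
obb_corners <- function(b) {
  if (inherits(b, "horizontal_box")) b <- oriented_box(b$cx, b$cy, b$w, b$h, 0)
  local <- matrix(c(-b$w / 2, -b$h / 2,
                     b$w / 2, -b$h / 2,
                     b$w / 2,  b$h / 2,
                    -b$w / 2,  b$h / 2), 4, 2, byrow = TRUE)
  world <- local %*% t(.rotmat(b$theta))
  world[, 1] <- world[, 1] + b$cx
  world[, 2] <- world[, 2] + b$cy
  world
}

#' Minimum-area enclosing rectangle of a point set
#'
#' Rotating calipers over the convex hull: one hull edge is flush with the
#' optimal rectangle.  Used both to refit an `oriented_box` from label-file
#' corners and to estimate boxes from thresholded image regions.
#'
#' @param pts n x 2 matrix of points (n >= 3, not all collinear).
#' @return An `oriented_box` (canonical form; for squares theta in [0, 90)).
#' @export
min_area_rect <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 3)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) < 3)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  best <- NULL; best_area <- Inf
  n <- nrow(hull)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1 else i + 1, ]
    e <- b - a
    len <- sqrt(sum(e * e))
    if (len < 1e-12) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    du <- max(pu) - min(pu); dv <- max(pv) - min(pv)
    area <- du * dv
    if (area < best_area - 1e-12) {
      best_area <- area
      cu <- (max(pu) + min(pu)) / 2; cv <- (max(pv) + min(pv)) / 2
      center <- cu * u + cv * v
      ang <- .rad2deg(atan2(u[2], u[1])) %% 180
      best <- list(cx = center[1], cy = center[2], w = du, h = dv, theta = ang)
    }
  }
  b <- oriented_box(best$cx, best$cy, max(best$w, 1e-9), max(best$h, 1e-9),
                    best$theta)
  if (abs(b$w - b$h) < 1e-9 && b$theta >= 90)  # square: resolve theta to [0,90)
    b <- structure(list(cx = b$cx, cy = b$cy, w = b$w, h = b$h,
                        theta = b$theta - 90), class = "oriented_box")
  b
}

#' Long axis of an oriented box
#'
#' The line through the center along the side of greater length (the `h` side
#' in canonical form) — the clinical angulation reference of a detected tooth.
#' For a square box the long axis is ill-defined; the `h` axis is used and a
#' warning is raised.
#'
#' @param b an `oriented_box`.
#' @return Canonical `ipath_line` through the center.
#' @export
long_axis <- function(b) {
  if (abs(b$w - b$h) < 1e-12)
    warning("square box: long axis is ill-defined, using the h axis",
            call. = FALSE)
  line_from_point_direction(c(b$cx, b$cy), (b$theta + 90) %% 180)
}

#' Lateral edge lines of an oriented box
#'
#' The two lines along the long sides of the box: parallel to [long_axis()],
#' offset by half the short side on either side, so the long axis is exactly
#' their midline.  These are the auxiliary lines extended along the OBB edges
#' of an adjacent tooth.
#'
#' @param b an `oriented_box`.
#' @return List of two canonical `ipath_line`s.
#' @export
lateral_edge_lines <- function(b) {
  axis <- suppressWarnings(long_axis(b))
  half <- min(b$w, b$h) / 2
  list(canonicalize_line(structure(list(A = axis$A, B = axis$B, C = axis$C - half),
                                   class = "ipath_line")),
       canonicalize_line(structure(list(A = axis$A, B = axis$B, C = axis$C + half),
                                   class = "ipath_line")))
}

#' Is a point inside an oriented box?
#' @param b an `oriented_box`; `p` numeric `c(x, y)`.
#' @return Logical.
#' @export
point_in_obb <- function(b, p) {
  d <- c(p[1] - b$cx, p[2] - b$cy)
  local <- t(.rotmat(-b$theta) %*% d)
  abs(local[1]) <= b$w / 2 + 1e-9 && abs(local[2]) <= b$h / 2 + 1e-9
}
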