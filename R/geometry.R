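# Coordinate convention, used identically across all modules:
#   * image coordinates, 0-based, pixel centers at integer coordinates;
#   * x grows rightwards (matrix column - 1), y grows DOWNWARDS (matrix row - 1);
#   * angles in degrees, measured from the +x axis towards the +y axis
#     (counter-clockwise in the y-down image frame), reduced modulo 180.

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

#' Implicit 2-D line A*x + B*y + C = 0
#'
#' Lines are stored in canonical implicit form: `A^2 + B^2 = 1` with the sign
#' fixed so that `A > 0`, or `A = 0` and `B > 0`.  The canonical form makes the
#' two branches of the angle-bisector equation deterministic and lets the
#' bisector denominators drop out (they are exactly 1).
#'
#' @param A,B,C coefficients of the implicit form; `A` and `B` must not both
#'   be (numerically) zero.
#' @return An object of class `ipath_line`.
#' @export
ipath_line <- function(A, B, C) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C),
            length(A) == 1, length(B) == 1, length(C) == 1,
            is.finite(A), is.finite(B), is.finite(C))
  canonicalize_line(structure(list(A = A, B = B, C = C), class = "ipath_line"))
}

#' Canonicalize an implicit line
#'
#' Rescales the coefficients so `A^2 + B^2 = 1` and fixes the overall sign
#' (`A > 0`, or `A = 0` and `B > 0`).  Idempotent; the point set is unchanged.
#'
#' @param l an `ipath_line` (or a bare list with fields A, B, C).
#' @return The canonical `ipath_line`.
#' @export
canonicalize_line <- function(l) {
  A <- l$A; B <- l$B; C <- l$C
  n <- sqrt(A * A + B * B)
  if (!is.finite(n) || n < 1e-300)
    stop("invalid line: A and B are both zero", call. = FALSE)
  A <- A / n; B <- B / n; C <- C / n
  # snap a numerically-zero leading coefficient so the sign rule is stable
  if (abs(A) < 1e-12) {
    s <- if (B < 0) -1 else 1
    A <- 0; C <- s * C; B <- 1
  } else if (A < 0) {
    A <- -A; B <- -B; C <- -C
  }
  structure(list(A = A, B = B, C = C), class = "ipath_line")
}

#' @export
print.ipath_line <- function(x, ...) {
  cat(sprintf("<line> %+.6f*x %+.6f*y %+.6f = 0  (direction %.3f deg)\n",
              x$A, x$B, x$C, line_direction_deg(x)))
  invisible(x)
}

#' @export
format.ipath_line <- function(x, ...) {
  sprintf("(%.6f, %.6f, %.6f)", x$A, x$B, x$C)
}

#' Line through two points
#'
#' @param p1,p2 numeric length-2 vectors `c(x, y)`; must differ.
#' @return Canonical `ipath_line` through both points.
#' @export
line_from_points <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2, all(is.finite(c(p1, p2))))
  if (max(abs(p1 - p2)) < 1e-12)
    stop("degenerate geometry: coincident points define no line", call. = FALSE)
  A <- p2[2] - p1[2]
  B <- p1[1] - p2[1]
  C <- p2[1] * p1[2] - p1[1] * p2[2]
  ipath_line(A, B, C)
}

#' Line through a point with a given direction
#'
#' @param p numeric `c(x, y)`.
#' @param direction_deg direction in degrees (mod 180).
#' @return Canonical `ipath_line`.
#' @export
line_from_point_direction <- function(p, direction_deg) {
  d <- .deg2rad(direction_deg)
  A <- sin(d); B <- -cos(d)
  ipath_line(A, B, -(A * p[1] + B * p[2]))
}

#' Direction of a line in degrees, in [0, 180)
#'
#' Consistent with the oriented-box `theta` convention (from +x towards +y).
#'
#' @param l an `ipath_line`.
#' @return Degrees in `[0, 180)`.
#' @export
line_direction_deg <- function(l) {
  l <- canonicalize_line(l)
  # direction vector of the line is (B, -A)
  d <- .rad2deg(atan2(-l$A, l$B)) %% 180
  if (d >= 180 - 1e-12) d <- 0
  d
}

#' Unsigned angle between two lines, in [0, 90] degrees
#'
#' Symmetric; 0 iff parallel, 90 iff perpendicular.
#'
#' @param l1,l2 `ipath_line` objects.
#' @return Degrees in `[0, 90]`.
#' @export
angle_between <- function(l1, l2) {
  d <- abs(line_direction_deg(l1) - line_direction_deg(l2)) %% 180
  min(d, 180 - d)
}

#' Signed perpendicular distance from a point to a line
#'
#' For a canonical line the implicit form evaluated at the point *is* the
#' signed distance.
#'
#' @param l an `ipath_line`; `p` numeric `c(x, y)`.
#' @return Signed distance in pixels.
#' @export
line_eval <- function(l, p) {
  l <- canonicalize_line(l)
  l$A * p[1] + l$B * p[2] + l$C
}

#' Intersection point of two lines
#'
#' @param l1,l2 `ipath_line` objects.
#' @return `c(x, y)`, or `NULL` when the lines are parallel.
#' @export
line_intersection <- function(l1, l2) {
  l1 <- canonicalize_line(l1); l2 <- canonicalize_line(l2)
  D <- l1$A * l2$B - l2$A * l1$B
  if (abs(D) < 1e-12) return(NULL)
  x <- (-l1$C * l2$B + l2$C * l1$B) / D
  y <- (-l1$A * l2$C + l2$A * l1$C) / D
  c(x, y)
}

#' Angle bisectors of two lines
#'
#' Solves the bisector equation of the two canonical implicit forms,
#' `(A1 x + B1 y + C1) = +/- (A2 x + B2 y + C2)` (unit denominators).  For
#' non-parallel input the two solutions make equal angles with both inputs and
#' are mutually perpendicular.
#'
#' For *parallel* (but not identical) inputs the midline is returned as a
#' single line carrying `attr(, "parallel") = TRUE` — two adjacent teeth can
#' have perfectly parallel axes, so this is a legitimate input, not an error.
#'
#' @param l1,l2 `ipath_line` objects; must not be identical.
#' @return A list of two `ipath_line`s, or a single midline with attribute
#'   `parallel = TRUE`.
#' @export
angle_bisectors <- function(l1, l2) {
  l1 <- canonicalize_line(l1); l2 <- canonicalize_line(l2)
  # canonical parallel lines share (A, B) exactly up to the snap tolerance
  par <- abs(l1$A - l2$A) < 1e-9 && abs(l1$B - l2$B) < 1e-9
  if (par) {
    if (abs(l1$C - l2$C) < 1e-9)
      stop("degenerate geometry: identical lines have no bisector", call. = FALSE)
    mid <- canonicalize_line(structure(list(A = l1$A, B = l1$B,
                                            C = (l1$C + l2$C) / 2),
                                       class = "ipath_line"))
    attr(mid, "parallel") <- TRUE
    return(mid)
  }
  b_plus  <- ipath_line(l1$A - l2$A, l1$B - l2$B, l1$C - l2$C)
  b_minus <- ipath_line(l1$A + l2$A, l1$B + l2$B, l1$C + l2$C)
  list(b_plus, b_minus)
}

# --- convex polygon helpers (shared by rotated IoU and overlap checks) -------

#' Area of a simple polygon (shoelace)
#' @param poly n x 2 matrix of vertices in order.
#' @return Non-negative area.
#' @export
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Clip a convex polygon against another (Sutherland-Hodgman)
#'
#' @param subject,clip n x 2 vertex matrices of convex polygons (any winding).
#' @return Vertex matrix of the intersection polygon (possibly 0 rows).
#' @export
convex_clip <- function(subject, clip) {
  # orient the clip polygon counter-clockwise (in the numeric sense)
  x <- clip[, 1]; y <- clip[, 2]
  signed <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (signed < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    n <- nrow(inp)
    # interior of a CCW-oriented clip polygon is to the left of each edge
    side <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])
    keep <- side >= -1e-12
    res <- matrix(0, 0, 2)
    for (j in seq_len(n)) {
      k <- if (j == n) 1 else j + 1
      p <- inp[j, ]; q <- inp[k, ]
      if (keep[j]) res <- rbind(res, p)
      if (xor(keep[j], keep[k])) {
        t <- side[j] / (side[j] - side[k])
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  out
}
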