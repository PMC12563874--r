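#' Pair of teeth adjacent to a single-tooth edentulous gap
#'
#' The two oriented boxes are ordered by center x (panoramic radiographs have
#' a standardized orientation), and must not overlap: an overlapping pair
#' cannot flank a gap.
#'
#' @param b1,b2 `oriented_box` detections of the two adjacent teeth.
#' @param gap_center optional `c(x, y)`; computed from the gap-facing edges
#'   when absent.
#' @return An object of class `tooth_pair` with fields `left`, `right`,
#'   `gap_center`.
#' @export
tooth_pair <- function(b1, b2, gap_center = NULL) {
  stopifnot(inherits(b1, "oriented_box"), inherits(b2, "oriented_box"))
  if (b1$cx <= b2$cx) { left <- b1; right <- b2 } else { left <- b2; right <- b1 }
  inter <- convex_clip(obb_corners(left), obb_corners(right))
  if (polygon_area(inter) > 1e-9 ||
      point_in_obb(left, c(right$cx, right$cy)) ||
      point_in_obb(right, c(left$cx, left$cy)))
    stop("invalid pair: tooth boxes overlap", call. = FALSE)
  pair <- structure(list(left = left, right = right, gap_center = gap_center),
                    class = "tooth_pair")
  if (is.null(gap_center))
    pair$gap_center <- (gap_edge_info(pair$left, pair$right)$edge_mid +
                        gap_edge_info(pair$right, pair$left)$edge_mid) / 2
  pair
}

#' @export
print.tooth_pair <- function(x, ...) {
  cat("<tooth pair>\n  left : "); print(x$left)
  cat("  right: "); print(x$right)
  cat(sprintf("  gap center (%.2f, %.2f)\n", x$gap_center[1], x$gap_center[2]))
  invisible(x)
}

# Gap-facing lateral edge of `b` (the one nearer the other box's center),
# together with its two corners and their midpoint, and the crest-side corner
# (smaller y = coronal in the y-down image frame).
gap_edge_info <- function(b, other) {
  edges <- lateral_edge_lines(b)
  d <- vapply(edges, function(l) abs(line_eval(l, c(other$cx, other$cy))),
              numeric(1))
  edge <- edges[[which.min(d)]]
  corners <- obb_corners(b)
  on_edge <- abs(corners[, 1] * edge$A + corners[, 2] * edge$B + edge$C) < 1e-6
  ec <- corners[on_edge, , drop = FALSE]
  list(edge = edge,
       corners = ec,
       edge_mid = colMeans(ec),
       crest_corner = ec[which.min(ec[, 2]), ])
}

#' Select the internal bisector of the Eq.-style ± pair
#'
#' Of the two mutually perpendicular bisectors, returns the one whose
#' direction lies inside the wedge spanned by the two tooth long-axis
#' directions (the wedge of span < 90 degrees).  When the wedge spans exactly
#' 90 degrees both candidates qualify; the tie is broken towards the bisector
#' closer to vertical (90 degrees) and the result carries
#' `attr(, "wedge_tie") = TRUE`.
#'
#' @param b1,b2 the two candidate bisector `ipath_line`s (perpendicular pair).
#' @param axes list of the two axis `ipath_line`s defining the wedge.
#' @return One of `b1`, `b2`.
#' @export
select_internal_bisector <- function(b1, b2, axes) {
  d1 <- line_direction_deg(axes[[1]])
  d2 <- line_direction_deg(axes[[2]])
  delta <- ((d2 - d1 + 90) %% 180) - 90     # signed wedge span in (-90, 90]
  mid <- (d1 + delta / 2) %% 180            # direction of the internal bisector
  cand <- list(b1, b2)
  dev <- vapply(cand, function(l) {
    dd <- abs(line_direction_deg(l) - mid) %% 180
    min(dd, 180 - dd)
  }, numeric(1))
  if (abs(abs(delta) - 90) < 1e-9) {
    # 90-degree wedge: both are internal; prefer the more vertical candidate
    vert <- vapply(cand, function(l) {
      dd <- abs(line_direction_deg(l) - 90) %% 180
      min(dd, 180 - dd)
    }, numeric(1))
    out <- cand[[which.min(vert)]]
    attr(out, "wedge_tie") <- TRUE
    return(out)
  }
  cand[[which.min(dev)]]
}

#' Derive the implant pathway for a tooth pair
#'
#' Implements the auxiliary-line / internal-bisector construction: auxiliary
#' lines are extended along the gap-facing lateral edges of the two adjacent
#' teeth (optionally their central long axes), their angle bisectors are
#' computed from the canonical implicit forms, and the internal bisector —
#' the one lying inside the wedge spanned by the two tooth long-axis
#' directions — is taken as the implant pathway orientation.  Parallel
#' auxiliary lines (parallel adjacent teeth) yield their midline.
#'
#' The entry point is the intersection of the pathway with the crest segment
#' joining the two gap-facing, crest-side box corners (the coronal ends of
#' the gap).
#'
#' @param pair a `tooth_pair`.
#' @param use_edges use the gap-facing lateral edge lines as the auxiliary
#'   lines (default); `FALSE` uses the central long axes instead.
#' @param extent half-length, in pixels, of the rendered pathway segment;
#'   default 60% of the longer tooth box.
#' @return An object of class `implant_pathway`: fields `line` (canonical
#'   `ipath_line`), `entry_point`, `angle_deg` (= direction of `line`),
#'   `segment` (2 x 2 endpoint matrix), plus the auxiliary lines and axes for
#'   plotting.
#' @export
derive_pathway <- function(pair, use_edges = TRUE, extent = NULL) {
  stopifnot(inherits(pair, "tooth_pair"))
  axes <- list(suppressWarnings(long_axis(pair$left)),
               suppressWarnings(long_axis(pair$right)))
  infoL <- gap_edge_info(pair$left, pair$right)
  infoR <- gap_edge_info(pair$right, pair$left)
  aux <- if (use_edges) list(infoL$edge, infoR$edge) else axes

  bis <- angle_bisectors(aux[[1]], aux[[2]])
  parallel <- !is.list(bis) || inherits(bis, "ipath_line")
  path_line <- if (parallel) bis else
    select_internal_bisector(bis[[1]], bis[[2]], axes)

  # entry: pathway meets the crest segment between the coronal gap corners
  crest <- line_from_points(infoL$crest_corner, infoR$crest_corner)
  entry <- line_intersection(path_line, crest)
  if (is.null(entry)) entry <- .project_onto_line(path_line, pair$gap_center)

  if (is.null(extent))
    extent <- 0.6 * max(pair$left$h, pair$right$h)
  seg <- pathway_segment(path_line, entry, extent)

  structure(list(line = path_line,
                 entry_point = entry,
                 angle_deg = line_direction_deg(path_line),
                 segment = seg,
                 aux_lines = aux,
                 axes = axes,
                 parallel_aux = isTRUE(attr(path_line, "parallel")),
                 pair = pair),
            class = "implant_pathway")
}

.project_onto_line <- function(l, p) {
  l <- canonicalize_line(l)
  d <- line_eval(l, p)
  c(p[1] - d * l$A, p[2] - d * l$B)
}

#' Segment of given half-length along a line, centered on a point
#'
#' @param line an `ipath_line`; `center` a point on (or near) the line;
#'   `extent` half-length in pixels.
#' @return 2 x 2 matrix, one endpoint per row.
#' @export
pathway_segment <- function(line, center, extent) {
  l <- canonicalize_line(line)
  u <- c(l$B, -l$A)                      # unit direction
  rbind(center - extent * u, center + extent * u)
}

#' @export
print.implant_pathway <- function(x, ...) {
  cat("<implant pathway>\n")
  cat(sprintf("  angle      : %.3f deg\n", x$angle_deg))
  cat(sprintf("  line       : %+.6f*x %+.6f*y %+.6f = 0\n",
              x$line$A, x$line$B, x$line$C))
  cat(sprintf("  entry point: (%.2f, %.2f)\n",
              x$entry_point[1], x$entry_point[2]))
  if (x$parallel_aux)
    cat("  note: parallel auxiliary lines; pathway is their midline\n")
  invisible(x)
}

#' @export
summary.implant_pathway <- function(object, ...) {
  axdeg <- vapply(object$axes, line_direction_deg, numeric(1))
  cat("Implant pathway summary\n")
  cat(sprintf("  tooth axis directions : %.3f, %.3f deg\n", axdeg[1], axdeg[2]))
  cat(sprintf("  wedge span            : %.3f deg\n",
              angle_between(object$axes[[1]], object$axes[[2]])))
  print(object)
  invisible(object)
}

#' Plot an implant pathway over its tooth pair
#'
#' Draws the two tooth boxes, the auxiliary lines (yellow / blue), the
#' pathway segment (green) and the entry point, in image coordinates
#' (y axis pointing down).
#'
#' @param x an `implant_pathway`. @param image optional grayscale matrix
#'   (values 0-255) drawn underneath. @param ... passed to `plot`.
#' @export
plot.implant_pathway <- function(x, image = NULL, ...) {
  cl <- obb_corners(x$pair$left); cr <- obb_corners(x$pair$right)
  allx <- c(cl[, 1], cr[, 1], x$segment[, 1])
  ally <- c(cl[, 2], cr[, 2], x$segment[, 2])
  plot(NA, xlim = range(allx) + c(-10, 10), ylim = rev(range(ally) + c(-10, 10)),
       xlab = "x (px)", ylab = "y (px)", asp = 1, ...)
  if (!is.null(image)) {
    h <- nrow(image); w <- ncol(image)
    graphics::rasterImage(image / 255, -0.5, h - 0.5, w - 0.5, -0.5)
  }
  graphics::polygon(cl[, 1], cl[, 2], border = "red")
  graphics::polygon(cr[, 1], cr[, 2], border = "red")
  .abline_ipath(x$aux_lines[[1]], col = "goldenrod", lty = 2)
  .abline_ipath(x$aux_lines[[2]], col = "blue", lty = 2)
  graphics::segments(x$segment[1, 1], x$segment[1, 2],
                     x$segment[2, 1], x$segment[2, 2],
                     col = "forestgreen", lwd = 2)
  graphics::points(x$entry_point[1], x$entry_point[2], pch = 19, col = "forestgreen")
  invisible(x)
}

.abline_ipath <- function(l, ...) {
  l <- canonicalize_line(l)
  if (abs(l$B) < 1e-9) graphics::abline(v = -l$C / l$A, ...)
  else graphics::abline(a = -l$C / l$B, b = -l$A / l$B, ...)
}
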