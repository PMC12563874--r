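# Rasterization helpers for the overlay renderer.  Strokes are stamped as
# squares of side `width` at 0.25-px steps along the segment — crude but
# dependency-free and adequate for visual QC output.

.stamp <- function(rgb, x, y, width, col) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  r <- floor((width - 1) / 2)
  xi <- round(x); yi <- round(y)
  for (dy in -r:r) for (dx in -r:r) {
    cx <- xi + dx; cy <- yi + dy
    ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
    if (any(ok)) {
      idx_r <- cy[ok] + 1L; idx_c <- cx[ok] + 1L
      for (k in 1:3) rgb[cbind(idx_r, idx_c, k)] <- col[k]
    }
  }
  rgb
}

.draw_segment <- function(rgb, p1, p2, col, width = 3) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(2L, ceiling(len / 0.25))
  t <- seq(0, 1, length.out = n)
  .stamp(rgb, p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]),
         width, col)
}

.draw_polygon <- function(rgb, corners, col, width = 2) {
  n <- nrow(corners)
  for (i in seq_len(n))
    rgb <- .draw_segment(rgb, corners[i, ], corners[if (i == n) 1 else i + 1, ],
                         col, width)
  rgb
}

#' Render an annotation / pathway overlay
#'
#' Produces an RGB copy of the grayscale image with detection boxes (red),
#' the two auxiliary reference lines (yellow and blue), the pathway segment
#' (green) and the entry point.  The input image is not modified.
#'
#' @param img integer grayscale matrix in `[0, 255]`.
#' @param set optional `annotation_set` whose records carry pixel-unit boxes.
#' @param pathway optional `implant_pathway`.
#' @param stroke stroke width in pixels (default 3).
#' @return `height x width x 3` numeric array in `[0, 1]`.
#' @export
render_overlay <- function(img, set = NULL, pathway = NULL, stroke = 3) {
  assert_gray(img)
  rgb <- array(rep(img / 255, 3), dim = c(nrow(img), ncol(img), 3))
  if (!is.null(set)) {
    for (rec in set$records) {
      if (is.null(rec$box)) next
      rgb <- .draw_polygon(rgb, obb_corners(.as_obb(rec$box)), c(1, 0.25, 0.25),
                           width = max(1, stroke - 1))
    }
  }
  if (!is.null(pathway)) {
    ext <- sqrt(sum((pathway$segment[2, ] - pathway$segment[1, ])^2)) / 2
    aux_cols <- list(c(1, 0.85, 0), c(0.1, 0.3, 1))   # yellow, blue
    for (i in 1:2) {
      l <- pathway$aux_lines[[i]]
      foot <- .project_onto_line(l, pathway$entry_point)
      seg <- pathway_segment(l, foot, ext)
      rgb <- .draw_segment(rgb, seg[1, ], seg[2, ], aux_cols[[i]],
                           width = max(1, stroke - 1))
    }
    rgb <- .draw_segment(rgb, pathway$segment[1, ], pathway$segment[2, ],
                         c(0, 0.8, 0.2), width = stroke)
    rgb <- .stamp(rgb, pathway$entry_point[1], pathway$entry_point[2],
                  stroke + 2, c(0, 0.8, 0.2))
  }
  rgb
}

#' Write an overlay to a PNG file
#' @param rgb array from [render_overlay()]. @param path destination.
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
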