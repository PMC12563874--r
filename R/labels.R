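# Label interchange: the de-facto normalized text dialects.
#   OBB : "class x1 y1 x2 y2 x3 y3 x4 y4 [confidence]"  (corners, normalized)
#   HBB : "class cx cy w h [confidence]"                 (normalized)
# Normalized coordinates are pixel coordinates divided by image width/height.

#' Annotation set for one image
#'
#' @param image_id non-empty string identifying the image.
#' @param records list of label records (see [read_obb_labels()]).
#' @param truth_endpoints optional 2 x 2 matrix: ground-truth pathway endpoints.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, records = list(), truth_endpoints = NULL) {
  stopifnot(is.character(image_id), nzchar(image_id))
  structure(list(image_id = image_id, records = records,
                 truth_endpoints = truth_endpoints),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation set> image '%s': %d record(s)%s\n", x$image_id,
              length(x$records),
              if (is.null(x$truth_endpoints)) "" else " + truth pathway"))
  invisible(x)
}

.parse_label_line <- function(line, lineno, ntok_geom, path) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (!(length(tok) %in% c(ntok_geom + 1L, ntok_geom + 2L)))
    stop(sprintf("parse error in %s, line %d: expected %d or %d fields, got %d",
                 basename(path), lineno, ntok_geom + 1L, ntok_geom + 2L,
                 length(tok)), call. = FALSE)
  vals <- suppressWarnings(as.numeric(tok))
  if (any(is.na(vals)))
    stop(sprintf("parse error in %s, line %d: non-numeric field",
                 basename(path), lineno), call. = FALSE)
  geom <- vals[2:(ntok_geom + 1L)]
  if (any(geom < -1e-9 | geom > 1 + 1e-9))
    stop(sprintf("parse error in %s, line %d: normalized coordinate out of [0, 1]",
                 basename(path), lineno), call. = FALSE)
  conf <- if (length(tok) == ntok_geom + 2L) vals[ntok_geom + 2L] else NA_real_
  if (!is.na(conf) && (conf < 0 || conf > 1))
    stop(sprintf("parse error in %s, line %d: confidence out of [0, 1]",
                 basename(path), lineno), call. = FALSE)
  list(class_id = as.integer(vals[1]), geom = pmin(pmax(geom, 0), 1), conf = conf)
}

#' Read oriented-box labels
#'
#' One object per line: class id, then the four corner coordinate pairs
#' normalized to `[0, 1]`, optionally followed by a confidence.  Corners must
#' form a rectangle within a normalized tolerance of 1e-3.  When
#' `image_size` is supplied, corners are de-normalized and each record gains
#' an `oriented_box` (`box` field) fitted by minimum-area rectangle.
#'
#' @param path label text file.
#' @param image_size optional `c(width, height)` in pixels.
#' @return An `annotation_set`; each record has fields `class_id`, `corners`
#'   (4 x 2, normalized), `box` (`oriented_box` or `NULL`), `confidence`.
#' @export
read_obb_labels <- function(path, image_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  records <- vector("list", length(lines_keep))
  for (i in seq_along(lines_keep)) {
    ln <- lines_keep[i]
    p <- .parse_label_line(lines[ln], ln, 8L, path)
    corners <- matrix(p$geom, 4, 2, byrow = TRUE)
    box <- NULL
    if (!is.null(image_size)) {
      px <- corners
      px[, 1] <- px[, 1] * image_size[1]
      px[, 2] <- px[, 2] * image_size[2]
      box <- min_area_rect(px)
      fitc <- obb_corners(box)
      err <- max(apply(px, 1, function(pt)
        min(sqrt(rowSums((fitc - matrix(pt, 4, 2, byrow = TRUE))^2)))))
      if (err > 1e-3 * max(image_size))
        stop(sprintf("parse error in %s, line %d: corners are not a rectangle",
                     basename(path), ln), call. = FALSE)
    } else {
      # without the pixel aspect ratio true rectangularity cannot be checked
      # (anisotropic normalization turns rectangles into parallelograms), so
      # validate the scale-invariant parallelogram property instead
      if (max(abs(corners[1, ] + corners[3, ] - corners[2, ] - corners[4, ])) > 1e-3)
        stop(sprintf("parse error in %s, line %d: corners are not a rectangle",
                     basename(path), ln), call. = FALSE)
    }
    records[[i]] <- list(class_id = p$class_id, corners = corners,
                         box = box, confidence = p$conf)
  }
  annotation_set(tools::file_path_sans_ext(basename(path)), records)
}

#' Write oriented-box labels
#'
#' Inverse of [read_obb_labels()]; coordinates are written with 6 decimals so
#' a write-read round trip is lossless to 1e-6.
#'
#' @param set an `annotation_set` whose records carry `box` (`oriented_box`,
#'   pixel units; requires `image_size`) or normalized `corners`.
#' @param path destination file.
#' @param image_size `c(width, height)`; required when writing from boxes.
#' @return Invisibly, `path`.
#' @export
write_obb_labels <- function(set, path, image_size = NULL) {
  lines <- vapply(set$records, function(rec) {
    if (!is.null(rec$box)) {
      stopifnot(!is.null(image_size))
      corners <- obb_corners(rec$box)
      corners[, 1] <- corners[, 1] / image_size[1]
      corners[, 2] <- corners[, 2] / image_size[2]
    } else corners <- rec$corners
    vals <- sprintf("%.6f", as.vector(t(corners)))
    conf <- if (!is.null(rec$confidence) && !is.na(rec$confidence))
      sprintf(" %.6f", rec$confidence) else ""
    paste0(rec$class_id, " ", paste(vals, collapse = " "), conf)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read horizontal-box labels ("class cx cy w h", normalized)
#'
#' @inheritParams read_obb_labels
#' @return An `annotation_set`; records carry `class_id`, `hbb_norm`
#'   (`c(cx, cy, w, h)` normalized), `box` (`horizontal_box` in pixels or
#'   `NULL`), `confidence`.
#' @export
read_hbb_labels <- function(path, image_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  records <- vector("list", length(lines_keep))
  for (i in seq_along(lines_keep)) {
    ln <- lines_keep[i]
    p <- .parse_label_line(lines[ln], ln, 4L, path)
    if (p$geom[3] <= 0 || p$geom[4] <= 0)
      stop(sprintf("parse error in %s, line %d: non-positive box size",
                   basename(path), ln), call. = FALSE)
    box <- NULL
    if (!is.null(image_size))
      box <- horizontal_box(p$geom[1] * image_size[1], p$geom[2] * image_size[2],
                            p$geom[3] * image_size[1], p$geom[4] * image_size[2])
    records[[i]] <- list(class_id = p$class_id, hbb_norm = p$geom,
                         box = box, confidence = p$conf)
  }
  annotation_set(tools::file_path_sans_ext(basename(path)), records)
}

#' Write horizontal-box labels
#' @inheritParams write_obb_labels
#' @export
write_hbb_labels <- function(set, path, image_size = NULL) {
  lines <- vapply(set$records, function(rec) {
    if (!is.null(rec$box)) {
      stopifnot(!is.null(image_size))
      g <- c(rec$box$cx / image_size[1], rec$box$cy / image_size[2],
             rec$box$w / image_size[1], rec$box$h / image_size[2])
    } else g <- rec$hbb_norm
    conf <- if (!is.null(rec$confidence) && !is.na(rec$confidence))
      sprintf(" %.6f", rec$confidence) else ""
    paste0(rec$class_id, " ", paste(sprintf("%.6f", g), collapse = " "), conf)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# fixed-precision JSON so identical runs produce byte-identical artifacts
write_json6 <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 6, pretty = TRUE,
                              na = "null"), path)
  invisible(path)
}

#' Write a derived pathway as JSON
#'
#' Schema: `{image, line: {A, B, C}, angle_deg, entry: [x, y],
#' segment: [[x, y], [x, y]]}`, numbers at 6 decimals.
#'
#' @param pathway an `implant_pathway`. @param image_id image identifier.
#' @param path destination file.
#' @export
write_pathway_json <- function(pathway, image_id, path) {
  write_json6(list(
    image = image_id,
    line = list(A = pathway$line$A, B = pathway$line$B, C = pathway$line$C),
    angle_deg = pathway$angle_deg,
    entry = as.numeric(pathway$entry_point),
    segment = unname(lapply(seq_len(2), function(i) as.numeric(pathway$segment[i, ])))
  ), path)
}

#' Read a pathway JSON written by [write_pathway_json()]
#' @param path JSON file.
#' @return List with fields `image`, `line` (`ipath_line`), `angle_deg`,
#'   `entry`, `segment` (2 x 2 matrix).
#' @export
read_pathway_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(image = x$image,
       line = ipath_line(x$line$A, x$line$B, x$line$C),
       angle_deg = x$angle_deg,
       entry = as.numeric(x$entry),
       segment = if (is.matrix(x$segment)) x$segment
                 else matrix(unlist(x$segment), 2, 2, byrow = TRUE))
}

#' Read / write ground-truth pathway endpoints
#'
#' Dentist-annotated reference pathways are stored as two endpoints per image
#' in a JSON sidecar: `{"<image>": [[x1, y1], [x2, y2]], ...}` (pixel units).
#'
#' @param path JSON file.
#' @return Named list of 2 x 2 endpoint matrices.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(m) matrix(unlist(m), 2, 2, byrow = is.null(dim(m))))
}

#' @rdname read_truth_json
#' @param truth named list of 2 x 2 endpoint matrices (rows = points).
#' @export
write_truth_json <- function(truth, path) {
  write_json6(lapply(truth, function(m)
    unname(lapply(seq_len(2), function(i) as.numeric(m[i, ])))), path)
}
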