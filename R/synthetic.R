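# Synthetic panoramic-like fixtures: two bright tooth-shaped objects flanking
# a darker gap on a noisy low-contrast background, with exact box labels and
# an analytic ground-truth pathway.  Enough structure for OBB fitting and
# enhancement testing — not an anatomical simulation.

#' Specification of a synthetic two-tooth scene
#'
#' Defaults emulate a low-contrast radiograph crop: background level 60,
#' tooth level 160 with ±10% per-tooth contrast jitter, additive Gaussian
#' noise (sd 8), two 36 x 120 px teeth flanking a 40 px gap at the image
#' center.  `theta` gives the two tooth long-axis angles in degrees (from the
#' +x axis, so a vertical tooth is 90); the stored `oriented_box` rotation is
#' `theta - 90` accordingly.
#'
#' @param image_size `c(width, height)` pixels.
#' @param theta `c(left, right)` tooth box angles, degrees in `[0, 180)`.
#' @param tooth_length,tooth_width,gap_width pixels.
#' @param background,foreground intensity levels in `[0, 255]`.
#' @param contrast_jitter relative per-tooth intensity jitter (fraction).
#' @param noise_sd additive Gaussian noise standard deviation, gray levels.
#' @param seed integer RNG seed.
#' @return Object of class `scene_spec` (includes the two `oriented_box`es).
#' @export
scene_spec <- function(image_size = c(256, 256), theta = c(95, 85),
                       tooth_length = 120, tooth_width = 36, gap_width = 40,
                       background = 60, foreground = 160,
                       contrast_jitter = 0.10, noise_sd = 8, seed = 1L) {
  stopifnot(gap_width > 0, tooth_length > 0, tooth_width > 0,
            all(theta >= 0), all(theta < 180), noise_sd >= 0)
  cx0 <- (image_size[1] - 1) / 2
  cy0 <- (image_size[2] - 1) / 2
  off <- gap_width / 2 + tooth_width / 2
  boxes <- list(oriented_box(cx0 - off, cy0, tooth_width, tooth_length,
                             (theta[1] - 90) %% 180),
                oriented_box(cx0 + off, cy0, tooth_width, tooth_length,
                             (theta[2] - 90) %% 180))
  inter <- convex_clip(obb_corners(boxes[[1]]), obb_corners(boxes[[2]]))
  if (polygon_area(inter) > 1e-9)
    stop("invalid scene: tooth boxes overlap at these angles", call. = FALSE)
  structure(list(image_size = image_size, theta = theta,
                 tooth_length = tooth_length, tooth_width = tooth_width,
                 gap_width = gap_width, background = background,
                 foreground = foreground, contrast_jitter = contrast_jitter,
                 noise_sd = noise_sd, seed = as.integer(seed), boxes = boxes),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene spec> %dx%d px, teeth at %.1f / %.1f deg, gap %g px, noise sd %g\n",
              x$image_size[1], x$image_size[2], x$theta[1], x$theta[2],
              x$gap_width, x$noise_sd))
  invisible(x)
}

# rounded, mildly root-tapered tooth silhouette in box-local coordinates
.tooth_mask <- function(X, Y, box, taper = 0.25) {
  dx <- X - box$cx; dy <- Y - box$cy
  t <- .deg2rad(box$theta)
  u <- cos(t) * dx + sin(t) * dy      # across the width
  v <- -sin(t) * dx + cos(t) * dy     # along the length
  hl <- box$h / 2
  hw <- (box$w / 2) * (1 - taper * pmax(0, v / hl))   # taper towards the root
  rr <- 0.25 * box$w
  du <- pmax(abs(u) - (hw - rr), 0)
  dv <- pmax(abs(v) - (hl - rr), 0)
  (du * du + dv * dv) <= rr * rr
}

#' Generate one synthetic scene
#'
#' Deterministic given the spec's seed.  The emitted OBB labels are the exact
#' rectangles the teeth were rendered into; the emitted pathway is the
#' internal bisector of the spec's gap-facing edge lines.
#'
#' @param spec a `scene_spec`.
#' @return List: `image` (integer matrix), `annotations` (`annotation_set`,
#'   class 0 tooth boxes), `truth` (`implant_pathway`), `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$image_size[1]; H <- spec$image_size[2]
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  img <- with_seed(spec$seed, {
    m <- matrix(spec$background, H, W)
    for (b in spec$boxes) {
      lvl <- spec$foreground *
        (1 + stats::runif(1, -spec$contrast_jitter, spec$contrast_jitter))
      m[.tooth_mask(X, Y, b)] <- lvl
    }
    if (spec$noise_sd > 0)
      m <- m + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    m
  })
  img <- clip8(img)
  records <- lapply(spec$boxes, function(b) {
    corners <- obb_corners(b)
    corners[, 1] <- corners[, 1] / W
    corners[, 2] <- corners[, 2] / H
    list(class_id = 0L, corners = corners, box = b, confidence = NA_real_)
  })
  truth <- derive_pathway(tooth_pair(spec$boxes[[1]], spec$boxes[[2]]))
  list(image = img,
       annotations = annotation_set("scene", records),
       truth = truth,
       spec = spec)
}

#' Generate a batch of synthetic scenes on disk
#'
#' Writes `scene_###.png` and matching `scene_###.txt` OBB labels, a
#' `truth.json` sidecar of ground-truth pathway endpoints, and a
#' `manifest.json` recording the configuration, all per-scene seeds and the
#' analytic truth angles.  Tooth angles are sampled uniformly from
#' `angle_range`, resampling the rare overlapping draw.
#'
#' @param n number of scenes (>= 1).
#' @param out_dir output directory (created).
#' @param angle_range `c(min, max)` degrees for both tooth angles.
#' @param noise_sd Gaussian noise sd, gray levels.
#' @param seed master seed; per-scene seeds are derived from it.
#' @param image_size `c(width, height)` pixels.
#' @return Invisibly, the manifest as a list.
#' @export
generate_batch <- function(n, out_dir, angle_range = c(75, 105),
                           noise_sd = 8, seed = 1L,
                           image_size = c(256, 256)) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- with_seed(seed, list(
    seeds = sample.int(2^30, n),
    th1 = stats::runif(n, angle_range[1], angle_range[2]),
    th2 = stats::runif(n, angle_range[1], angle_range[2]),
    spare = matrix(stats::runif(2 * n * 20, angle_range[1], angle_range[2]),
                   ncol = 2)
  ))
  scenes <- vector("list", n)
  truth <- list()
  spare_i <- 1L
  for (i in seq_len(n)) {
    th <- c(draws$th1[i], draws$th2[i])
    spec <- NULL
    repeat {
      spec <- tryCatch(scene_spec(image_size = image_size, theta = th,
                                  noise_sd = noise_sd, seed = draws$seeds[i]),
                       error = function(e) NULL)
      if (!is.null(spec)) break
      th <- draws$spare[spare_i, ]; spare_i <- spare_i + 1L
    }
    sc <- generate_scene(spec)
    id <- sprintf("scene_%03d", i)
    write_gray_image(sc$image, file.path(out_dir, paste0(id, ".png")))
    write_obb_labels(sc$annotations, file.path(out_dir, paste0(id, ".txt")),
                     image_size = image_size)
    truth[[id]] <- sc$truth$segment
    scenes[[i]] <- list(id = id, seed = draws$seeds[i],
                        theta = as.numeric(spec$theta),
                        truth_angle_deg = sc$truth$angle_deg)
  }
  write_truth_json(truth, file.path(out_dir, "truth.json"))
  manifest <- list(n = n, seed = seed, angle_range = angle_range,
                   noise_sd = noise_sd, image_size = image_size,
                   scenes = scenes)
  write_json6(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Re-estimate tooth boxes from a rendered scene image
#'
#' Thresholds the image midway between its extreme intensities, labels
#' connected components, keeps the two largest, and fits each a minimum-area
#' rectangle.  Fitted extents are widened by 1 px to account for the pixel
#' footprint (pixel centers under-span the rendered rectangle by about one
#' pixel).
#'
#' @param img integer grayscale matrix.
#' @param threshold intensity cut; default `(min + max) / 2`.
#' @param min_pixels ignore components smaller than this (noise specks).
#' @return List of two `oriented_box`es ordered by center x.
#' @export
fit_boxes_from_image <- function(img, threshold = NULL, min_pixels = 50) {
  assert_gray(img)
  if (is.null(threshold)) threshold <- (min(img) + max(img)) / 2
  bin <- matrix(as.numeric(img > threshold), nrow(img), ncol(img))
  lab <- EBImage::bwlabel(bin)
  sizes <- table(lab[lab > 0])
  sizes <- sizes[sizes >= min_pixels]
  if (length(sizes) < 2)
    stop("could not find two tooth components above the threshold", call. = FALSE)
  keep <- as.integer(names(sort(sizes, decreasing = TRUE)[1:2]))
  boxes <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    b <- min_area_rect(pts)
    oriented_box(b$cx, b$cy, b$w + 1, b$h + 1, b$theta)
  })
  boxes[order(vapply(boxes, `[[`, numeric(1), "cx"))]
}
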