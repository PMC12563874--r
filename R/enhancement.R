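# Gray images are integer matrices with values in [0, 255]; row i, column j
# holds the pixel at (x = j - 1, y = i - 1).

assert_gray <- function(img) {
  stopifnot(is.matrix(img), nrow(img) >= 1, ncol(img) >= 1)
  if (any(img < 0 | img > 255) || any(!is.finite(img)))
    stop("gray image values must be finite and within [0, 255]", call. = FALSE)
  invisible(img)
}

# round-half-up then clip to [0, 255]; fixed so outputs are bit-reproducible
clip8 <- function(x) {
  x <- floor(x + 0.5)
  x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

# symmetric (mirror-with-edge-repeat) padding by r pixels on every side
pad_reflect <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(r < h + 1, r < w + 1)
  ri <- c(rev(seq_len(min(r, h))), seq_len(h), h + 1 - seq_len(min(r, h)))
  ci <- c(rev(seq_len(min(r, w))), seq_len(w), w + 1 - seq_len(min(r, w)))
  img[ri, ci, drop = FALSE]
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the normalized double-Gaussian weighted mean of its
#' window: a spatial kernel (sigma_spatial, pixels) times an intensity
#' similarity kernel (sigma_range, gray levels).  Smooths noise while
#' preserving edges — unlike a plain Gaussian blur, neighbours on the far
#' side of an intensity edge receive almost no weight.  The window radius is
#' `ceiling(3 * sigma_spatial)` (capped at the image size), which captures
#' over 99% of the spatial kernel mass; boundaries are reflect-padded.
#'
#' @param img integer matrix in `[0, 255]`.
#' @param sigma_spatial spatial standard deviation, pixels, `> 0` (default 3).
#' @param sigma_range intensity standard deviation, gray levels, `> 0`
#'   (default 30).  A very large value reduces the filter to a Gaussian blur.
#' @return Filtered image, same dimensions, integer `[0, 255]`.
#' @export
bilateral_filter <- function(img, sigma_spatial = 3, sigma_range = 30) {
  assert_gray(img)
  if (!is.finite(sigma_spatial) || sigma_spatial <= 0 ||
      !is.finite(sigma_range) || sigma_range <= 0)
    stop("sigma_spatial and sigma_range must be positive", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  r <- min(as.integer(ceiling(3 * sigma_spatial)), h, w)
  pad <- pad_reflect(img, r)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  inv2ss <- 1 / (2 * sigma_spatial^2)
  inv2sr <- 1 / (2 * sigma_range^2)
  center <- pad[r + seq_len(h), r + seq_len(w), drop = FALSE]
  for (dy in -r:r) {
    for (dx in -r:r) {
      shifted <- pad[r + dy + seq_len(h), r + dx + seq_len(w), drop = FALSE]
      wgt <- exp(-(dx * dx + dy * dy) * inv2ss -
                  (shifted - center)^2 * inv2sr)
      num <- num + wgt * shifted
      den <- den + wgt
    }
  }
  clip8(num / den)
}

#' Global histogram equalization
#'
#' Monotone intensity remapping through the cumulative distribution function:
#' level `r_k` maps to `(L - 1) * sum_{j<=k} p(r_j)` with `L = 256` gray
#' levels, rounded half-up.  Flattens the gray-level histogram, boosting
#' contrast in images with concentrated intensity distributions.
#'
#' @param img integer matrix in `[0, 255]`.
#' @param return_mapping also return the 256-entry level mapping.
#' @return Equalized image, or `list(image, mapping)` if `return_mapping`.
#' @export
hist_equalize <- function(img, return_mapping = FALSE) {
  assert_gray(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  p <- counts / length(img)
  s <- clip8(255 * cumsum(p))
  out <- matrix(s[as.integer(img) + 1L], nrow(img), ncol(img))
  storage.mode(out) <- "integer"
  if (return_mapping) list(image = out, mapping = s) else out
}

#' Per-pixel weighted compositing of two images (HE : BF)
#'
#' `round(ratio_he * a + (1 - ratio_he) * b)` per pixel.  The default ratio
#' 0.3 corresponds to the 3:7 HE:BF composite.
#'
#' @param img_he,img_bf images of equal dimensions.
#' @param ratio_he weight of the first image, in `[0, 1]`.
#' @return Composite image.
#' @export
blend_images <- function(img_he, img_bf, ratio_he = 0.3) {
  assert_gray(img_he); assert_gray(img_bf)
  if (!identical(dim(img_he), dim(img_bf)))
    stop("dimension mismatch between images", call. = FALSE)
  if (!is.finite(ratio_he) || ratio_he < 0 || ratio_he > 1)
    stop("ratio_he must lie in [0, 1]", call. = FALSE)
  if (ratio_he == 1) return(clip8(img_he))
  if (ratio_he == 0) return(clip8(img_bf))
  clip8(ratio_he * img_he + (1 - ratio_he) * img_bf)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Photometric augmentation: brightness, exposure, Gaussian noise
#'
#' Emulates variation in acquisition conditions.  Brightness is a
#' multiplicative scale `1 + pct/100` (range -25..+25); exposure is a
#' gamma-style power transform with exponent `1 - pct/100` on the normalized
#' intensity (range -15..+15, positive = brighter midtones); noise adds
#' zero-mean Gaussian noise with standard deviation `|pct|% of 255`
#' (range -15..+15).  Deterministic given `seed`.
#'
#' @param img integer matrix in `[0, 255]`.
#' @param brightness_pct,exposure_pct,noise_pct percentages within the stated
#'   ranges.
#' @param seed integer RNG seed for the noise draw.
#' @return Augmented image, same dimensions, integer `[0, 255]`.
#' @export
augment_image <- function(img, brightness_pct = 0, exposure_pct = 0,
                          noise_pct = 0, seed = 1L) {
  assert_gray(img)
  if (abs(brightness_pct) > 25)
    stop("brightness_pct out of range [-25, 25]", call. = FALSE)
  if (abs(exposure_pct) > 15)
    stop("exposure_pct out of range [-15, 15]", call. = FALSE)
  if (abs(noise_pct) > 15)
    stop("noise_pct out of range [-15, 15]", call. = FALSE)
  x <- img * (1 + brightness_pct / 100)
  if (exposure_pct != 0) {
    gamma <- 1 - exposure_pct / 100
    x <- 255 * pmin(pmax(x / 255, 0), 1)^gamma
  }
  if (noise_pct != 0) {
    sd_noise <- abs(noise_pct) / 100 * 255
    noise <- with_seed(seed, stats::rnorm(length(x), 0, sd_noise))
    x <- x + matrix(noise, nrow(x), ncol(x))
  }
  clip8(x)
}

#' Augment a directory of images, doubling the dataset
#'
#' Copies every grayscale image in `in_dir` to `out_dir` and writes one
#' augmented variant per image with parameters drawn uniformly from the
#' stated ranges, so the output holds exactly twice as many images.
#' Deterministic given `seed`.
#'
#' @param in_dir,out_dir directories; `out_dir` is created.
#' @param seed integer seed.
#' @param brightness_range,exposure_range,noise_range sampling ranges (pct).
#' @return Invisibly, the vector of files written.
#' @export
augment_dataset <- function(in_dir, out_dir, seed = 1L,
                            brightness_range = c(-25, 25),
                            exposure_range = c(-15, 15),
                            noise_range = c(-15, 15)) {
  files <- list.files(in_dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  params <- with_seed(seed, {
    n <- length(files)
    data.frame(b = stats::runif(n, brightness_range[1], brightness_range[2]),
               e = stats::runif(n, exposure_range[1], exposure_range[2]),
               s = stats::runif(n, noise_range[1], noise_range[2]),
               seed = sample.int(.Machine$integer.max - 1L, n))
  })
  for (i in seq_along(files)) {
    img <- read_gray_image(files[i])
    base <- tools::file_path_sans_ext(basename(files[i]))
    orig <- file.path(out_dir, paste0(base, ".png"))
    aug <- file.path(out_dir, paste0(base, "_aug.png"))
    write_gray_image(img, orig)
    write_gray_image(augment_image(img, params$b[i], params$e[i], params$s[i],
                                   seed = params$seed[i]), aug)
    written <- c(written, orig, aug)
  }
  invisible(written)
}
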