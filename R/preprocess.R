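# Image preprocessing: bicubic rescaling built on the cubic-convolution
# interpolation kernel, stochastic photometric/geometric augmentation, and the
# 6:2:2 train/validation/test split.

#' Cubic-convolution interpolation kernel
#'
#' The piecewise-cubic weight function used by bicubic resampling:
#' \deqn{W(x) = (a+2)|x|^3 - (a+3)|x|^2 + 1 \quad (|x| \le 1)}
#' \deqn{W(x) = a|x|^3 - 5a|x|^2 + 8a|x| - 4a \quad (1 < |x| < 2)}
#' and 0 otherwise. With the default sharpness constant `a = -0.5` (the Keys
#' kernel) the weights of the four neighbours at any fractional offset sum to
#' one, so constant images are reproduced exactly.
#'
#' @param x Numeric vector of signed offsets from the sample position.
#' @param a Kernel sharpness constant; `-0.5` (default) or `1` are the usual
#'   choices.
#' @return Numeric vector of interpolation weights.
#' @export
bicubic_weight <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(ax))
  i1 <- ax <= 1
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  i2 <- ax > 1 & ax < 2
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

#' Resize an image by bicubic interpolation
#'
#' Each output pixel is the double sum over its 4 x 4 source neighbourhood of
#' source values weighted by the separable cubic-convolution kernel. Source
#' positions use half-pixel centers (so resizing to the same size is the
#' identity), out-of-grid neighbours are clamped to the edge, channels are
#' processed independently, and the result is clamped to `[0, 255]`.
#'
#' @param image `H x W x C` numeric array (or `H x W` matrix), values on the
#'   0-255 scale; `H, W >= 4`.
#' @param target Integer vector `c(H, W)` of the output size.
#' @param a Kernel sharpness constant, see [bicubic_weight()].
#' @return Resized array (or matrix) with the requested spatial size.
#' @export
resize_bicubic <- function(image, target = c(224L, 224L), a = -0.5) {
  d <- dim(image)
  was_matrix <- length(d) == 2L
  if (was_matrix) { image <- array(image, c(d, 1L)); d <- dim(image) }
  if (length(d) != 3L) stop("image must be an H x W x C array")
  if (d[1] < 4 || d[2] < 4)
    stop("degenerate input: bicubic resampling needs H and W of at least 4")
  out <- .resize_bicubic_cpp(as.numeric(image), d[1], d[2], d[3],
                             as.integer(target[1]), as.integer(target[2]),
                             a, 0, 255)
  if (was_matrix) out <- out[, , 1]
  out
}

#' Augmentation configuration
#'
#' @param brightness_max_frac Maximum fractional brightness jitter; pixels are
#'   multiplied by a factor drawn uniformly from `1 +/- brightness_max_frac`
#'   (default 0.15, i.e. up to 15 percent).
#' @param contrast_max_frac Maximum fractional contrast jitter; per channel,
#'   `(p - mean) * c + mean` with `c` drawn uniformly from
#'   `1 +/- contrast_max_frac` (default 0.10).
#' @param hflip,vflip Allow random horizontal / vertical flips (probability
#'   1/2 each when allowed).
#' @param rotation_set Degrees to draw the random rotation from; restricted to
#'   multiples of 90 so no interpolation or border fill is involved.
#' @return An `augment_config` list.
#' @export
augment_config <- function(brightness_max_frac = 0.15,
                           contrast_max_frac = 0.10,
                           hflip = TRUE, vflip = TRUE,
                           rotation_set = c(0, 90, 180, 270)) {
  stopifnot(brightness_max_frac >= 0, brightness_max_frac <= 1,
            contrast_max_frac >= 0, contrast_max_frac <= 1,
            all(rotation_set %% 90 == 0))
  structure(list(brightness_max_frac = brightness_max_frac,
                 contrast_max_frac = contrast_max_frac,
                 hflip = hflip, vflip = vflip,
                 rotation_set = rotation_set),
            class = "augment_config")
}

rot90k <- function(img, k) {
  k <- ((k %% 360) / 90) %% 4
  if (k == 0) return(img)
  for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))
    img <- img[dim(img)[1]:1, , , drop = FALSE]
  }
  img
}

#' Apply stochastic photometric and geometric augmentation
#'
#' Draws a brightness factor, a contrast factor, flip indicators and a
#' rotation from the caller's RNG stream (seed before calling for
#' reproducibility), applies them in the order brightness, contrast, flips,
#' rotation, and clamps to `[0, 255]`. With zeroed magnitudes, flips disabled
#' and rotation set `{0}`, the output equals the input.
#'
#' @param image `H x W x 3` numeric array in `[0, 255]`.
#' @param cfg An [augment_config()].
#' @param draws Optional list forcing the random draws (fields
#'   `brightness_factor`, `contrast_factor`, `hflip`, `vflip`, `rotation`);
#'   used for deterministic checks.
#' @return Augmented image array, same shape as the input.
#' @export
augment_image <- function(image, cfg = augment_config(), draws = NULL) {
  b <- draws$brightness_factor %||%
    runif(1, 1 - cfg$brightness_max_frac, 1 + cfg$brightness_max_frac)
  cc <- draws$contrast_factor %||%
    runif(1, 1 - cfg$contrast_max_frac, 1 + cfg$contrast_max_frac)
  hf <- draws$hflip %||% (cfg$hflip && runif(1) < 0.5)
  vf <- draws$vflip %||% (cfg$vflip && runif(1) < 0.5)
  rot <- draws$rotation %||%
    cfg$rotation_set[sample.int(length(cfg$rotation_set), 1)]
  image <- image * b
  for (ch in seq_len(dim(image)[3])) {
    m <- mean(image[, , ch])
    image[, , ch] <- (image[, , ch] - m) * cc + m
  }
  if (hf) image <- image[, dim(image)[2]:1, , drop = FALSE]
  if (vf) image <- image[dim(image)[1]:1, , , drop = FALSE]
  image <- rot90k(image, rot)
  image[image < 0] <- 0
  image[image > 255] <- 255
  image
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign train/validation/test splits to a manifest
#'
#' Records are globally permuted with a seeded RNG and cut into contiguous
#' train/val/test groups whose sizes follow largest-remainder rounding of
#' `N * ratios` (ties broken in train, val, test order), so 2655 records at
#' 6:2:2 yield exactly 1593/531/531. The split is global, not class-stratified.
#'
#' @param manifest A `dataset_manifest` with all records unassigned.
#' @param ratios Numeric vector `c(train, val, test)` summing to 1.
#' @param seed Integer seed for the permutation.
#' @return The manifest with `split` filled in.
#' @export
split_manifest <- function(manifest, ratios = c(train = 0.6, val = 0.2, test = 0.2),
                           seed = 0L) {
  if (abs(sum(ratios) - 1) > 1e-8 || any(ratios < 0))
    stop("split ratios must be nonnegative and sum to 1")
  if (!all(manifest$split == "unassigned"))
    stop("manifest already has split assignments")
  n <- nrow(manifest)
  sizes <- largest_remainder(n, ratios)
  perm <- with_seed(seed, sample.int(n))
  lab <- rep(c("train", "val", "test"), times = sizes)
  manifest$split[perm] <- lab
  manifest
}

largest_remainder <- function(n, ratios) {
  raw <- n * ratios / sum(ratios)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    pick <- order(-(raw - base), seq_along(raw))[seq_len(left)]
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}

#' Load manifest images as a batch matrix for the network
#'
#' Reads each image, resizes it to `size x size` with [resize_bicubic()], and
#' stacks the result into the flattened `(N * size * size) x 3` row-major
#' feature layout used by the network (one block of `size^2` consecutive rows
#' per image). Values stay on the 0-255 scale; normalization to the network's
#' input range happens at batch assembly time.
#'
#' @param manifest A `dataset_manifest` (or subset of one).
#' @param size Target side length in pixels.
#' @param a Bicubic kernel constant.
#' @return List with `x` (the stacked matrix), `y` (factor of stage labels)
#'   and `size`.
#' @export
load_images <- function(manifest, size = 224L, a = -0.5) {
  n <- nrow(manifest)
  hw <- as.integer(size)^2
  x <- matrix(0, n * hw, 3L)
  for (i in seq_len(n)) {
    img <- png::readPNG(manifest$path[i]) * 255
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    if (dim(img)[1] != size || dim(img)[2] != size)
      img <- resize_bicubic(img, c(size, size), a)
    x[((i - 1) * hw + 1):(i * hw), ] <- chw_rows(img)
  }
  list(x = x, y = factor(manifest$stage, levels = STAGES), size = as.integer(size))
}

# H x W x C array -> (H*W) x C matrix, row index (h-1)*W + w (w fastest).
chw_rows <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  m <- matrix(0, H * W, C)
  for (ch in seq_len(C)) m[, ch] <- as.numeric(t(img[, , ch]))
  m
}

rows_chw <- function(m, H, W) {
  C <- ncol(m)
  img <- array(0, c(H, W, C))
  for (ch in seq_len(C)) img[, , ch] <- t(matrix(m[, ch], W, H))
  img
}
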