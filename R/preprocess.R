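# Image augmentation (lossless flips / quarter-turn rotations used to
# balance class counts) and the two contrast-enhancement filters applied
# before feature extraction: a Laplacian-pyramid detail remap and a
# morphological top-hat/bottom-hat filter.

AUGMENT_OPS <- c("hflip", "vflip", "rot90", "rot180", "rot270")

#' Horizontal flip
#'
#' Reverses column order (mirror about the vertical axis); the pixel
#' multiset is preserved, and the operator is an involution.
#'
#' @param img An [as_image_grid()] image.
#' @return The flipped image.
#' @export
hflip <- function(img) {
  img <- as_image_grid(img)
  x <- unclass(img)
  out <- if (length(dim(x)) == 3) x[, ncol(x):1, , drop = FALSE] else x[, ncol(x):1, drop = FALSE]
  as_image_grid(out)
}

#' Vertical flip
#'
#' Reverses row order (mirror about the horizontal axis, i.e. flip along
#' the X-axis). Involution; `vflip(hflip(img))` equals a 180-degree turn.
#'
#' @inheritParams hflip
#' @return The flipped image.
#' @export
vflip <- function(img) {
  img <- as_image_grid(img)
  x <- unclass(img)
  out <- if (length(dim(x)) == 3) x[nrow(x):1, , , drop = FALSE] else x[nrow(x):1, , drop = FALSE]
  as_image_grid(out)
}

#' Quarter-turn rotation
#'
#' Rotates counterclockwise about the image center by `quarter_turns` x 90
#' degrees. Only multiples of 90 degrees are supported: these are lossless
#' pixel permutations (the intensity histogram is exactly preserved),
#' which is what the augmentation plan relies on.
#'
#' @inheritParams hflip
#' @param quarter_turns 1, 2 or 3 counterclockwise quarter turns.
#' @return The rotated image; dimensions are swapped for odd turns.
#' @export
rotate90 <- function(img, quarter_turns = 1L) {
  img <- as_image_grid(img)
  if (!quarter_turns %in% 1:3) stopf("`quarter_turns` must be 1, 2 or 3")
  x <- unclass(img)
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]  # one CCW turn
  apply_rot <- function(m) { for (i in seq_len(quarter_turns)) m <- rot1(m); m }
  if (length(dim(x)) == 3) {
    chans <- lapply(1:3, function(c) apply_rot(x[, , c]))
    out <- array(unlist(chans), dim = c(dim(chans[[1]]), 3))
  } else {
    out <- apply_rot(x)
  }
  as_image_grid(out)
}

#' Augmentation plan
#'
#' Configuration for topping a class up to a target image count by applying
#' randomly chosen lossless operators to randomly chosen source images.
#'
#' @param target_count_per_class Desired number of images after augmentation.
#' @param ops Character vector drawn from
#'   `c("hflip","vflip","rot90","rot180","rot270")`.
#' @param seed Integer seed controlling the op/source draws.
#' @return An `augment_plan` object.
#' @export
augment_plan <- function(target_count_per_class, ops = AUGMENT_OPS, seed = 1L) {
  target_count_per_class <- assert_scalar_int(target_count_per_class,
                                              "target_count_per_class", min = 1)
  ops <- match.arg(ops, AUGMENT_OPS, several.ok = TRUE)
  structure(list(target_count_per_class = target_count_per_class,
                 ops = ops, seed = as.integer(seed)),
            class = "augment_plan")
}

#' @noRd
apply_augment_op <- function(img, op) {
  switch(op,
         hflip = hflip(img),
         vflip = vflip(img),
         rot90 = rotate90(img, 1L),
         rot180 = rotate90(img, 2L),
         rot270 = rotate90(img, 3L),
         stopf("unknown op `%s`", op))
}

#' Augment a class to a target count
#'
#' Keeps all originals and appends seeded random (op, source image) draws
#' until the target count is reached; this is how minority classes (e.g. a
#' 64-image class grown to 3,200) are brought to parity.
#'
#' @param images Non-empty list of [as_image_grid()] images.
#' @param plan An [augment_plan()].
#' @return List of images of length `plan$target_count_per_class`,
#'   originals first. Deterministic under the plan seed.
#' @export
augment_to_count <- function(images, plan) {
  if (!inherits(plan, "augment_plan")) stopf("`plan` must be an augment_plan")
  if (!is.list(images) || length(images) == 0) stopf("`images` must be non-empty")
  n0 <- length(images)
  target <- plan$target_count_per_class
  if (target < n0) stopf("target (%d) below existing count (%d)", target, n0)
  if (target == n0) return(images)
  extra <- with_seed_or_stream(plan$seed, {
    src <- sample.int(n0, target - n0, replace = TRUE)
    op <- sample(plan$ops, target - n0, replace = TRUE)
    mapply(function(s, o) apply_augment_op(images[[s]], o),
           src, op, SIMPLIFY = FALSE)
  })
  c(images, extra)
}

#' Top-hat / bottom-hat contrast enhancement
#'
#' Adds small bright structures (top-hat: image minus its opening) and
#' subtracts small dark structures (bottom-hat: closing minus image) with a
#' disc structuring element, then clips to `[0,1]`:
#' `clip(I + tophat(I) - bottomhat(I))`. Constant images are fixed points.
#' RGB images are enhanced channel-wise.
#'
#' @inheritParams hflip
#' @param selem_radius Disc structuring-element radius in pixels (>= 1);
#'   default 5.
#' @return The enhanced image.
#' @export
tophat_bottomhat_enhance <- function(img, selem_radius = 5L) {
  img <- as_image_grid(img)
  selem_radius <- assert_scalar_int(selem_radius, "selem_radius", min = 1)
  kern <- EBImage::makeBrush(2L * selem_radius + 1L, shape = "disc")
  enhance1 <- function(m) {
    op <- as.matrix(EBImage::opening(m, kern))
    cl <- as.matrix(EBImage::closing(m, kern))
    clip01(m + (m - op) - (cl - m))
  }
  x <- unclass(img)
  if (length(dim(x)) == 3) {
    out <- array(0, dim(x))
    for (c in 1:3) out[, , c] <- enhance1(x[, , c])
  } else {
    out <- enhance1(x)
  }
  as_image_grid(out)
}

# --- Laplacian-pyramid detail enhancement -------------------------------

# Separable binomial [1 4 6 4 1]/16 blur with reflective padding.
#' @noRd
binomial_blur <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  conv_rows <- function(a) {
    n <- nrow(a)
    idx <- function(off) pmin(pmax(seq_len(n) + off, 1L), n)
    out <- 0
    for (o in -2:2) out <- out + k[o + 3] * a[idx(o), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' @noRd
downsample2 <- function(m) m[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]

# Nearest-neighbour upsample to an explicit target size; reconstruction is
# exact because build and reconstruct use the same operator.
#' @noRd
upsample_to <- function(m, h, w) {
  ri <- pmin(ceiling(seq_len(h) / 2), nrow(m))
  ci <- pmin(ceiling(seq_len(w) / 2), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' @noRd
laplacian_remap_gray <- function(m, levels, sigma, alpha) {
  gp <- vector("list", levels)
  gp[[1]] <- m
  for (l in 2:levels) gp[[l]] <- downsample2(binomial_blur(gp[[l - 1]]))
  lap <- vector("list", levels - 1)
  for (l in seq_len(levels - 1)) {
    up <- upsample_to(gp[[l + 1]], nrow(gp[[l]]), ncol(gp[[l]]))
    c0 <- gp[[l]] - up
    boost <- ifelse(abs(c0) < sigma, alpha, 1)
    lap[[l]] <- c0 * boost
  }
  rec <- gp[[levels]]
  for (l in rev(seq_len(levels - 1))) {
    rec <- upsample_to(rec, nrow(gp[[l]]), ncol(gp[[l]])) + lap[[l]]
  }
  rec
}

#' Laplacian-pyramid local detail enhancement
#'
#' Edge-aware detail boost in the spirit of local Laplacian filtering,
#' simplified to a fixed-depth pyramid detail remap: band-pass coefficients
#' `c` with `|c| < sigma` are scaled by `alpha` (a boost for `alpha > 1`),
#' the pyramid is reconstructed and the result clipped to `[0,1]`. With
#' `alpha = 1` the remap is the identity and reconstruction is exact. RGB
#' input is converted to YUV, only the luma channel is enhanced, and the
#' image is converted back.
#'
#' @inheritParams hflip
#' @param levels Pyramid depth (>= 2); default 3.
#' @param sigma Detail amplitude threshold (> 0), on the `[0,1]` intensity
#'   scale; default 0.1.
#' @param alpha Remap gain for small coefficients (> 0); default 2.
#' @return The enhanced image.
#' @export
local_laplacian_enhance <- function(img, levels = 3L, sigma = 0.1, alpha = 2) {
  img <- as_image_grid(img)
  levels <- assert_scalar_int(levels, "levels", min = 2)
  if (!(sigma > 0) || !(alpha > 0)) stopf("`sigma` and `alpha` must be > 0")
  x <- unclass(img)
  if (min(dim(x)[1:2]) < 2^levels)
    stopf("image must be at least %d px in each dimension", 2^levels)
  if (length(dim(x)) == 3) {
    # BT.601 luma/chroma; enhancement on luma only
    r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
    y <- 0.299 * r + 0.587 * g + 0.114 * b
    u <- -0.14713 * r - 0.28886 * g + 0.436 * b
    v <- 0.615 * r - 0.51499 * g - 0.10001 * b
    y2 <- laplacian_remap_gray(y, levels, sigma, alpha)
    out <- array(0, dim(x))
    out[, , 1] <- y2 + 1.13983 * v
    out[, , 2] <- y2 - 0.39465 * u - 0.58060 * v
    out[, , 3] <- y2 + 2.03211 * u
    out <- clip01(out)
  } else {
    out <- clip01(laplacian_remap_gray(x, levels, sigma, alpha))
  }
  as_image_grid(out)
}

#' Enhance an image with the full two-stage filter chain
#'
#' Applies the Laplacian-pyramid detail remap first and the
#' top-hat/bottom-hat morphological filter second.
#'
#' @inheritParams local_laplacian_enhance
#' @inheritParams tophat_bottomhat_enhance
#' @return The enhanced image.
#' @export
enhance_image <- function(img, levels = 3L, sigma = 0.1, alpha = 2,
                          selem_radius = 5L) {
  tophat_bottomhat_enhance(
    local_laplacian_enhance(img, levels = levels, sigma = sigma, alpha = alpha),
    selem_radius = selem_radius)
}

#' Read / write PNG images
#'
#' Thin wrappers around the `png` package that keep intensities in `[0,1]`
#' and return [as_image_grid()] objects. Images are written as 8-bit PNG.
#'
#' @param path File path.
#' @param img Image to write.
#' @return `read_image_png` returns an image grid; `write_image_png`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3]  # drop alpha
  if (length(dim(x)) == 3 && dim(x)[3] == 2) x <- x[, , 1]    # gray+alpha
  as_image_grid(x)
}

#' @rdname read_image_png
#' @export
write_image_png <- function(img, path) {
  img <- as_image_grid(img)
  png::writePNG(unclass(img), path)
  invisible(path)
}
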