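# Untrained ResNet-50 + self-attention feature extractor ("ResNet-Self").
# The backbone is the standard bottleneck architecture (stem 7x7/2 conv +
# 3x3/2 max-pool, stages of [3,4,6,3] residual bottleneck blocks with 1x1
# reduction filters and skip connections, channel widths 64..2048, global
# average pooling); convolutions are computed in base R via im2col and BLAS
# matrix products. Weights are He-initialized random draws and batch
# normalization at initialization is the identity, so no normalization
# layers are materialized. The network is never trained here: it serves as
# a fixed feature extractor honouring the N x 2,048 output contract, and
# downstream selection/classification operate on its (or any) feature
# matrix.

#' @noRd
he_weights <- function(kh, kw, cin, cout) {
  matrix(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
         kh * kw * cin, cout)
}

# x: H x W x C array; Wmat: (kh*kw*Cin) x Cout (im2col row order: kernel
# offset-major, channel-minor, matching the slab flattening below).
#' @noRd
conv2d <- function(x, Wmat, kh, kw, stride = 1L, pad = 0L) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  if (pad > 0) {
    xp <- array(0, c(H + 2 * pad, W + 2 * pad, Cin))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  Hout <- (H + 2 * pad - kh) %/% stride + 1L
  Wout <- (W + 2 * pad - kw) %/% stride + 1L
  r0 <- seq(1L, by = stride, length.out = Hout)
  c0 <- seq(1L, by = stride, length.out = Wout)
  cols <- matrix(0, Hout * Wout, kh * kw * Cin)
  for (p in seq_len(kh * kw)) {
    di <- (p - 1L) %% kh; dj <- (p - 1L) %/% kh
    slab <- xp[r0 + di, c0 + dj, , drop = FALSE]
    dim(slab) <- c(Hout * Wout, Cin)
    cols[, ((p - 1L) * Cin + 1L):(p * Cin)] <- slab
  }
  out <- cols %*% Wmat
  array(out, c(Hout, Wout, ncol(Wmat)))
}

#' @noRd
maxpool_3x3_s2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  pad <- 1L
  xp <- array(-Inf, c(H + 2L, W + 2L, Cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Hout <- (H + 2L - 3L) %/% 2L + 1L
  Wout <- (W + 2L - 3L) %/% 2L + 1L
  r0 <- seq(1L, by = 2L, length.out = Hout)
  c0 <- seq(1L, by = 2L, length.out = Wout)
  out <- array(-Inf, c(Hout, Wout, Cin))
  for (di in 0:2) for (dj in 0:2)
    out <- pmax(out, xp[r0 + di, c0 + dj, , drop = FALSE])
  out
}

#' @noRd
relu <- function(x) { x[x < 0] <- 0; x }

#' @noRd
make_bottleneck <- function(cin, cmid, cout, stride) {
  list(w1 = he_weights(1, 1, cin, cmid),
       w2 = he_weights(3, 3, cmid, cmid),
       w3 = he_weights(1, 1, cmid, cout),
       wproj = if (stride != 1L || cin != cout) he_weights(1, 1, cin, cout),
       stride = stride, cmid = cmid)
}

#' @noRd
forward_bottleneck <- function(x, blk) {
  h <- relu(conv2d(x, blk$w1, 1, 1))
  h <- relu(conv2d(h, blk$w2, 3, 3, stride = blk$stride, pad = 1L))
  h <- conv2d(h, blk$w3, 1, 1)
  sc <- if (is.null(blk$wproj)) x else conv2d(x, blk$wproj, 1, 1, stride = blk$stride)
  relu(h + sc)
}

#' Assemble the ResNet-Self feature extractor
#'
#' Builds an untrained ResNet-50 bottleneck backbone with a self-attention
#' head in place of the plain pooled output: global-average-pooled
#' activations (length 2,048) are flattened, standardized, and passed
#' through [attention_head()], yielding `feature_dim` attended features per
#' image. All weights are seeded He-initialized draws; no training is
#' performed, so the extractor is a fixed, deterministic map.
#'
#' @param attn_cfg An [attention_config()] with `input_dim = 2048`;
#'   defaults to the standard 2,048-feature head.
#' @param seed Seed for the backbone (and default head) weights.
#' @return A `resnet_self` model object usable with [extract_features()].
#' @examples
#' \donttest{
#' model <- build_resnet_self(seed = 1)
#' imgs <- replicate(2, array(runif(64 * 64 * 3), c(64, 64, 3)), simplify = FALSE)
#' dim(extract_features(model, imgs))  # 2 x 2048
#' }
#' @export
build_resnet_self <- function(attn_cfg = NULL, seed = 1L) {
  if (is.null(attn_cfg))
    attn_cfg <- attention_config(2048L, feature_dim = 2048L, seed = seed)
  if (attn_cfg$input_dim != 2048L)
    stopf("the backbone pools to 2048 channels; attn_cfg$input_dim must be 2048")
  backbone <- with_seed_or_stream(seed, {
    stage <- function(n, cin, cmid, cout, first_stride) {
      blks <- vector("list", n)
      blks[[1]] <- make_bottleneck(cin, cmid, cout, first_stride)
      for (b in seq_len(n - 1) + 1) blks[[b]] <- make_bottleneck(cout, cmid, cout, 1L)
      blks
    }
    list(stem = he_weights(7, 7, 3, 64),
         stages = list(stage(3, 64, 64, 256, 1L),
                       stage(4, 256, 128, 512, 2L),
                       stage(6, 512, 256, 1024, 2L),
                       stage(3, 1024, 512, 2048, 2L)))
  })
  structure(list(backbone = backbone, attn_cfg = attn_cfg),
            class = "resnet_self")
}

#' @noRd
forward_one <- function(model, img) {
  x <- unclass(img)
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3))  # gray -> 3 channels
  if (length(dim(x)) != 3 || dim(x)[3] != 3)
    stopf("each image must be H x W (gray) or H x W x 3")
  if (min(dim(x)[1:2]) < 32) stopf("images must be at least 32 x 32")
  h <- relu(conv2d(x, model$backbone$stem, 7, 7, stride = 2L, pad = 3L))
  h <- maxpool_3x3_s2(h)
  for (st in model$backbone$stages)
    for (blk in st) h <- forward_bottleneck(h, blk)
  pooled <- apply(h, 3, mean)                     # global average pooling
  z <- (pooled - mean(pooled)) / (stats::sd(pooled) + 1e-12)
  attention_head(z, model$attn_cfg)
}

#' Extract deep features for a batch of images
#'
#' Runs the forward pass of a [build_resnet_self()] model over a batch and
#' returns the `N x feature_dim` feature matrix (2,048 columns by default).
#' Images are processed in chunks of `batch_size` (default 128, the
#' extraction batch size used at full scale); results are independent of
#' the chunking.
#'
#' @param model A `resnet_self` model.
#' @param images List of images (`H x W` matrices or `H x W x 3` arrays,
#'   intensities in `[0,1]` or any finite range).
#' @param batch_size Chunk size for processing; default 128.
#' @return Numeric matrix `length(images) x feature_dim`.
#' @export
extract_features <- function(model, images, batch_size = 128L) {
  if (!inherits(model, "resnet_self")) stopf("`model` must come from build_resnet_self()")
  if (!is.list(images) || length(images) == 0) stopf("`images` must be a non-empty list")
  batch_size <- assert_scalar_int(batch_size, "batch_size", min = 1)
  n <- length(images)
  out <- matrix(0, n, model$attn_cfg$feature_dim)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    for (i in idx) out[i, ] <- forward_one(model, images[[i]])
  }
  out
}
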