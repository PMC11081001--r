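# Synthetic data: labeled feature matrices with planted informative
# features, and small phantom images. These stand in for the MRI-derived
# deep-feature tables so that selection, refinement and classification can
# be exercised and verified end-to-end on a desk machine.

#' Labeled feature matrix
#'
#' Container for an `N x d` numeric feature matrix with one integer class
#' label per row, the object that feature selection and classification act
#' on. Labels are coded `0..C-1`.
#'
#' @param values Numeric matrix, samples in rows.
#' @param labels Integer vector of class labels in `0..C-1`, length `nrow(values)`.
#' @param feature_ids Optional character vector of column identifiers.
#'
#' @return An object of class `feature_matrix` with elements `values`,
#'   `labels`, `feature_ids`.
#' @export
feature_matrix <- function(values, labels, feature_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stopf("`values` must be finite with no missing entries")
  if (ncol(values) < 1L) stopf("need at least one feature column")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stopf("`labels` length must match rows of `values`")
  classes <- sort(unique(labels))
  if (!identical(classes, seq_along(classes) - 1L))
    stopf("labels must cover 0..C-1 with every class present")
  if (nrow(values) < length(classes))
    stopf("need at least one sample per class")
  if (is.null(feature_ids)) feature_ids <- sprintf("f%04d", seq_len(ncol(values)))
  if (length(feature_ids) != ncol(values))
    stopf("`feature_ids` length must match columns")
  structure(list(values = values, labels = labels,
                 feature_ids = as.character(feature_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Generate Gaussian class data with planted informative features
#'
#' Draws a balanced `C`-class sample in which `d_informative` columns carry
#' class signal and the remaining columns are pure `N(0,1)` noise. The
#' informative columns are split into one block per class (column `j` is
#' owned by class `j mod C`) and the class mean vectors are the simplex
#' vertices `effect_size * u_c`, where `u_c` is the unit-norm indicator of
#' class `c`'s block: each owned column is shifted by
#' `effect_size / sqrt(block size)`. With blocks of equal size every pair
#' of class means is equally separated (at distance `effect_size * sqrt(2)`),
#' giving symmetric difficulty across the four dementia-stage stand-in
#' classes, and no single column is decisive on its own.
#'
#' @param n_per_class Samples per class (>= 2).
#' @param n_classes Number of classes `C` (>= 2).
#' @param d Total number of features.
#' @param d_informative Number of class-informative features (<= `d`).
#' @param effect_size Nonnegative mean separation; 0 yields pure noise.
#' @param seed Integer seed; the call is deterministic given the seed.
#'
#' @return A list with `data` (a [feature_matrix]) and `truth`, the planted
#'   ground truth: `informative_mask` (logical length `d`) and `effect_size`.
#' @examples
#' sim <- make_gaussian_feature_data(20, 4, 50, 10, effect_size = 3, seed = 1)
#' table(sim$data$labels)
#' sum(sim$truth$informative_mask)
#' @export
make_gaussian_feature_data <- function(n_per_class, n_classes = 4L, d,
                                       d_informative, effect_size, seed) {
  n_per_class <- assert_scalar_int(n_per_class, "n_per_class", min = 2)
  n_classes <- assert_scalar_int(n_classes, "n_classes", min = 2)
  d <- assert_scalar_int(d, "d", min = 1)
  d_informative <- assert_scalar_int(d_informative, "d_informative", min = 0)
  if (d_informative > d) stopf("`d_informative` must be <= `d`")
  if (!is.finite(effect_size) || effect_size < 0)
    stopf("`effect_size` must be a nonnegative number")
  if (effect_size > 0 && d_informative == 0)
    stopf("need at least one informative feature when effect_size > 0")

  n <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  mask <- c(rep(TRUE, d_informative), rep(FALSE, d - d_informative))

  values <- with_seed_or_stream(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    if (d_informative > 0 && effect_size > 0) {
      owner <- (seq_len(d_informative) - 1L) %% n_classes  # class owning column j
      block <- tabulate(owner + 1L, nbins = n_classes)     # block size per class
      for (j in seq_len(d_informative)) {
        rows <- labels == owner[j]
        x[rows, j] <- x[rows, j] + effect_size / sqrt(block[owner[j] + 1L])
      }
    }
    x
  })

  list(data = feature_matrix(values, labels),
       truth = list(informative_mask = mask, effect_size = effect_size))
}

#' Generate a phantom test image
#'
#' A deterministic image with a centered bright shape on a darker
#' background plus a single marker pixel in the top-left corner, so that
#' flips and rotations are detectable. Used as a fixture for the
#' augmentation and enhancement operators.
#'
#' @param h,w Image height and width in pixels (>= 1).
#' @param fg_level,bg_level Foreground/background intensities with
#'   `0 <= bg_level < fg_level <= 1`.
#' @param shape `"disc"` or `"square"`.
#' @param seed Accepted for interface uniformity; the phantom is
#'   deterministic and ignores it.
#'
#' @return An `image_grid`: an `h x w` numeric matrix in `[0,1]`,
#'   origin top-left, row-major.
#' @export
make_phantom_image <- function(h, w, fg_level = 1, bg_level = 0,
                               shape = c("disc", "square"), seed = NULL) {
  h <- assert_scalar_int(h, "h", min = 1)
  w <- assert_scalar_int(w, "w", min = 1)
  shape <- match.arg(shape)
  if (!(bg_level >= 0 && bg_level < fg_level && fg_level <= 1))
    stopf("need 0 <= bg_level < fg_level <= 1")

  img <- matrix(bg_level, h, w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- max(1, min(h, w) / 4)
  if (shape == "disc") {
    ix <- outer(seq_len(h), seq_len(w),
                function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
  } else {
    ix <- outer(seq_len(h), seq_len(w),
                function(i, j) abs(i - cy) <= r & abs(j - cx) <= r)
  }
  img[ix] <- fg_level
  img[1, 1] <- fg_level  # asymmetric corner marker
  as_image_grid(img)
}

#' Validate and tag an image grid
#'
#' @param x Numeric matrix (`H x W`) or array (`H x W x 3`) with finite
#'   values in `[0,1]`.
#' @return `x` with class `image_grid`.
#' @export
as_image_grid <- function(x) {
  if (!(is.matrix(x) || (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3)))
    stopf("an image must be an H x W matrix or H x W x 3 array")
  if (any(dim(x)[1:2] < 1)) stopf("image dimensions must be >= 1")
  if (anyNA(x) || any(!is.finite(x)) || min(x) < 0 || max(x) > 1)
    stopf("image intensities must be finite and within [0,1]")
  class(x) <- c("image_grid", class(unclass(x)))
  x
}

#' @noRd
strip_grid <- function(x) {
  cls <- class(unclass(x))
  y <- unclass(x)
  class(y) <- setdiff(cls, "image_grid")
  y
}
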