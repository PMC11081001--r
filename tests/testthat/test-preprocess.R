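test_that("flips are involutions and act as the axis definitions require", {
  row <- as_image_grid(matrix(c(0.1, 0.5, 0.9), 1, 3))
  expect_equal(unclass(hflip(row)), matrix(c(0.9, 0.5, 0.1), 1, 3), ignore_attr = TRUE)
  col <- as_image_grid(matrix(c(0.1, 0.5, 0.9), 3, 1))
  expect_equal(unclass(vflip(col)), matrix(c(0.9, 0.5, 0.1), 3, 1), ignore_attr = TRUE)

  for (rgb in c(FALSE, TRUE)) {
    img <- random_image(7, 5, rgb = rgb, seed = 11)
    expect_equal(unclass(hflip(hflip(img))), unclass(img))
    expect_equal(unclass(vflip(vflip(img))), unclass(img))
    # vflip o hflip = rot180, and the three ops commute pairwise
    expect_equal(unclass(vflip(hflip(img))), unclass(rotate90(img, 2)))
    expect_equal(unclass(hflip(vflip(img))), unclass(vflip(hflip(img))))
    expect_equal(unclass(rotate90(hflip(img), 2)), unclass(hflip(rotate90(img, 2))))
  }
})

test_that("quarter-turn rotation matches the coordinate map and preserves pixels", {
  m <- as_image_grid(matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2))  # [[a,b],[c,d]] row-wise
  # one CCW turn of [[a,b],[c,d]] is [[b,d],[a,c]]
  expect_equal(unclass(rotate90(m, 1)),
               matrix(c(0.2, 0.1, 0.4, 0.3), 2, 2), ignore_attr = TRUE)
  img <- random_image(6, 9, seed = 4)
  r <- rotate90(img, 1)
  expect_equal(dim(r), c(9, 6))                       # dims swap on odd turns
  expect_equal(sort(as.vector(unclass(r))), sort(as.vector(unclass(img))))
  four <- rotate90(rotate90(rotate90(rotate90(img, 1), 1), 1), 1)
  expect_equal(unclass(four), unclass(img))
  expect_equal(unclass(rotate90(rotate90(img, 1), 2)), unclass(rotate90(img, 3)))
  expect_error(rotate90(img, 4), "quarter_turns")
})

test_that("augmentation reaches the target count deterministically, originals first", {
  imgs <- lapply(1:64, function(i) make_phantom_image(8, 8, fg_level = i / 64))
  plan <- augment_plan(3200, seed = 5)
  out <- augment_to_count(imgs, plan)
  expect_length(out, 3200)                            # 64 originals grown to 3,200
  expect_identical(lapply(out[1:64], unclass), lapply(imgs, unclass))
  out2 <- augment_to_count(imgs, plan)
  expect_identical(lapply(out, unclass), lapply(out2, unclass))
  # histograms preserved by every augmentation op
  hists <- vapply(out, function(im) sum(unclass(im)), numeric(1))
  src_sums <- vapply(imgs, function(im) sum(unclass(im)), numeric(1))
  expect_true(all(hists %in% src_sums))
  expect_identical(augment_to_count(imgs, augment_plan(64)), imgs)
  expect_error(augment_to_count(list(), plan), "non-empty")
  expect_error(augment_plan(10, ops = "shear"), "arg")
})

test_that("top/bottom-hat enhancement fixes constants and lifts bright spots", {
  const <- as_image_grid(matrix(0.4, 16, 16))
  expect_equal(unclass(tophat_bottomhat_enhance(const, 3)), unclass(const),
               tolerance = 1e-12)
  spot <- matrix(0, 16, 16); spot[8, 8] <- 1
  spot <- as_image_grid(spot)
  out <- tophat_bottomhat_enhance(spot, 2)
  expect_gte(out[8, 8], spot[8, 8])
  img <- random_image(20, 20, seed = 2)
  enh <- tophat_bottomhat_enhance(img, 3)
  expect_true(min(enh) >= 0 && max(enh) <= 1)
})

test_that("Laplacian detail remap is exact at alpha = 1 and boosts edge contrast", {
  img <- random_image(32, 32, seed = 6)
  ident <- local_laplacian_enhance(img, levels = 3, sigma = 0.1, alpha = 1)
  expect_lt(max(abs(unclass(ident) - unclass(img))), 1e-6)

  const <- as_image_grid(matrix(0.7, 32, 32))
  expect_equal(unclass(local_laplacian_enhance(const, 3, 0.2, 3)), unclass(const),
               tolerance = 1e-9)

  # step edge: local contrast (2-px band mean difference) must not decrease
  step <- as_image_grid(matrix(rep(c(0.35, 0.65), each = 16), 32, 32, byrow = TRUE))
  enh <- local_laplacian_enhance(step, levels = 3, sigma = 0.2, alpha = 2)
  contrast <- function(m) mean(m[, 17:18]) - mean(m[, 15:16])
  expect_gte(contrast(unclass(enh)), contrast(unclass(step)) - 1e-12)

  expect_error(local_laplacian_enhance(random_image(6, 6), levels = 3), "at least")

  rgb <- random_image(32, 32, rgb = TRUE, seed = 8)
  out <- local_laplacian_enhance(rgb, 3, 0.1, 2)
  expect_equal(dim(out), dim(rgb))
  expect_true(min(out) >= 0 && max(out) <= 1)
})

test_that("PNG round trip preserves 8-bit image content", {
  img <- make_phantom_image(16, 12, fg_level = 0.8, bg_level = 0.2)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- read_image_png(path)
  expect_equal(unclass(back), unclass(img), tolerance = 1 / 255)
})
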