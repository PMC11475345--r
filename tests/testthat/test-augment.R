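no_aug <- augment_config(p_crop = 0, p_flip = 0, p_scale = 0,
                         p_hsv = 0, p_noise = 0)

# recover the tight box of a bright blob painted on a dark background
tight_white_box <- function(px, thr = 0.9) {
  m <- px[, , 1] > thr & px[, , 2] > thr & px[, , 3] > thr
  sel <- which(m, arr.ind = TRUE)
  c(min(sel[, 2]) - 1, min(sel[, 1]) - 1, max(sel[, 2]), max(sel[, 1]))
}

white_blob_image <- function(H = 64, W = 64, y = 21:30, x = 41:56) {
  px <- array(0.1, c(H, W, 3))
  px[y, x, ] <- 1
  corners <- c(min(x) - 1, min(y) - 1, max(x), max(y))
  labeled_image(px, pixels_to_boxes(matrix(corners, 1), 0L, c(H, W)))
}

test_that("all probabilities zero is the identity", {
  img <- generate_synthetic_scene(2, c(64, 64), seed = 1)
  out <- augment(img, no_aug, seed = 99)
  expect_identical(out$pixels, img$pixels)
  expect_identical(out$boxes, img$boxes)
})

test_that("horizontal flip mirrors pixels and reflects cx", {
  img <- white_blob_image()
  cfg <- no_aug; cfg$p_flip <- 1
  out <- augment(img, cfg, seed = 1)
  expect_equal(out$boxes$cx, 1 - img$boxes$cx)
  expect_equal(out$boxes$w, img$boxes$w)
  expect_equal(out$boxes$h, img$boxes$h)
  # pixel/label consistency after the flip
  expect_equal(as.numeric(boxes_to_pixels(out$boxes, c(64, 64))),
               as.numeric(tight_white_box(out$pixels)), tolerance = 1e-9)
})

test_that("cropping remaps surviving boxes and drops invisible ones", {
  img <- white_blob_image()   # blob entirely in the right half
  cfg <- no_aug; cfg$p_crop <- 1; cfg$crop_range <- c(0.5, 0.5)
  dropped <- 0; kept_consistent <- 0
  for (s in 1:40) {
    out <- augment(img, cfg, seed = s)
    if (nrow(out$boxes) == 0) {
      dropped <- dropped + 1
    } else {
      got <- as.numeric(boxes_to_pixels(out$boxes, dim(out$pixels)[1:2]))
      want <- as.numeric(tight_white_box(out$pixels))
      if (max(abs(got - want)) <= 2) kept_consistent <- kept_consistent + 1
    }
  }
  expect_gt(dropped, 0)                    # left-half windows lose the blob
  expect_equal(kept_consistent, 40 - dropped)
})

test_that("augmented synthetic scenes keep boxes within 2 px of the blob", {
  # one-instance scenes, geometric transforms only
  cfg <- augment_config(p_crop = 0.5, p_flip = 0.5, p_scale = 0.5,
                        p_hsv = 0, p_noise = 0, min_visibility = 0.2)
  img <- white_blob_image(96, 96, y = 30:60, x = 12:50)
  for (s in 1:15) {
    out <- augment(img, cfg, seed = s)
    if (nrow(out$boxes) == 0) next
    got <- as.numeric(boxes_to_pixels(out$boxes, dim(out$pixels)[1:2]))
    want <- as.numeric(tight_white_box(out$pixels))
    expect_lte(max(abs(got - want)), 2)
  }
})

test_that("photometric transforms change pixels but not labels", {
  img <- generate_synthetic_scene(3, c(64, 64), seed = 5)
  cfg <- no_aug; cfg$p_hsv <- 1; cfg$p_noise <- 1
  out <- augment(img, cfg, seed = 2)
  expect_identical(out$boxes, img$boxes)
  expect_false(identical(out$pixels, img$pixels))
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("a too-small crop window is rejected", {
  img <- white_blob_image(40, 40, y = 5:10, x = 5:10)
  cfg <- no_aug; cfg$p_crop <- 1; cfg$crop_range <- c(0.5, 0.5)  # 20 px < 32
  expect_error(augment(img, cfg, seed = 1), "32 px")
})
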