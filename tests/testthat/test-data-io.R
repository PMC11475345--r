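test_that("label files round-trip losslessly to 6 decimals", {
  path <- withr::local_tempfile(fileext = ".txt")
  b <- yolo_boxes(cls = c(2L, 0L, 3L),
                  cx = c(0.5, 0.123456789, 0.9),
                  cy = c(0.5, 0.25, 0.43),
                  w = c(0.25, 0.1, 0.2), h = c(0.4, 0.31, 0.05))
  write_yolo_labels(b, path)
  r <- read_yolo_labels(path)
  expect_equal(nrow(r), 3)
  expect_equal(r$cls, b$cls)
  expect_equal(r$cx, round(b$cx, 6), tolerance = 1e-12)
  expect_equal(r$w, round(b$w, 6), tolerance = 1e-12)
  # empty file -> empty table; empty table -> empty file
  write_yolo_labels(yolo_boxes(), path)
  expect_equal(nrow(read_yolo_labels(path)), 0)
})

test_that("label parsing rejects malformed and out-of-range input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.2", "1 0.5 0.5"), path)
  expect_error(read_yolo_labels(path), "line 2")
  writeLines("0 0.5 0.5 1.5 0.4", path)       # w > 1
  expect_error(read_yolo_labels(path), "sizes")
  writeLines("7 0.5 0.5 0.2 0.2", path)       # class out of range
  expect_error(read_yolo_labels(path), "class")
  writeLines("0 0.5 abc 0.2 0.2", path)
  expect_error(read_yolo_labels(path), "non-numeric")
})

test_that("normalized-to-pixel conversion matches hand arithmetic", {
  b <- yolo_boxes(cls = 2L, cx = 0.5, cy = 0.5, w = 0.25, h = 0.4)
  co <- boxes_to_pixels(b, c(640, 640))
  expect_equal(as.numeric(co), c(240, 192, 400, 448))
  back <- pixels_to_boxes(co, 2L, c(640, 640))
  expect_equal(back$cx, 0.5)
  expect_equal(back$w, 0.25)
})

test_that("splitting is a deterministic rounded-fraction partition", {
  s1 <- split_dataset(1:10, split_spec(seed = 7))
  expect_equal(lengths(s1), c(train = 8L, val = 1L, test = 1L))
  expect_setequal(unlist(s1), 1:10)

  s2 <- split_dataset(1:5051, split_spec(seed = 1))
  expect_true(abs(length(s2$train) - 4041) <= 1)
  expect_true(abs(length(s2$val) - 505) <= 1)
  expect_true(abs(length(s2$test) - 505) <= 1)
  expect_equal(sort(unname(unlist(s2))), 1:5051)        # exhaustive and disjoint

  s3 <- split_dataset(1:5051, split_spec(seed = 1))
  expect_identical(s2, s3)                      # same seed, same partition
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("synthetic scenes satisfy the labeling invariants", {
  img0 <- generate_synthetic_scene(0, c(64, 64), seed = 1)
  expect_equal(nrow(img0$boxes), 0)
  img <- generate_synthetic_scene(5, c(96, 96), occlusion_prob = 0.3, seed = 2)
  expect_equal(nrow(img$boxes), 5)
  co <- boxes_to_pixels(img$boxes, c(96, 96))
  expect_true(all(co[, 1] >= 0 & co[, 2] >= 0 & co[, 3] <= 96 & co[, 4] <= 96))
  expect_true(all(co[, 3] > co[, 1] & co[, 4] > co[, 2]))
  # determinism
  img_b <- generate_synthetic_scene(5, c(96, 96), occlusion_prob = 0.3, seed = 2)
  expect_identical(img$pixels, img_b$pixels)
  expect_identical(img$boxes, img_b$boxes)
})

test_that("forced occlusion produces substantial pairwise overlap", {
  hits <- 0
  for (s in 1:10) {
    img <- generate_synthetic_scene(2, c(96, 96), occlusion_prob = 1, seed = s)
    co <- boxes_to_pixels(img$boxes, c(96, 96))
    inter <- max(0, min(co[1, 3], co[2, 3]) - max(co[1, 1], co[2, 1])) *
             max(0, min(co[1, 4], co[2, 4]) - max(co[1, 2], co[2, 2]))
    amin <- min((co[1, 3] - co[1, 1]) * (co[1, 4] - co[1, 2]),
                (co[2, 3] - co[2, 1]) * (co[2, 4] - co[2, 2]))
    if (inter >= 0.25 * amin) hits <- hits + 1
  }
  expect_gte(hits, 8)   # constructive placement succeeds almost always
})

test_that("image + label pairs and dataset YAML round-trip on disk", {
  dir <- withr::local_tempdir()
  img <- generate_synthetic_scene(2, c(64, 64), seed = 3)
  p <- file.path(dir, "scene.png")
  save_labeled_image(img, p)
  back <- load_labeled_image(p)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_equal(back$boxes$cx, img$boxes$cx, tolerance = 1e-6)
  yml <- file.path(dir, "data.yaml")
  write_dataset_yaml(list(train = "tr", val = "va", test = "te",
                          names = cattle_classes), yml)
  cfg <- read_dataset_yaml(yml)
  expect_equal(cfg$names, cattle_classes)
})
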