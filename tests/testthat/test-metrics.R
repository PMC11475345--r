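test_that("average precision reproduces the hand-integrated PR curve", {
  # ranked [tp, fp, tp] with 2 ground truths: AP = 0.5*1 + 0.5*(2/3)
  ap <- average_precision(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, FALSE), 2)
  expect_equal(ap, 0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  expect_equal(round(ap, 4), 0.8333)
  expect_equal(average_precision(c(TRUE, TRUE), c(FALSE, FALSE), 2), 1)
  expect_equal(average_precision(logical(0), logical(0), 3), 0)
  expect_true(is.na(average_precision(logical(0), logical(0), 0)))
})

test_that("AP matches a brute-force integration on random rankings", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    tp <- runif(n) < 0.5
    n_gt <- sum(tp) + sample(0:5, 1)
    if (n_gt == 0) next
    expect_equal(average_precision(tp, !tp, n_gt), ap_bruteforce(tp, n_gt),
                 tolerance = 1e-9)
  }
})

test_that("AP is invariant to monotone rescaling of the scores", {
  set.seed(2)
  img <- generate_synthetic_scene(3, c(64, 64), seed = 4)
  gt <- img$boxes
  jitter_det <- function(scores) {
    d <- gt
    d$score <- scores
    d
  }
  s <- c(0.9, 0.5, 0.2)
  d1 <- jitter_det(s); d2 <- jitter_det(s^3)   # same ranking
  e1 <- evaluate_detector(function(im) d1, list(img))
  e2 <- evaluate_detector(function(im) d2, list(img))
  expect_equal(e1$map50, e2$map50)
  expect_equal(e1$ap_per_class, e2$ap_per_class)
})

test_that("greedy matching enforces one-to-one class-aware assignment", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  det <- rbind(c(0, 0, 10, 10), c(0.5, 0.5, 10.5, 10.5))
  m <- match_detections(det, c(0L, 0L), c(0.9, 0.8), gt, 0L)
  expect_equal(sum(m$tp), 1)                   # duplicate becomes fp
  expect_equal(sum(m$fp), 1)
  expect_equal(m$fn, 0)
  # exact IoU 0.45 pair fails the 0.5 threshold: fp + fn
  y <- 55 / 14.5
  b <- c(0, y, 10, 10 + y)
  expect_equal(box_iou(c(0, 0, 10, 10), b), 0.45, tolerance = 1e-12)
  m2 <- match_detections(matrix(b, 1), 0L, 0.9, gt, 0L, iou_thr = 0.5)
  expect_false(any(m2$tp))
  expect_equal(m2$fn, 1)
  # class mismatch never matches
  m3 <- match_detections(gt, 1L, 0.9, gt, 0L)
  expect_equal(m3$fn, 1)
})

test_that("mAP is exactly the unweighted mean of defined per-class APs", {
  set.seed(3)
  ds <- generate_synthetic_dataset(12, c(64, 64), seed = 8)
  oracle <- function(im) { d <- im$boxes; d$score <- 0.9; d }
  ev <- evaluate_detector(oracle, ds)
  defined <- !is.na(ev$ap_per_class)
  expect_equal(ev$map50, mean(ev$ap_per_class[defined]))
  expect_equal(ev$map50, 1)                    # oracle detector is perfect
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_error(evaluate_detector(oracle, list()), "empty")
})

test_that("2-px jitter keeps mAP high; random boxes score near zero", {
  ds <- generate_synthetic_dataset(30, c(64, 64), n_range = c(1, 3), seed = 9)
  jittered <- function(im) {
    d <- im$boxes
    if (nrow(d) == 0) return(d)
    co <- boxes_to_pixels(d, dim(im$pixels)[1:2])
    co <- co + matrix(runif(length(co), -2, 2), nrow(co))
    co[, 1] <- pmax(0, co[, 1]); co[, 2] <- pmax(0, co[, 2])
    co[, 3] <- pmin(64, pmax(co[, 3], co[, 1] + 1))
    co[, 4] <- pmin(64, pmax(co[, 4], co[, 2] + 1))
    out <- pixels_to_boxes(co, d$cls, dim(im$pixels)[1:2], score = 0.9)
    out
  }
  set.seed(10)
  ev <- evaluate_detector(jittered, ds)
  expect_gte(ev$map50, 0.99)
  rand_det <- function(im) {
    k <- 3
    x1 <- runif(k, 0, 48); y1 <- runif(k, 0, 48)
    co <- cbind(x1, y1, x1 + runif(k, 4, 16), y1 + runif(k, 4, 16))
    pixels_to_boxes(co, sample(0:3, k, TRUE), c(64, 64), score = runif(k))
  }
  ev2 <- evaluate_detector(rand_det, ds)
  expect_lt(ev2$map50, 0.05)
})
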