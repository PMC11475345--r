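ns <- asNamespace("cbryolo")

test_that("the learning-rate schedule warms up then decays linearly", {
  cfg <- train_config(epochs = 100)
  expect_lt(lr_schedule(0, cfg), cfg$lr0)                 # warm-up
  expect_equal(lr_schedule(cfg$warmup_epochs, cfg), cfg$lr0)
  expect_equal(lr_schedule(99, cfg), cfg$lr0 * cfg$lrf)   # endpoint
  lrs <- vapply(cfg$warmup_epochs:99, lr_schedule, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 1e-12))                    # non-increasing
  expect_error(train_config(lr0 = -1))
})

test_that("the criterion is finite on fixture batches and empty images", {
  set.seed(1)
  m <- build_model(cbr_config(img_size = 64), seed = 1)
  ds <- generate_synthetic_dataset(2, c(64, 64), seed = 3)
  x <- ns$stack_images(ds)
  fw <- ns$nn_forward(m$graph, x, training = TRUE)
  tg <- lapply(ds, ns$image_targets)
  ls <- detection_loss(m, fw$outputs, tg, c(64, 64))
  expect_true(is.finite(ls$total))
  expect_true(all(is.finite(unlist(ls$components))))
  expect_gt(ls$total, 0)
  # empty image: only the background classification term remains
  empty <- list(list(boxes = NULL, cls = integer(0)))
  x1 <- x[, , , 1, drop = FALSE]
  fw1 <- ns$nn_forward(m$graph, x1, training = TRUE)
  ls0 <- detection_loss(m, fw1$outputs, empty, c(64, 64))
  expect_equal(unname(ls0$components["box"]), 0)
  expect_equal(unname(ls0$components["dfl"]), 0)
  expect_gt(unname(ls0$components["cls"]), 0)
  # non-finite predictions are rejected with a diagnostic
  bad <- fw1$outputs
  bad[[1]][1] <- NaN
  expect_error(detection_loss(m, bad, empty, c(64, 64)), "non-finite")
})

test_that("confident predictions centred on the targets zero the box loss", {
  # hand-built raw outputs: one anchor carries a delta distribution whose
  # decoded box is the ground truth; its class logit is confident
  md <- loss_model_stub()
  out <- blank_outputs(64)
  # anchor (3, 3) at stride 8: center (20, 20); distances 2 bins = 16 px
  gt <- matrix(c(4, 4, 36, 36), 1)
  for (s in 1:4) out[[1]][3, 3, (s - 1) * 16 + 3, 1] <- 60   # bin 2 delta
  out[[2]][3, 3, 1, 1] <- 8
  ls <- detection_loss(md, out, list(list(boxes = gt, cls = 0L)), c(64, 64))
  expect_lt(unname(ls$components["box"]), 1e-3)
  expect_lt(unname(ls$components["dfl"]), 1e-3)
})

test_that("switching the box criterion changes the training gradients", {
  set.seed(2)
  ds <- generate_synthetic_dataset(1, c(64, 64), seed = 5)
  tg <- lapply(ds, ns$image_targets)
  m1 <- build_model(cbr_config(img_size = 64, loss = "inner_mpdiou"), seed = 1)
  m2 <- build_model(cbr_config(img_size = 64, loss = "ciou"), seed = 1)
  x <- ns$stack_images(ds)
  fw <- ns$nn_forward(m1$graph, x, training = TRUE)
  l1 <- detection_loss(m1, fw$outputs, tg, c(64, 64))
  l2 <- detection_loss(m2, fw$outputs, tg, c(64, 64))
  d1 <- l1$grads[[1]]; d2 <- l2$grads[[1]]
  expect_gt(max(abs(d1 - d2)), 1e-8)
  # the classification gradients agree (the criterion differs in box only)
  expect_equal(l1$grads[[2]], l2$grads[[2]], tolerance = 1e-12)
})

test_that("training is deterministic and reduces the loss on a tiny fixture", {
  ds <- generate_synthetic_dataset(2, c(64, 64), n_range = c(1, 1), seed = 6)
  cfg <- train_config(batch = 2, img_size = 64, epochs = 8, seed = 11)
  m1 <- build_model(cbr_config(img_size = 64), seed = 2)
  r1 <- train(m1, ds, cfg)
  m2 <- build_model(cbr_config(img_size = 64), seed = 2)
  r2 <- train(m2, ds, cfg)
  expect_identical(r1$history$total[1], r2$history$total[1])
  expect_identical(r1$history$total, r2$history$total)
  expect_lt(mean(tail(r1$history$box, 2)), r1$history$box[1])
})
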