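ns <- asNamespace("cbryolo")

lmfd_graph <- function(chs = c(8, 8, 8), cfg = lmfd_config(hidden = 8,
                                                           gn_groups = 2)) {
  g <- ns$nn_new()
  p3 <- ns$nn_add(g, "act", 0, cfg = list(fun = "silu"))     # stride-8 stub
  p4 <- ns$nn_avgpool(g, p3, 2, 2, 0)
  p5 <- ns$nn_avgpool(g, p4, 2, 2, 0)
  outs <- ns$build_lmfd(g, c(p3, p4, p5), chs, cfg)
  g$outputs <- outs
  list(g = g, cfg = cfg)
}

test_that("head outputs have the contract channel counts per level", {
  set.seed(1)
  z <- lmfd_graph()
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  fw <- ns$nn_forward(z$g, x)
  expect_length(fw$outputs, 6)
  for (lv in 1:3) {
    expect_equal(dim(fw$outputs[[2 * lv - 1]])[3], 4 * z$cfg$reg_max)
    expect_equal(dim(fw$outputs[[2 * lv]])[3], z$cfg$n_classes)
    expect_equal(dim(fw$outputs[[2 * lv - 1]])[1], 16 / 2^(lv - 1))
  }
})

test_that("the 3x3 conv is shared across levels, the 1x1 convs are not", {
  set.seed(2)
  z <- lmfd_graph()
  g <- z$g
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  base <- ns$nn_forward(g, x)$outputs
  shared_id <- which(vapply(g$layers, function(l)
    l$type == "conv" && l$cfg$k[1] == 3 && is.na(l$share_with), logical(1)))
  expect_length(shared_id, 1)         # one owner, two sharers
  g$layers[[shared_id]]$params$w <- g$layers[[shared_id]]$params$w + 0.05
  pert <- ns$nn_forward(g, x)$outputs
  for (lv in 1:3)                      # all levels change
    expect_gt(max(abs(pert[[2 * lv]] - base[[2 * lv]])), 1e-8)
  # perturb the level-2 1x1: only level 2 changes
  g$layers[[shared_id]]$params$w <- g$layers[[shared_id]]$params$w - 0.05
  lvl_convs <- which(vapply(g$layers, function(l)
    l$type == "conv" && l$cfg$k[1] == 1 && !isTRUE(l$cfg$bias) &&
      is.na(l$share_with), logical(1)))
  g$layers[[lvl_convs[2]]]$params$w <- g$layers[[lvl_convs[2]]]$params$w + 0.05
  pert2 <- ns$nn_forward(g, x)$outputs
  expect_lt(max(abs(pert2[[1]] - base[[1]])), 1e-12)
  expect_gt(max(abs(pert2[[3]] - base[[3]])), 1e-8)
  expect_lt(max(abs(pert2[[5]] - base[[5]])), 1e-12)
})

test_that("group normalisation makes the head batch-size independent", {
  set.seed(3)
  z <- lmfd_graph()
  x1 <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  x2 <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  xb <- array(c(x1, x2), c(16, 16, 8, 2))
  ob <- ns$nn_forward(z$g, xb)$outputs
  o1 <- ns$nn_forward(z$g, x1)$outputs
  for (j in seq_along(ob))
    expect_equal(ob[[j]][, , , 1, drop = FALSE], o1[[j]], tolerance = 1e-12)
})

test_that("per-level scales start neutral and act multiplicatively", {
  set.seed(4)
  z <- lmfd_graph()
  g <- z$g
  scale_ids <- which(vapply(g$layers, function(l) l$type == "scale",
                            logical(1)))
  expect_length(scale_ids, 3)
  expect_true(all(vapply(scale_ids, function(i) g$layers[[i]]$params$s,
                         numeric(1)) == 1))
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  base <- ns$nn_forward(g, x)$outputs
  g$layers[[scale_ids[1]]]$params$s <- 2
  out <- ns$nn_forward(g, x)$outputs
  expect_equal(out[[1]], 2 * base[[1]], tolerance = 1e-12)
  expect_equal(out[[3]], base[[3]])
})

test_that("head parameter budget: closed form, graph count, 85% reduction", {
  cfg <- lmfd_config()
  g <- ns$nn_new()
  p3 <- ns$nn_add(g, "act", 0, cfg = list(fun = "silu"))
  p4 <- ns$nn_avgpool(g, p3, 2, 2, 0)
  p5 <- ns$nn_avgpool(g, p4, 2, 2, 0)
  ns$build_lmfd(g, c(p3, p4, p5), c(64, 128, 256), cfg)
  n_lmfd <- ns$nn_params(g)
  expect_equal(n_lmfd, lmfd_param_count(c(64, 128, 256), cfg))
  g2 <- ns$nn_new()
  p3 <- ns$nn_add(g2, "act", 0, cfg = list(fun = "silu"))
  p4 <- ns$nn_avgpool(g2, p3, 2, 2, 0)
  p5 <- ns$nn_avgpool(g2, p4, 2, 2, 0)
  ns$build_v8_head(g2, c(p3, p4, p5), c(64, 128, 256), nc = 4)
  n_v8 <- ns$nn_params(g2)
  expect_gte(1 - n_lmfd / n_v8, 0.85)
  # doubling the hidden width roughly quadruples the shared 3x3 term
  t3 <- function(h) 9 * h^2
  expect_equal(t3(2 * cfg$hidden) / t3(cfg$hidden), 4)
})

test_that("decode inverts a peaked distribution and NMS deduplicates", {
  # distribution peaked at bin b -> decoded distance b * stride
  reg <- array(0, c(2, 2, 64, 1))
  b <- 5
  for (s in 1:4) reg[, , (s - 1) * 16 + b + 1, 1] <- 50   # delta at bin b
  dec <- ns$decode_level(reg[, , , 1], stride = 8, reg_max = 16)
  # anchor (1,1) center is (4, 4); sides all b*8 = 40
  expect_equal(unname(dec[1, ]), c(4 - 40, 4 - 40, 4 + 40, 4 + 40),
               tolerance = 1e-6)
  # NMS keeps the higher-scoring of two identical boxes
  bx <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(50, 50, 60, 60))
  keep <- nms(bx, c(0.9, 0.8, 0.7), iou_thr = 0.5)
  expect_equal(keep, c(1, 3))
  # empty input
  expect_length(nms(matrix(numeric(0), 0, 4), numeric(0)), 0)
})

test_that("a detector with driven-down class logits detects nothing", {
  m <- build_model(cbr_config(img_size = 64), seed = 1)
  for (ly in m$graph$layers)
    if (ly$type == "conv" && isTRUE(ly$cfg$bias) && ly$cfg$cout == m$nc)
      m$graph$layers[[ly$id]]$params$b[] <- -30
  img <- generate_synthetic_scene(2, c(64, 64), seed = 1)
  det <- predict_boxes(m, img, conf_thr = 0.25)
  expect_equal(nrow(det), 0)
})
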