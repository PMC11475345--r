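test_that("IoU matches hand cases and is symmetric", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  set.seed(1)
  for (i in 1:50) {
    a <- rand_box(); b <- rand_box()
    expect_equal(box_iou(a, b), box_iou(b, a))
  }
  expect_warning(v <- box_iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
  expect_equal(v, 0)
})

test_that("IoU agrees with the 0.01-px rasterization oracle", {
  set.seed(42)
  for (i in 1:1000) {
    a <- rand_box(min_side = 8)
    b <- if (i %% 3 == 0) a + runif(4, -5, 5) else rand_box(min_side = 8)
    if (b[3] <= b[1] || b[4] <= b[2]) next
    expect_lt(abs(box_iou(a, b) - raster_iou(a, b)), 1e-3)
  }
})

test_that("inner boxes preserve the center and scale the area by ratio^2", {
  expect_equal(inner_box(c(0, 0, 10, 10), 1), c(0, 0, 10, 10))
  expect_equal(inner_box(c(0, 0, 10, 10), 0.5), c(2.5, 2.5, 7.5, 7.5))
  set.seed(2)
  for (r in c(0.5, 0.7, 1.2, 1.5)) {
    b <- rand_box()
    ib <- inner_box(b, r)
    expect_equal((ib[1] + ib[3]) / 2, (b[1] + b[3]) / 2)
    expect_equal((ib[3] - ib[1]) * (ib[4] - ib[2]),
                 r^2 * (b[3] - b[1]) * (b[4] - b[2]))
  }
})

test_that("MPDIoU matches direct substitution and its invariances", {
  # IoU 64/136, both corner distances 8, frame 100x100
  v <- mpdiou(c(0, 0, 10, 10), c(2, 2, 12, 12), 100, 100)
  expect_equal(v, 64 / 136 - 16 / 20000, tolerance = 1e-12)
  expect_equal(round(v, 5), 0.46979)
  expect_equal(mpdiou(c(3, 4, 13, 14), c(3, 4, 13, 14), 100, 100), 1)
  # translation invariance of the measure
  set.seed(3)
  for (i in 1:20) {
    p <- rand_box(); g <- rand_box(); d <- runif(1, -10, 10)
    expect_equal(mpdiou(p, g, 100, 100),
                 mpdiou(p + d, g + d, 100, 100), tolerance = 1e-12)
  }
  # penalty symmetric under swapping the roles of the two boxes
  p <- rand_box(); g <- rand_box()
  pen1 <- box_iou(p, g) - mpdiou(p, g, 100, 100)
  pen2 <- box_iou(g, p) - mpdiou(g, p, 100, 100)
  expect_equal(pen1, pen2)
})

test_that("inner-MPDIoU reduces to MPDIoU at ratio 1 and peaks at identity", {
  set.seed(4)
  for (i in 1:100) {
    p <- rand_box(); g <- rand_box()
    expect_equal(inner_mpdiou(p, g, 100, 100, ratio = 1),
                 mpdiou(p, g, 100, 100), tolerance = 1e-12)
  }
  for (r in c(0.5, 0.7, 1, 1.3)) {
    b <- rand_box()
    expect_equal(inner_mpdiou(b, b, 100, 100, ratio = r), 1)
  }
  # all family members are at most 1, equal 1 iff coincident (ratio 1)
  for (i in 1:50) {
    p <- rand_box(); g <- rand_box()
    vals <- c(box_iou(p, g), ciou(p, g), mpdiou(p, g, 100, 100),
              inner_mpdiou(p, g, 100, 100))
    expect_true(all(vals <= 1 + 1e-12))
    if (max(abs(p - g)) > 1e-6) expect_lt(vals[1], 1)
  }
  # inner overlap term via the rasterization oracle
  p <- c(0, 0, 10, 10); g <- c(2, 2, 12, 12)
  want <- raster_iou(inner_box(p, 0.75), inner_box(g, 0.75)) - 16 / 20000
  expect_lt(abs(inner_mpdiou(p, g, 100, 100, ratio = 0.75) - want), 1e-3)
})

test_that("CIoU matches an independent scalar reference", {
  expect_equal(ciou(c(1, 2, 11, 12), c(1, 2, 11, 12)), 1, tolerance = 1e-6)
  # same aspect, concentric: aspect term vanishes (reduces to DIoU = IoU)
  expect_equal(ciou(c(4, 4, 8, 8), c(2, 2, 10, 10)),
               box_iou(c(4, 4, 8, 8), c(2, 2, 10, 10)) - 0, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:200) {
    p <- rand_box(); g <- rand_box()
    expect_lt(abs(ciou(p, g) - ciou_ref(p, g)), 1e-6)
  }
})

test_that("the analytic Inner-MPDIoU gradient matches finite differences", {
  set.seed(6)
  checked <- 0
  for (i in 1:80) {
    p <- rand_box(); g <- rand_box()
    # skip configurations near the non-differentiable corner ties
    if (min(abs(c(p[1] - g[1], p[2] - g[2], p[3] - g[3], p[4] - g[4]))) < 1e-3)
      next
    for (r in c(0.7, 1)) {
      an <- as.numeric(grad_inner_mpdiou(p, g, 100, 100, ratio = r))
      fd <- fd_box_grad(function(pp)
        inner_mpdiou(pp, g, 100, 100, ratio = r), p)
      denom <- pmax(abs(fd), 1e-3)
      expect_lt(max(abs(an - fd) / denom), 1e-4)
    }
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})
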