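det_from <- function(x_min, y_min, x_max, y_max, score)
  detections(boxes(x_min, y_min, x_max, y_max), score)

test_that("nms keeps the winner among duplicates and all disjoint boxes", {
  d <- det_from(c(0, 0), c(0, 0), c(10, 10), c(10, 10), c(0.9, 0.8))
  out <- nms(d, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)

  d2 <- det_from(c(0, 50), c(0, 50), c(10, 60), c(10, 60), c(0.9, 0.8))
  expect_equal(nrow(nms(d2, 0.5)), 2)
})

test_that("nms agrees with the brute-force reference on random instances", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(1:12, 1)
    d <- random_detections(n, s)
    thr <- runif(1, 0.2, 0.8)
    got <- nms(d, thr)
    ref <- oracle_nms(d, thr)
    expect_equal(got[, 1:5], ref[, 1:5], ignore_attr = TRUE)
  }
})

test_that("wbf reproduces the hand-worked fusion formulas", {
  # three identical boxes from three scales: fused box = B, score = mean
  b3 <- det_from(rep(0, 3), rep(0, 3), rep(10, 3), rep(10, 3),
                 c(0.9, 0.6, 0.3))
  f <- wbf(b3, fusion_config("wbf", n_sources = 3))
  expect_equal(nrow(f), 1)
  expect_equal(unlist(f[, 1:4]), c(x_min = 0, y_min = 0, x_max = 10, y_max = 10))
  expect_equal(f$score, mean(c(0.9, 0.6, 0.3)) * 3 / 3)

  # a single-scale detection is down-weighted by 1/T
  f1 <- wbf(det_from(0, 0, 10, 10, 0.9), fusion_config("wbf", n_sources = 3))
  expect_equal(f1$score, 0.9 / 3)

  # score-weighted coordinate average
  d <- det_from(c(0, 2), c(0, 0), c(10, 12), c(10, 10), c(0.8, 0.4))
  f2 <- wbf(d, fusion_config("wbf", n_sources = 1))
  expect_equal(f2$x_min, (0 * 0.8 + 2 * 0.4) / 1.2)
  expect_equal(f2$x_max, (10 * 0.8 + 12 * 0.4) / 1.2)
  expect_equal(f2$score, 0.6)
})

test_that("wbf agrees with the independent reference on random instances", {
  for (s in 1:100) {
    set.seed(s + 5000)
    n <- sample(1:15, 1)
    d <- random_detections(n, s + 5000)
    thr <- runif(1, 0.3, 0.7)
    Tn <- sample(1:4, 1)
    got <- wbf(list(d), fusion_config("wbf", iou_threshold = thr,
                                      n_sources = Tn))
    ref <- oracle_wbf(d, thr, Tn)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got[, c("x_min", "y_min", "x_max", "y_max", "score")],
                 ref[, c("x_min", "y_min", "x_max", "y_max", "score")],
                 ignore_attr = TRUE)
    expect_equal(got$cluster_size, ref$n)
  }
})

test_that("wbf invariants: hull containment, identity, permutation invariance", {
  for (s in 1:30) {
    d <- random_detections(10, s + 900)
    cfg <- fusion_config("wbf", n_sources = 3)
    f <- wbf(list(d), cfg)
    # each fused box within the componentwise hull of all inputs
    expect_true(all(f$x_min >= min(d$x_min) - 1e-9))
    expect_true(all(f$x_max <= max(d$x_max) + 1e-9))
    expect_true(all(f$y_min >= min(d$y_min) - 1e-9))
    expect_true(all(f$y_max <= max(d$y_max) + 1e-9))
    # permutation invariance (scores distinct w.p. 1)
    set.seed(s)
    perm <- sample(nrow(d))
    f2 <- wbf(list(d[perm, ]), cfg)
    expect_equal(f[, 1:5], f2[, 1:5], ignore_attr = TRUE)
  }
  # identity on disjoint single-source boxes with T = 1
  d <- det_from(c(0, 40, 80), c(0, 40, 80), c(10, 50, 90), c(10, 50, 90),
                c(0.3, 0.9, 0.6))
  f <- wbf(list(d), fusion_config("wbf", n_sources = 1))
  expect_equal(f[order(f$x_min), c(1:4)],
               d[order(d$x_min), c(1:4)], ignore_attr = TRUE)
  expect_equal(sort(f$score), sort(d$score))
})

test_that("wbf averages boxes where nms merely discards them", {
  d <- det_from(c(0, 2), c(0, 0), c(10, 12), c(10, 10), c(0.8, 0.4))
  kept <- nms(d, 0.5)
  fused <- wbf(list(d), fusion_config("wbf", iou_threshold = 0.5,
                                      n_sources = 1))
  expect_equal(unlist(kept[1, 1:4]), unlist(d[1, 1:4])) # subset of input
  expect_false(any(fused$x_min %in% d$x_min))           # genuinely new box
})

test_that("fuse_scales dispatches and preserves basic contracts", {
  empty3 <- list(empty_detections(), empty_detections(), empty_detections())
  expect_equal(nrow(fuse_scales(empty3, fusion_config("wbf"))), 0)
  expect_equal(nrow(fuse_scales(empty3, fusion_config("nms"))), 0)

  for (s in 1:20) {
    a <- random_detections(6, s)
    b <- random_detections(5, s + 100)
    cfg <- fusion_config("nms", n_sources = 2)
    pooled <- rbind(a, b)
    expect_equal(fuse_scales(list(a, b), cfg)[, 1:5],
                 nms(pooled, cfg$iou_threshold)[, 1:5], ignore_attr = TRUE)
    wcfg <- fusion_config("wbf", n_sources = 2)
    expect_lte(nrow(fuse_scales(list(a, b), wcfg)), nrow(pooled))
  }

  # nms_threshold applies the score floor first
  d <- det_from(c(0, 40), c(0, 0), c(10, 50), c(10, 10), c(0.9, 0.2))
  out <- fuse_scales(list(d), fusion_config("nms_threshold", score_floor = 0.5,
                                            n_sources = 1))
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)
})
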