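test_that("the hit criterion is center-in-box, not overlap", {
  expect_true(is_hit(boxes(4, 4, 6, 6), boxes(0, 0, 10, 10)))
  # overlapping boxes whose center lies outside: not a hit
  expect_false(is_hit(boxes(9, 9, 19, 19), boxes(0, 0, 10, 10)))
  g <- boxes(3, 4, 11, 12)
  expect_true(is_hit(g, g))
})

mk_preds <- function(image_id, x, y, score, half = 1)
  data.frame(image_id = image_id, x_min = x - half, y_min = y - half,
             x_max = x + half, y_max = y + half, score = score)

test_that("match_at_threshold applies the duplicate and multi-hit rules", {
  gt <- data.frame(image_id = "a", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  # one hitting prediction
  m <- match_at_threshold(mk_preds("a", 5, 5, 0.9), gt, 0.5)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$fpi, 0)
  # two predictions on the same lesion: one hit, zero FPs
  m2 <- match_at_threshold(mk_preds(c("a", "a"), c(5, 6), c(5, 6),
                                    c(0.9, 0.8)), gt, 0.5)
  expect_equal(m2$n_hit, 1)
  expect_equal(m2$n_fp, 0)
  # ... unless duplicates are configured to count as FPs
  m3 <- match_at_threshold(mk_preds(c("a", "a"), c(5, 6), c(5, 6),
                                    c(0.9, 0.8)), gt, 0.5, dup_as_fp = TRUE)
  expect_equal(m3$n_fp, 1)
  # one prediction inside two nested lesions detects both by default
  gt2 <- rbind(gt, data.frame(image_id = "a", x_min = 4, y_min = 4,
                              x_max = 6, y_max = 6))
  m4 <- match_at_threshold(mk_preds("a", 5, 5, 0.9), gt2, 0.5)
  expect_equal(m4$n_hit, 2)
  m5 <- match_at_threshold(mk_preds("a", 5, 5, 0.9), gt2, 0.5,
                           multi_gt = FALSE)
  expect_equal(m5$n_hit, 1)
  # unknown image ids are an input error
  expect_error(match_at_threshold(mk_preds("zzz", 5, 5, 0.9), gt, 0.5,
                                  image_ids = "a"), "unknown image_id")
})

test_that("normal images enlarge the FPI denominator", {
  gt <- data.frame(image_id = "a", x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  p <- mk_preds(c("a", "b"), c(50, 50), c(50, 50), c(0.9, 0.8))
  m <- match_at_threshold(p, gt, 0.5, image_ids = c("a", "b", "c", "d"))
  expect_equal(m$n_fp, 2)
  expect_equal(m$fpi, 0.5)
})

test_that("froc produces the exact step curve", {
  gt <- data.frame(image_id = c("a", "b"),
                   x_min = c(0, 20), y_min = c(0, 20),
                   x_max = c(10, 30), y_max = c(10, 30))
  # perfect detector: one hitting prediction per lesion, no extras
  p <- mk_preds(c("a", "b"), c(5, 25), c(5, 25), c(0.9, 0.8))
  cv <- froc(p, gt, image_ids = c("a", "b"))
  expect_equal(nrow(cv$points), 3) # n unique scores + 1
  expect_equal(sensitivity_at_fpi(cv, 0), 1)
  # all-unique scores: n + 1 points
  p2 <- mk_preds(rep("a", 4), c(5, 50, 60, 70), c(5, 50, 60, 70),
                 c(0.9, 0.7, 0.5, 0.3))
  cv2 <- froc(p2, gt, image_ids = c("a", "b"))
  expect_equal(nrow(cv2$points), 5)
  expect_error(froc(p, gt[0, ], image_ids = c("a", "b")), "zero ground-truth")
})

test_that("froc agrees with the exhaustive oracle on random instances", {
  for (s in 1:50) {
    inst <- random_eval_instance(s)
    cv <- froc(inst$preds, inst$gts, image_ids = inst$ids)
    ref <- oracle_froc(inst$preds, inst$gts, inst$ids)
    expect_equal(cv$points, ref, ignore_attr = TRUE)
    # curve invariants
    expect_true(all(diff(cv$points$threshold) < 0))
    expect_true(all(diff(cv$points$fpi) >= 0))
    expect_true(all(diff(cv$points$sensitivity) >= 0))
  }
})

test_that("kept predictions are conserved between hits and false positives", {
  for (s in 1:20) {
    inst <- random_eval_instance(s + 300)
    for (t in c(0.25, 0.5, 0.75)) {
      m <- match_at_threshold(inst$preds, inst$gts, t, image_ids = inst$ids)
      kept <- inst$preds[inst$preds$score >= t, , drop = FALSE]
      hitting <- sum(apply(hit_matrix_ref(kept, inst$gts), 1, any))
      expect_equal(hitting + m$n_fp, nrow(kept))
    }
  }
})

test_that("sensitivity_at_fpi is the conservative step readout", {
  cv <- structure(list(points = data.frame(threshold = c(Inf, 0.8, 0.6),
                                           fpi = c(0, 0.1, 0.3),
                                           sensitivity = c(0, 0.6, 0.8)),
                       n_images = 10, n_gt = 5), class = "mammotile_froc")
  expect_equal(sensitivity_at_fpi(cv, 0.3), 0.8)
  expect_equal(sensitivity_at_fpi(cv, 0.2), 0.6)
  expect_equal(sensitivity_at_fpi(cv, 0.05), 0)
  # never exceeds the sensitivity of the next point above the target
  for (s in 1:20) {
    inst <- random_eval_instance(s + 600)
    cv2 <- froc(inst$preds, inst$gts, image_ids = inst$ids)
    for (target in c(0.05, 0.25, 1, 3)) {
      v <- sensitivity_at_fpi(cv2, target)
      above <- cv2$points$sensitivity[cv2$points$fpi > target]
      if (length(above) > 0) expect_lte(v, min(above))
    }
  }
})
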