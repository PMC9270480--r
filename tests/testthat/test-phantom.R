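test_that("mm_to_px follows size * 1000 / spacing", {
  expect_equal(mm_to_px(10, 100), 100)
  expect_equal(mm_to_px(5.8, 70), 5800 / 70)
  expect_equal(mm_to_px(1, 50), 20)
  expect_error(mm_to_px(-1, 70), "positive")
  expect_error(mm_to_px(5, 0), "positive")
})

test_that("phantom generation is bit-identical for a fixed spec", {
  sp <- quarter_spec(n_lesions = 3, seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$gt, b$gt)
  expect_equal(nrow(a$gt), 3)
})

test_that("zero-lesion phantoms have an empty ground-truth list", {
  ph <- generate_phantom(quarter_spec(n_lesions = 0, seed = 3))
  expect_equal(nrow(ph$gt), 0)
  expect_true(all(dim(ph$image) == c(1024, 832)))
})

test_that("phantom intensities are 16-bit and the breast fills 40-70%", {
  for (s in c(2, 9)) {
    ph <- generate_phantom(quarter_spec(seed = s))
    expect_gte(min(ph$image), 0)
    expect_lte(max(ph$image), 65535)
    frac <- mean(ph$breast_mask)
    expect_gt(frac, 0.4)
    expect_lt(frac, 0.7)
  }
})

# mean intensity inside the box vs a surrounding annulus of equal area
box_annulus_contrast <- function(img, g) {
  side <- g$x_max - g$x_min
  grow <- side * (sqrt(2) - 1) / 2 # outer box has twice the area
  px <- function(x0, y0, x1, y1) {
    xs <- max(1, floor(x0)):min(ncol(img), ceiling(x1))
    ys <- max(1, floor(y0)):min(nrow(img), ceiling(y1))
    img[ys, xs]
  }
  inner <- px(g$x_min, g$y_min, g$x_max, g$y_max)
  outer_px <- px(g$x_min - grow, g$y_min - grow, g$x_max + grow, g$y_max + grow)
  (sum(outer_px) - sum(inner)) -> ann_sum
  mean(inner) - ann_sum / max(1, length(outer_px) - length(inner))
}

test_that("lesions are conspicuous: in-box mean exceeds the equal-area annulus", {
  for (s in 1:20) {
    ph <- generate_phantom(quarter_spec(n_lesions = 2, seed = s))
    for (j in seq_len(nrow(ph$gt)))
      expect_gt(box_annulus_contrast(ph$image, ph$gt[j, ]), 0)
  }
})

test_that("conspicuity is monotone in lesion_contrast at fixed seed", {
  vals <- sapply(c(0.1, 0.2, 0.4), function(ct) {
    ph <- generate_phantom(quarter_spec(n_lesions = 1, seed = 5,
                                        lesion_contrast = ct))
    box_annulus_contrast(ph$image, ph$gt[1, ])
  })
  expect_true(all(diff(vals) > 0))
})

test_that("ground truth lies inside the image and the breast mask", {
  for (s in c(1, 4, 8)) {
    ph <- generate_phantom(quarter_spec(n_lesions = 3, seed = s,
                                        spiculation = TRUE))
    g <- ph$gt
    expect_true(all(g$x_min >= 0 & g$y_min >= 0 &
                      g$x_max <= ncol(ph$image) & g$y_max <= nrow(ph$image)))
    ctr <- box_center(g)
    idx <- cbind(floor(ctr[, "cy"]) + 1, floor(ctr[, "cx"]) + 1)
    expect_true(all(ph$breast_mask[idx]))
    # corners of the tight box also inside the breast
    for (j in seq_len(nrow(g)))
      expect_true(ph$breast_mask[floor(g$y_min[j]) + 1, floor(g$x_min[j]) + 1])
  }
})

test_that("lesion placement fails cleanly when the breast cannot hold it", {
  sp <- phantom_spec(height = 200, width = 160, pixel_spacing = 280,
                     n_lesions = 2, lesion_diameters = 30, seed = 1)
  expect_error(generate_phantom(sp), "retries")
})

test_that("dataset generation is deterministic with exact bookkeeping", {
  base <- quarter_spec(n_lesions = 2)
  a <- generate_dataset(5, small_mix, seed = 1, base = base)
  b <- generate_dataset(5, small_mix, seed = 1, base = base)
  expect_identical(a$gt, b$gt)
  expect_identical(a$images, b$images)
  expect_equal(nrow(a$gt), 5 * 2)
  expect_equal(length(a$images), 5)
  expect_equal(unique(as.character(a$gt$image_id)), a$image_ids)
  c_ <- generate_dataset(5, small_mix, seed = 2, base = base)
  expect_false(identical(a$gt, c_$gt))
})

test_that("fixed 6 mm mix at 70 um spacing gives ~85.7 px box sides", {
  base <- phantom_spec(height = 1200, width = 900, pixel_spacing = 70,
                       n_lesions = 2, background_texture_sigma = 2)
  ds <- generate_dataset(2, 6, seed = 3, base = base)
  sides <- c(ds$gt$x_max - ds$gt$x_min, ds$gt$y_max - ds$gt$y_min)
  expect_true(all(abs(sides - 6000 / 70) < 2))
})
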