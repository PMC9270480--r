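# Fast experiment-harness checks on tiny datasets; the directional
# reproductions at full (quarter-world) size live in test-acceptance.R.

tiny_dataset <- function(seed, sizes = c(5.8, 8)) {
  base <- phantom_spec(height = 512, width = 416, pixel_spacing = 280,
                       n_lesions = 2, background_texture_sigma = 2)
  generate_dataset(2, sizes, seed = seed, base = base)
}

tiny_config <- function() ablation_config(tile_len = 128, fpi = 0.5)

test_that("resolution ablation arms share bookkeeping and geometry", {
  ds <- tiny_dataset(1)
  cfg <- tiny_config()
  rep <- run_resolution_ablation(ds, cfg)
  expect_equal(rep$proposed$n_images, rep$resolution_negated$n_images)
  expect_equal(rep$proposed$n_gt, rep$resolution_negated$n_gt)
  expect_equal(rep$proposed$config_hash, rep$resolution_negated$config_hash)
  # negated pyramid levels have identical dimensions to the proposed ones
  img <- ds$images[[1]]
  for (s in c(1, 0.5, 0.25)) {
    mock_dims <- function(image, config) {
      dims <<- dim(image)
      empty_detections()
    }
    dims <- NULL
    run_scale(img, s, 128, detector = mock_dims)
    prop_dims <- dims
    dims <- NULL
    run_scale(img, s, 128, detector = mock_dims, base_scale = 0.25)
    expect_equal(dims, prop_dims)
  }
})

test_that("scale ablation's single arm carries only full-resolution frames", {
  ds <- tiny_dataset(2)
  rep <- run_scale_ablation(ds, tiny_config())
  expect_named(rep, c("proposed", "single_scale_fullres"))
  per <- mammotile:::detect_dataset(ds, tiny_config())
  single <- mammotile:::pool_scale(per, 1)
  expect_true(all(single$source_scale == 1))
})

test_that("context ablation evaluates one arm per scale with fixed resolution", {
  ds <- tiny_dataset(3)
  cfg <- tiny_config()
  reps <- run_context_ablation(ds, cfg)
  expect_length(reps, length(cfg$scales))
  expect_named(reps, sprintf("context_scale_%g", cfg$scales))
  hashes <- vapply(reps, `[[`, "", "config_hash")
  expect_length(unique(hashes), 1)
  # tile counts: the 0.25X arm sees one tile, the X arm four
  expect_equal(nrow(plan_tiles(c(512, 416), 128, 0.25 * 4)$tiles), 4)
  expect_equal(nrow(plan_tiles(round(0.25 * c(512, 416)), 128)$tiles), 1)
})

test_that("per-scale exclusivity follows the 'hit at exactly one scale' rule", {
  gt <- data.frame(image_id = "i1", x_min = 10, y_min = 10, x_max = 30,
                   y_max = 30, size_mm = 6)
  ds <- list(images = list(i1 = matrix(0, 64, 64)), gt = gt,
             image_ids = "i1")
  cfg <- ablation_config(tile_len = 64)

  # scripted detector emitting a fixed tile-frame box: at scale 1 it
  # hits the GT; remapped from scale 0.5 / 0.25 frames it lands at
  # (30,...)/0.5 etc., missing -> lesion exclusive to scale 1
  fixed_box <- function(image, config) detections(boxes(15, 15, 25, 25), 0.9)
  tab <- per_scale_analysis(ds, cfg, detector = fixed_box)
  expect_equal(nrow(tab), length(cfg$scales))
  expect_equal(tab$n_exclusive[tab$scale == 1], 1L)
  expect_equal(tab$mean_exclusive_size_mm[tab$scale == 1], 6)
  expect_true(is.na(tab$mean_exclusive_size_mm[tab$scale == 0.25]))

  # detector hitting the GT in every scale's frame: no exclusivity left
  omni <- function(image, config) {
    # tile frame box whose full-res remap is centered on (20, 20)
    s <- nrow(image) / 64
    detections(boxes(18 * s, 18 * s, 22 * s, 22 * s), 0.9)
  }
  tab2 <- per_scale_analysis(ds, cfg, detector = omni)
  expect_true(all(tab2$n_exclusive == 0L))
  expect_true(all(is.na(tab2$mean_exclusive_size_mm)))
  expect_true(all(tab2$sensitivity == 1))
})
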