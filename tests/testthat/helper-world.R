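# The frozen quarter-scale test world: same physical lesion sizes and
# geometry ratios as the nominal 3328 x 4096 @ 70 um acquisition, at a
# quarter of the pixel budget (832 x 1024 @ 280 um, tile_len 256) so the
# full pipeline runs in seconds per image.  Per-scale tile counts stay
# 4 / 2 / 1.

quarter_spec <- function(n_lesions = 3, seed = 1, ...) {
  phantom_spec(height = 1024, width = 832, pixel_spacing = 280,
               n_lesions = n_lesions, background_texture_sigma = 2,
               seed = seed, ...)
}

# small lesions: the sub-centimetre regime (mean ~5.9 mm)
small_mix <- c(4, 5.8, 8)
# large masses: fit the detector band only at the 0.25X scale
large_mix <- c(20, 26, 32)
mixed_mix <- c(small_mix, large_mix)

quarter_config <- function(...) {
  ablation_config(tile_len = 256, fpi = 0.3, ...)
}

small_dataset <- function(seed, n_images = 8)
  generate_dataset(n_images, small_mix, seed = seed, base = quarter_spec(3))
mixed_dataset <- function(seed, n_images = 8)
  generate_dataset(n_images, mixed_mix, seed = seed, base = quarter_spec(2))
large_dataset <- function(seed, n_images = 8)
  generate_dataset(n_images, large_mix, seed = seed, base = quarter_spec(2))

# clean synthetic Gaussian blob on a dark background, 16-bit scale
blob_image <- function(h, w, cx, cy, sigma, peak = 0.5 * 65535) {
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  peak * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
}
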