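#' Reference detector configuration
#'
#' The reference detector is a classical difference-of-Gaussians (DoG)
#' blob detector restricted to a bounded sigma band
#' `[sigma_min, sigma_max]`.  The band plays the role of a fixed
#' receptive field: structures much larger than the band are invisible
#' at full resolution and only enter it at reduced scales, which is what
#' makes multi-scale tiled inference worth studying with a deterministic
#' CPU detector.
#'
#' Defaults are calibrated to the sub-centimetre lesion regime of the
#' quarter-scale phantom world used throughout the test-suite (280
#' micron spacing): a tapered mass of physical diameter D mm has an
#' effective Gaussian width of about 0.75 D px there, so 4-9 mm lesions
#' respond at sigmas of roughly 3-7.  The response threshold sits just
#' above the parenchymal-texture noise floor of the default phantom, so
#' emitted detections are predominantly lesions.
#'
#' @param sigma_min,sigma_max bounds of the sigma ladder in px
#'   (`0 < sigma_min < sigma_max`).
#' @param n_sigma number of ladder levels (>= 2), geometrically spaced.
#' @param response_threshold minimum scale-normalized DoG response for a
#'   peak to become a detection (on the unit intensity scale).
#' @param box_radius_factor half-side of the emitted box as a multiple
#'   of the peak's sigma.
#' @param intensity_scale divisor normalizing image intensities to
#'   `[0, 1]` (65535 for 16-bit images).
#' @param score_scale constant `c` of the monotone score squash
#'   `score = resp/(resp + c)` mapping responses into `[0, 1]`.
#' @return list of class `mammotile_detector_config`.
#' @export
detector_config <- function(sigma_min = 2.5, sigma_max = 7, n_sigma = 6,
                            response_threshold = 0.12,
                            box_radius_factor = 2,
                            intensity_scale = 65535,
                            score_scale = 0.02) {
  if (!(sigma_min > 0 && sigma_min < sigma_max))
    stop("detector_config: need 0 < sigma_min < sigma_max")
  if (n_sigma < 2) stop("detector_config: n_sigma must be >= 2")
  if (response_threshold < 0) stop("detector_config: threshold must be >= 0")
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 n_sigma = as.integer(n_sigma),
                 response_threshold = response_threshold,
                 box_radius_factor = box_radius_factor,
                 intensity_scale = intensity_scale,
                 score_scale = score_scale),
            class = "mammotile_detector_config")
}

#' Difference-of-Gaussians blob detection
#'
#' Builds a geometric sigma ladder over the configured band (padded by
#' one level at each end so band-edge responses still have scale
#' neighbours), takes successive Gaussian differences normalized by the
#' ladder ratio, and reports strict 3x3x3 local maxima above the
#' response threshold.  Each peak at sigma becomes a box of half-side
#' `box_radius_factor * sigma` centered on the peak (unclipped, so that
#' seam duplicates from adjacent tiles coincide; [run_scale()] clips to
#' the full image after remapping); the response `r` is squashed into a
#' score `resp/(resp + c)`.  Fully deterministic.
#'
#' This function satisfies the pluggable detector contract used by
#' [run_scale()]: a pure function `(image, config) -> detection table`
#' in the tile frame with scores in `[0, 1]`.
#'
#' @param image numeric matrix (tile), intensities on the configured
#'   scale.
#' @param config a [detector_config()].
#' @return detection table (see [detections()]) in the tile frame;
#'   empty when nothing exceeds the threshold.
#' @export
dog_detect <- function(image, config = detector_config()) {
  if (length(image) == 0) stop("dog_detect: empty image")
  img <- image / config$intensity_scale
  n <- config$n_sigma
  k <- (config$sigma_max / config$sigma_min)^(1 / (n - 1))
  # pad one level below the band and two above so every band sigma is an
  # interior layer of the DoG stack
  sigmas <- config$sigma_min * k^(seq_len(n + 3) - 2)
  blurred <- lapply(sigmas, function(s) gaussian_blur_cpp(img, s))
  dog <- lapply(seq_len(length(sigmas) - 1), function(i)
    (blurred[[i]] - blurred[[i + 1]]) / (k - 1))
  peaks <- local_maxima3d_cpp(dog, config$response_threshold)
  if (nrow(peaks) == 0) return(empty_detections())
  sig <- sigmas[peaks[, "layer"]]
  cx <- peaks[, "col"] - 0.5
  cy <- peaks[, "row"] - 0.5
  half <- config$box_radius_factor * sig
  # boxes are left unclipped here: a blob peaking at a tile border must
  # produce near-identical boxes in both adjacent tiles so seam NMS can
  # merge them; run_scale clips to the full image after remapping
  df <- data.frame(x_min = cx - half, y_min = cy - half,
                   x_max = cx + half, y_max = cy + half)
  score <- peaks[, "value"] / (peaks[, "value"] + config$score_scale)
  detections(df, score)
}

#' Run one pyramid scale of the tiled inference pipeline
#'
#' Composes rescaling, systematic tiling, per-tile detection, and
#' remapping into the full-resolution frame, then suppresses duplicate
#' detections across overlapping tile seams with within-scale NMS.
#' Every returned detection carries its originating scale in
#' `source_scale`.
#'
#' @param image full-resolution numeric matrix.
#' @param scale pyramid scale in `(0, 1]`.
#' @param tile_len strip length in scaled px (see [plan_tiles()]).
#' @param detector a detector-contract function
#'   `(image, config) -> detection table`; default [dog_detect()].
#' @param config detector configuration passed through.
#' @param seam_iou IoU threshold of the within-scale seam NMS, or `NULL`
#'   to disable suppression.
#' @param base_scale if non-`NULL`, negate resolution: build this
#'   pyramid level by first downsampling the image to `base_scale` and
#'   bilinearly upsampling back to the level's dimensions (used by the
#'   resolution/context ablations).
#' @return detection table in the full-resolution frame.
#' @export
run_scale <- function(image, scale, tile_len, detector = dog_detect,
                      config = detector_config(), seam_iou = 0.5,
                      base_scale = NULL) {
  if (!is.finite(scale) || scale <= 0 || scale > 1)
    stop("run_scale: scale must be in (0, 1]")
  target <- c(max(1L, round(scale * nrow(image))),
              max(1L, round(scale * ncol(image))))
  img_s <- if (is.null(base_scale)) {
    rescale(image, scale)
  } else {
    base <- rescale(image, base_scale)
    if (identical(dim(base), as.integer(target))) base
    else upsample(base, out_dim = target)
  }
  plan <- plan_tiles(dim(img_s), tile_len, scale = scale)
  tiles <- extract_tiles(img_s, plan)
  dets <- lapply(tiles, function(t) {
    d <- detector(t$image, config)
    if (nrow(d) == 0) return(d)
    d$scale <- t$frame$scale
    d$offset_x <- t$frame$offset_x
    d$offset_y <- t$frame$offset_y
    d$source_scale <- scale
    detections_to_fullres(d)
  })
  out <- do.call(rbind, c(list(empty_detections()), dets))
  out$source_scale <- rep(scale, nrow(out))
  rownames(out) <- NULL
  # clip to the full-resolution image (peaks lie inside it, so boxes
  # stay valid)
  if (nrow(out) > 0) {
    out$x_min <- pmax(out$x_min, 0)
    out$y_min <- pmax(out$y_min, 0)
    out$x_max <- pmin(out$x_max, ncol(image))
    out$y_max <- pmin(out$y_max, nrow(image))
  }
  if (!is.null(seam_iou) && nrow(out) > 1) out <- nms(out, seam_iou)
  out
}
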