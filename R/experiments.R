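#' Configuration of an ablation / pipeline run
#'
#' Bundles the geometric and detector settings shared by every arm of
#' an experiment, so that arms differ only in the manipulated factor
#' (asserted via [config_hash()]).
#'
#' @param scales strictly decreasing scale factors in (0, 1], containing
#'   1 (the scale pyramid).
#' @param tile_len systematic-crop strip length in scaled px.
#' @param detector detector configuration ([detector_config()]).
#' @param fusion fusion configuration ([fusion_config()]); its
#'   `n_sources` defaults to `length(scales)`.
#' @param fpi operating point (false positives per image) at which arm
#'   sensitivities are compared.
#' @param seam_iou within-scale seam-NMS IoU (`NULL` disables).
#' @param size_cut lesion-size cut (mm) between the "small" and "large"
#'   breakdown bins (default 10 mm, the sub-centimetre boundary).
#' @return list of class `mammotile_ablation_config`.
#' @export
ablation_config <- function(scales = c(1, 0.5, 0.25), tile_len = 1024,
                            detector = detector_config(),
                            fusion = fusion_config(n_sources = length(scales)),
                            fpi = 0.3, seam_iou = 0.5, size_cut = 10) {
  if (any(scales <= 0) || any(scales > 1) || any(diff(scales) >= 0) ||
      !(1 %in% scales))
    stop("ablation_config: scales must be strictly decreasing in (0,1] and contain 1")
  structure(list(scales = scales, tile_len = as.integer(tile_len),
                 detector = detector, fusion = fusion, fpi = fpi,
                 seam_iou = seam_iou, size_cut = size_cut),
            class = "mammotile_ablation_config")
}

# Per-scale detections for every image of a dataset, optionally with
# resolution negated (all pyramid levels rebuilt from the base_scale
# image).  Returns list[image][scale] of detection tables tagged with
# image_id, in the full-resolution frame.
detect_dataset <- function(dataset, config, base_scale = NULL,
                           detector = dog_detect) {
  lapply(seq_along(dataset$images), function(i) {
    img <- dataset$images[[i]]
    id <- dataset$image_ids[i]
    per_scale <- lapply(config$scales, function(s)
      run_scale(img, s, config$tile_len, detector = detector,
                config = config$detector, seam_iou = config$seam_iou,
                base_scale = base_scale))
    lapply(per_scale, function(d) {
      if (nrow(d) > 0) cbind(image_id = id, d, stringsAsFactors = FALSE)
      else cbind(data.frame(image_id = character(0)), d)
    })
  })
}

# Fuse per-image per-scale detections into one prediction table.
fuse_dataset <- function(per_image, config) {
  rows <- lapply(per_image, function(ps) {
    fused <- fuse_scales(lapply(ps, function(d)
      d[, names(empty_detections()), drop = FALSE]), config$fusion)
    id <- unique(unlist(lapply(ps, function(d) as.character(d$image_id))))
    if (nrow(fused) > 0 && length(id) == 1)
      cbind(image_id = id, fused, stringsAsFactors = FALSE)
    else if (nrow(fused) > 0) stop("fuse_dataset: ambiguous image_id")
    else cbind(data.frame(image_id = character(0)), fused)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pool a single scale's detections across images.
pool_scale <- function(per_image, scale_index) {
  out <- do.call(rbind, lapply(per_image, `[[`, scale_index))
  rownames(out) <- NULL
  out
}

# sensitivity within lesion-size bins at the operating threshold that
# attains the target FPI
sens_by_size <- function(preds, gts, image_ids, fpi, size_cut) {
  cv <- froc(preds, gts, image_ids = image_ids)
  ok <- cv$points$fpi <= fpi
  thr <- if (!any(ok)) Inf else
    min(cv$points$threshold[ok & cv$points$sensitivity ==
                              max(cv$points$sensitivity[ok])])
  m <- match_at_threshold(preds, gts, thr, image_ids = image_ids)
  small <- gts$size_mm < size_cut
  c(small = if (any(small)) mean(m$gt_detected[small]) else NA_real_,
    large = if (any(!small)) mean(m$gt_detected[!small]) else NA_real_)
}

ablation_report <- function(condition, preds, dataset, config) {
  curve <- froc(preds, dataset$gt, image_ids = dataset$image_ids)
  structure(list(condition = condition, curve = curve,
                 sensitivity = sensitivity_at_fpi(curve, config$fpi),
                 fpi = config$fpi,
                 per_size = sens_by_size(preds, dataset$gt,
                                         dataset$image_ids, config$fpi,
                                         config$size_cut),
                 n_images = length(dataset$image_ids),
                 n_gt = nrow(dataset$gt),
                 config_hash = config_hash(unclass(config))),
            class = "mammotile_ablation_report")
}

#' @export
print.mammotile_ablation_report <- function(x, ...) {
  cat(sprintf("<ablation arm '%s': sensitivity %.3f at %.2f FPI (%d images, %d lesions) [config %s]>\n",
              x$condition, x$sensitivity, x$fpi, x$n_images, x$n_gt,
              x$config_hash))
  invisible(x)
}

#' Resolution ablation
#'
#' Compares the standard pipeline (pyramid levels carved from the
#' original full-resolution image) against a resolution-negated arm in
#' which the image is first downsampled to the coarsest scale and every
#' level is rebuilt by upsampling it — same scales, same tiling, same
#' fusion, but no level retains fine detail.  On sub-centimetre
#' lesions the negated arm is expected to underperform.
#'
#' @param dataset a [generate_dataset()] result (or compatible list).
#' @param config an [ablation_config()].
#' @param detector detector-contract function.
#' @return list of two ablation reports: `proposed` and
#'   `resolution_negated`.
#' @export
run_resolution_ablation <- function(dataset, config = ablation_config(),
                                    detector = dog_detect) {
  base <- min(config$scales)
  prop <- detect_dataset(dataset, config, detector = detector)
  neg <- detect_dataset(dataset, config, base_scale = base,
                        detector = detector)
  list(proposed = ablation_report("proposed",
                                  fuse_dataset(prop, config), dataset, config),
       resolution_negated = ablation_report("resolution_negated",
                                            fuse_dataset(neg, config),
                                            dataset, config))
}

#' Scale ablation
#'
#' Compares the full multi-scale pipeline with fusion against a
#' single-scale arm that processes only the full-resolution level with
#' no fusion.  On a mixed-size lesion set the single-scale arm misses
#' masses larger than the detector's band.
#'
#' @inheritParams run_resolution_ablation
#' @return list of reports `proposed` and `single_scale_fullres`.
#' @export
run_scale_ablation <- function(dataset, config = ablation_config(),
                               detector = dog_detect) {
  prop <- detect_dataset(dataset, config, detector = detector)
  full_idx <- which(config$scales == 1)
  single <- pool_scale(prop, full_idx)
  list(proposed = ablation_report("proposed",
                                  fuse_dataset(prop, config), dataset, config),
       single_scale_fullres = ablation_report("single_scale_fullres",
                                              single, dataset, config))
}

#' Context ablation
#'
#' Holds resolution fixed by building every pyramid level from the
#' upsampled coarsest image, then evaluates each scale separately,
#' pre-fusion.  Crops from the coarsest scale see the whole image
#' (maximum context — one tile); crops from the full-size level see the
#' least (many tiles).
#'
#' @inheritParams run_resolution_ablation
#' @return list of ablation reports, one per scale, named
#'   `context_scale_<s>`.
#' @export
run_context_ablation <- function(dataset, config = ablation_config(),
                                 detector = dog_detect) {
  base <- min(config$scales)
  neg <- detect_dataset(dataset, config, base_scale = base,
                        detector = detector)
  reps <- lapply(seq_along(config$scales), function(k)
    ablation_report(sprintf("context_scale_%g", config$scales[k]),
                    pool_scale(neg, k), dataset, config))
  names(reps) <- sprintf("context_scale_%g", config$scales)
  reps
}

#' Per-scale analysis prior to fusion
#'
#' Evaluates each pyramid scale's detections alone and, over lesions
#' hit at exactly one scale, reports the mean annotated lesion size per
#' scale.  With a bounded detector band, lesions caught exclusively at
#' full resolution are expected to be smaller than those caught
#' exclusively at the coarsest scale.
#'
#' A lesion counts as "hit at scale s" if any detection emitted at that
#' scale (i.e. above the detector's own response threshold) hits it.
#'
#' @inheritParams run_resolution_ablation
#' @return data frame with one row per scale: `scale`, `sensitivity`
#'   (at `config$fpi`), `n_exclusive`, `mean_exclusive_size_mm`.
#' @export
per_scale_analysis <- function(dataset, config = ablation_config(),
                               detector = dog_detect) {
  per <- detect_dataset(dataset, config, detector = detector)
  hit_sets <- list()
  sens <- numeric(length(config$scales))
  for (k in seq_along(config$scales)) {
    preds <- pool_scale(per, k)
    cv <- froc(preds, dataset$gt, image_ids = dataset$image_ids)
    sens[k] <- sensitivity_at_fpi(cv, config$fpi)
    m <- match_at_threshold(preds, dataset$gt, -Inf,
                            image_ids = dataset$image_ids)
    hit_sets[[k]] <- m$gt_detected
  }
  n_scales_hit <- Reduce(`+`, hit_sets)
  data.frame(scale = config$scales,
             sensitivity = sens,
             n_exclusive = vapply(hit_sets, function(h)
               sum(h & n_scales_hit == 1), integer(1)),
             mean_exclusive_size_mm = vapply(hit_sets, function(h) {
               ex <- h & n_scales_hit == 1
               if (any(ex)) mean(dataset$gt$size_mm[ex]) else NA_real_
             }, numeric(1)))
}
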