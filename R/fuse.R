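#' Fusion configuration
#'
#' Controls how per-scale prediction sets are combined: Weighted Box
#' Fusion (the default), plain greedy NMS on the pooled set, or NMS
#' preceded by a score floor ("NMS with thresholds").
#'
#' @param method one of `"wbf"`, `"nms"`, `"nms_threshold"`.
#' @param iou_threshold cluster/suppression IoU; defaults to 0.55 for
#'   WBF and 0.5 for the NMS variants (conventional values).
#' @param n_sources expected number of prediction sources `T` (number
#'   of pyramid scales); WBF down-weights clusters supported by fewer
#'   than `T` sources.
#' @param score_floor pre-filter: detections below this score are
#'   dropped before fusion (0 disables).
#' @param score_rescale WBF score rescaling variant: `"min"` for
#'   `min(N, T) / T` (default) or `"count"` for `N / T` (capped at 1).
#' @return list of class `mammotile_fusion_config`.
#' @export
fusion_config <- function(method = c("wbf", "nms", "nms_threshold"),
                          iou_threshold = NULL, n_sources = 3,
                          score_floor = 0,
                          score_rescale = c("min", "count")) {
  method <- match.arg(method)
  score_rescale <- match.arg(score_rescale)
  iou_threshold <- iou_threshold %||% if (method == "wbf") 0.55 else 0.5
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("fusion_config: iou_threshold must be in (0, 1)")
  if (n_sources < 1) stop("fusion_config: n_sources must be >= 1")
  structure(list(method = method, iou_threshold = iou_threshold,
                 n_sources = as.integer(n_sources),
                 score_floor = score_floor, score_rescale = score_rescale),
            class = "mammotile_fusion_config")
}

# deterministic processing order: score desc, then larger area, then
# original index
det_order <- function(det) {
  area <- (det$x_max - det$x_min) * (det$y_max - det$y_min)
  order(-det$score, -area, seq_len(nrow(det)))
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scored remaining box and discards every
#' remaining box whose IoU with it exceeds the threshold.  Ties in
#' score are broken by larger area, then input order, so the result is
#' deterministic.  The output is a subset of the input, sorted by score
#' descending.
#'
#' @param det detection table (all rows in the same frame).
#' @param iou_threshold suppression IoU in (0, 1).
#' @return the surviving detections.
#' @export
nms <- function(det, iou_threshold = 0.5) {
  n <- nrow(det)
  if (n <= 1) return(det)
  ord <- det_order(det)
  d <- det[ord, , drop = FALSE]
  M <- iou_matrix(d, d)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    sup <- which(alive & M[i, ] > iou_threshold)
    alive[sup] <- FALSE
    alive[i] <- FALSE
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted Box Fusion
#'
#' Combines overlapping boxes from several prediction sources (here,
#' pyramid scales) into confidence-weighted average boxes rather than
#' discarding all but one.  All detections are processed in descending
#' score order; each is matched by IoU against the running list of
#' fused cluster boxes (best IoU above the threshold wins) and either
#' joins that cluster or founds a new one.  A cluster's fused
#' coordinates are the score-weighted means of its members' coordinates
#' and its fused score is the mean member score rescaled by
#' `min(N, T) / T` (`N` members, `T` expected sources), so boxes
#' corroborated by fewer scales are down-weighted.
#'
#' @param per_source list of detection tables, one per source, all in
#'   the full-resolution frame (a single pooled table is also accepted).
#' @param config a [fusion_config()] with `method = "wbf"`.
#' @return fused detection table, sorted by fused score descending,
#'   with a `cluster_size` column.
#' @export
wbf <- function(per_source, config = fusion_config("wbf")) {
  if (is.data.frame(per_source)) per_source <- list(per_source)
  pool <- do.call(rbind, c(list(empty_detections()),
                           lapply(per_source, function(d)
                             d[, names(empty_detections()), drop = FALSE])))
  rownames(pool) <- NULL
  if (nrow(pool) > 0 && config$score_floor > 0)
    pool <- pool[pool$score >= config$score_floor, , drop = FALSE]
  n <- nrow(pool)
  if (n == 0) {
    out <- empty_detections()
    out$cluster_size <- integer(0)
    return(out)
  }
  pool <- pool[det_order(pool), , drop = FALSE]
  coords <- as.matrix(pool[, c("x_min", "y_min", "x_max", "y_max")])
  scores <- pool$score

  fused <- matrix(NA_real_, 0, 4)
  members <- list()
  for (i in seq_len(n)) {
    best <- 0; best_j <- 0L
    if (nrow(fused) > 0) {
      fdf <- data.frame(x_min = fused[, 1], y_min = fused[, 2],
                        x_max = fused[, 3], y_max = fused[, 4])
      bi <- data.frame(x_min = coords[i, 1], y_min = coords[i, 2],
                       x_max = coords[i, 3], y_max = coords[i, 4])
      ious <- iou_matrix(fdf, bi)[, 1]
      best_j <- which.max(ious)
      best <- ious[best_j]
    }
    if (best > config$iou_threshold) {
      members[[best_j]] <- c(members[[best_j]], i)
      m <- members[[best_j]]
      w <- scores[m]
      fused[best_j, ] <- colSums(coords[m, , drop = FALSE] * w) / sum(w)
    } else {
      fused <- rbind(fused, coords[i, ])
      members[[length(members) + 1]] <- i
    }
  }
  Tn <- config$n_sources
  nmem <- vapply(members, length, integer(1))
  mscore <- vapply(members, function(m) mean(scores[m]), numeric(1))
  rescale_f <- if (config$score_rescale == "min") pmin(nmem, Tn) / Tn
  else pmin(1, nmem / Tn)
  src <- vapply(members, function(m) {
    s <- unique(pool$source_scale[m])
    if (length(s) == 1) s else NA_real_
  }, numeric(1))
  out <- data.frame(x_min = fused[, 1], y_min = fused[, 2],
                    x_max = fused[, 3], y_max = fused[, 4],
                    score = mscore * rescale_f,
                    scale = 1, offset_x = 0, offset_y = 0,
                    source_scale = src, cluster_size = nmem)
  out <- out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine per-scale prediction sets
#'
#' Dispatches to [wbf()], pooled [nms()], or score-floored NMS
#' according to the fusion configuration.  Inputs must already be in
#' the full-resolution frame (one table per pyramid scale, in scale
#' order); output is sorted by score descending.
#'
#' @param per_scale list of detection tables, one per scale.
#' @param config a [fusion_config()].
#' @return fused detection table in the full-resolution frame.
#' @export
fuse_scales <- function(per_scale, config = fusion_config()) {
  stopifnot(inherits(config, "mammotile_fusion_config"))
  if (config$method == "wbf") return(wbf(per_scale, config))
  pool <- do.call(rbind, c(list(empty_detections()),
                           lapply(per_scale, function(d)
                             d[, names(empty_detections()), drop = FALSE])))
  rownames(pool) <- NULL
  if (config$method == "nms_threshold" && nrow(pool) > 0)
    pool <- pool[pool$score >= config$score_floor, , drop = FALSE]
  nms(pool, config$iou_threshold)
}
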