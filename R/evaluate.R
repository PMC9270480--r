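#' Center-in-box hit criterion
#'
#' A prediction detects a lesion iff the center of the predicted box
#' falls anywhere inside the ground-truth box — the standard matching
#' rule in mammography CAD (overlap alone does not count).
#'
#' @param pred,gt box tables of equal row count (or one row, recycled).
#' @return logical vector.
#' @export
is_hit <- function(pred, gt) {
  ctr <- box_center(pred)
  ctr[, "cx"] >= gt$x_min & ctr[, "cx"] < gt$x_max &
    ctr[, "cy"] >= gt$y_min & ctr[, "cy"] < gt$y_max
}

# n_pred x n_gt logical matrix: center of pred i inside gt j
hit_matrix <- function(preds, gts) {
  np <- nrow(preds); ng <- nrow(gts)
  if (np == 0 || ng == 0) return(matrix(logical(0), np, ng))
  ctr <- box_center(preds)
  cx <- ctr[, "cx"]; cy <- ctr[, "cy"]
  outer(cx, gts$x_min, `>=`) & outer(cx, gts$x_max, `<`) &
    outer(cy, gts$y_min, `>=`) & outer(cy, gts$y_max, `<`)
}

check_image_ids <- function(preds, gts, image_ids) {
  if (is.null(image_ids))
    image_ids <- sort(unique(c(as.character(preds$image_id),
                               as.character(gts$image_id))))
  bad <- setdiff(unique(as.character(preds$image_id)), image_ids)
  if (length(bad) > 0)
    stop("predictions reference unknown image_id(s): ",
         paste(bad, collapse = ", "))
  bad <- setdiff(unique(as.character(gts$image_id)), image_ids)
  if (length(bad) > 0)
    stop("ground truth references unknown image_id(s): ",
         paste(bad, collapse = ", "))
  image_ids
}

#' Match predictions to ground truth at a score threshold
#'
#' Predictions with `score >= threshold` are kept.  A ground-truth box
#' is detected if at least one kept prediction hits it (center rule); a
#' kept prediction hitting no ground truth is a false positive.  By
#' default several predictions hitting one lesion count as a single hit
#' and no false positives, and one prediction whose center lies in
#' several (nested/overlapping) ground-truth boxes credits all of them;
#' both conventions are switchable.
#'
#' Images with no lesions still contribute to the FPI denominator,
#' which is why the image roster can be passed explicitly.
#'
#' @param preds prediction table with columns `image_id`, box corners
#'   and `score` (full-resolution frame).
#' @param gts ground-truth table with `image_id` and box corners.
#' @param threshold score cut-off.
#' @param image_ids full image roster; default: ids present in either
#'   table.
#' @param dup_as_fp count extra predictions on an already-hit lesion as
#'   false positives (default `FALSE`).
#' @param multi_gt allow one prediction to credit several lesions
#'   (default `TRUE`).
#' @return list with counts (`n_gt`, `n_hit`, `n_fp`, `n_images`),
#'   `sensitivity`, `fpi`, per-image false-positive counts `fp_per_image`
#'   and the per-row `gt_detected` flags.
#' @export
match_at_threshold <- function(preds, gts, threshold, image_ids = NULL,
                               dup_as_fp = FALSE, multi_gt = TRUE) {
  image_ids <- check_image_ids(preds, gts, image_ids)
  kept <- preds[preds$score >= threshold, , drop = FALSE]
  gt_detected <- rep(FALSE, nrow(gts))
  fp_per_image <- stats::setNames(rep(0L, length(image_ids)), image_ids)
  for (id in unique(as.character(kept$image_id))) {
    p <- kept[kept$image_id == id, , drop = FALSE]
    gidx <- which(as.character(gts$image_id) == id)
    H <- hit_matrix(p, gts[gidx, , drop = FALSE])
    if (!multi_gt && nrow(p) > 0 && length(gidx) > 0) {
      # credit only the smallest-area gt containing the center
      areas <- (gts$x_max[gidx] - gts$x_min[gidx]) *
        (gts$y_max[gidx] - gts$y_min[gidx])
      for (i in seq_len(nrow(p))) {
        hits <- which(H[i, ])
        if (length(hits) > 1) {
          keep_j <- hits[which.min(areas[hits])]
          H[i, ] <- FALSE
          H[i, keep_j] <- TRUE
        }
      }
    }
    hit_any_gt <- if (length(gidx) > 0) apply(H, 2, any) else logical(0)
    pred_is_hit <- if (length(gidx) > 0) apply(H, 1, any) else
      rep(FALSE, nrow(p))
    gt_detected[gidx] <- hit_any_gt
    n_fp <- if (dup_as_fp) {
      # first hitting prediction per gt is credited; the rest are FPs
      credited <- rep(FALSE, nrow(p))
      for (j in seq_along(gidx)) {
        hi <- which(H[, j])
        if (length(hi) > 0) credited[hi[1]] <- TRUE
      }
      sum(!credited)
    } else sum(!pred_is_hit)
    fp_per_image[id] <- n_fp
  }
  n_gt <- nrow(gts)
  list(n_gt = n_gt, n_hit = sum(gt_detected), n_fp = sum(fp_per_image),
       n_images = length(image_ids),
       sensitivity = if (n_gt > 0) sum(gt_detected) / n_gt else NA_real_,
       fpi = sum(fp_per_image) / length(image_ids),
       fp_per_image = fp_per_image, gt_detected = gt_detected)
}

#' Free-response ROC curve
#'
#' Sweeps the threshold over the sorted unique prediction scores
#' (descending, preceded by +Inf) and records false positives per image
#' against sensitivity at each, giving the exact step curve with no
#' binning artifacts.  Thresholds are strictly decreasing; FPI and
#' sensitivity are non-decreasing along the curve.
#'
#' @inheritParams match_at_threshold
#' @return object of class `mammotile_froc`: list with `points` (data
#'   frame `threshold,fpi,sensitivity`), `n_images`, `n_gt`.
#' @export
froc <- function(preds, gts, image_ids = NULL, dup_as_fp = FALSE,
                 multi_gt = TRUE) {
  image_ids <- check_image_ids(preds, gts, image_ids)
  if (length(image_ids) < 1) stop("froc: need at least one image")
  if (nrow(gts) == 0)
    stop("froc: zero ground-truth lesions; sensitivity undefined")
  thresholds <- c(Inf, sort(unique(preds$score), decreasing = TRUE))
  pts <- lapply(thresholds, function(t) {
    m <- match_at_threshold(preds, gts, t, image_ids = image_ids,
                            dup_as_fp = dup_as_fp, multi_gt = multi_gt)
    data.frame(threshold = t, fpi = m$fpi, sensitivity = m$sensitivity)
  })
  structure(list(points = do.call(rbind, pts), n_images = length(image_ids),
                 n_gt = nrow(gts)),
            class = "mammotile_froc")
}

#' @export
print.mammotile_froc <- function(x, ...) {
  cat(sprintf("<FROC: %d image(s), %d lesion(s), %d point(s); max sensitivity %.3f at %.3f FPI>\n",
              x$n_images, x$n_gt, nrow(x$points),
              max(x$points$sensitivity), max(x$points$fpi)))
  invisible(x)
}

#' Sensitivity at an FPI operating point
#'
#' Conservative step-function readout: the maximum sensitivity among
#' curve points with `fpi <= target_fpi` (0 if the curve starts above
#' the target).  No interpolation, so the readout never over-credits.
#'
#' @param curve a [froc()] result.
#' @param target_fpi operating point in false positives per image.
#' @return sensitivity in `[0, 1]`.
#' @export
sensitivity_at_fpi <- function(curve, target_fpi) {
  stopifnot(inherits(curve, "mammotile_froc"), target_fpi >= 0)
  ok <- curve$points$fpi <= target_fpi
  if (!any(ok)) return(0)
  max(curve$points$sensitivity[ok])
}

#' Plot an FROC curve
#'
#' @param x a [froc()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mammotile_froc <- function(x, ...) {
  graphics::plot(x$points$fpi, x$points$sensitivity, type = "s",
                 xlab = "False positives per image",
                 ylab = "Sensitivity", ylim = c(0, 1), ...)
  invisible(x)
}
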