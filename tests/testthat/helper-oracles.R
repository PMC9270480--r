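# Independent brute-force reference implementations used as oracles.
# These are deliberately written as plain, slow loops with no code
# shared with the package internals.

oracle_iou <- function(a, b) {
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  un <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  if (un <= 0) 0 else inter / un
}

# exhaustive greedy NMS: repeatedly pick the best remaining box by
# (score, area, index) and delete everything overlapping it
oracle_nms <- function(det, thr) {
  remaining <- seq_len(nrow(det))
  kept <- integer(0)
  area <- (det$x_max - det$x_min) * (det$y_max - det$y_min)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (i in remaining)
      if (det$score[i] > det$score[best] ||
          (det$score[i] == det$score[best] && area[i] > area[best]) ||
          (det$score[i] == det$score[best] && area[i] == area[best] &&
           i < best)) best <- i
    kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
    drop <- c()
    for (i in remaining)
      if (oracle_iou(det[best, ], det[i, ]) > thr) drop <- c(drop, i)
    remaining <- setdiff(remaining, drop)
  }
  det[kept, , drop = FALSE]
}

# straightforward weighted-box-fusion reference: same stated rules,
# independently coded (explicit cluster lists, no vectorization)
oracle_wbf <- function(det, thr, n_sources, score_rescale = "min") {
  area <- (det$x_max - det$x_min) * (det$y_max - det$y_min)
  ord <- order(-det$score, -area, seq_len(nrow(det)))
  clusters <- list()
  for (i in ord) {
    ious <- numeric(length(clusters))
    for (j in seq_along(clusters)) {
      m <- clusters[[j]]
      w <- det$score[m]
      fb <- list(x_min = sum(det$x_min[m] * w) / sum(w),
                 y_min = sum(det$y_min[m] * w) / sum(w),
                 x_max = sum(det$x_max[m] * w) / sum(w),
                 y_max = sum(det$y_max[m] * w) / sum(w))
      ious[j] <- oracle_iou(fb, det[i, ])
    }
    if (length(ious) > 0 && max(ious) > thr) {
      j <- which.max(ious)
      clusters[[j]] <- c(clusters[[j]], i)
    } else clusters[[length(clusters) + 1]] <- i
  }
  rows <- lapply(clusters, function(m) {
    w <- det$score[m]
    n <- length(m)
    f <- if (score_rescale == "min") min(n, n_sources) / n_sources
    else min(1, n / n_sources)
    data.frame(x_min = sum(det$x_min[m] * w) / sum(w),
               y_min = sum(det$y_min[m] * w) / sum(w),
               x_max = sum(det$x_max[m] * w) / sum(w),
               y_max = sum(det$y_max[m] * w) / sum(w),
               score = mean(w) * f, n = n)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}

# exhaustive FROC: for every threshold, re-match every prediction
# against every ground-truth box from scratch
oracle_match <- function(preds, gts, thr, image_ids) {
  n_hit <- 0; n_fp <- 0
  detected <- rep(FALSE, nrow(gts))
  for (id in image_ids) {
    p <- preds[preds$image_id == id & preds$score >= thr, , drop = FALSE]
    gi <- which(gts$image_id == id)
    for (k in seq_len(nrow(p))) {
      cx <- (p$x_min[k] + p$x_max[k]) / 2
      cy <- (p$y_min[k] + p$y_max[k]) / 2
      hit <- FALSE
      for (j in gi) {
        if (cx >= gts$x_min[j] && cx < gts$x_max[j] &&
            cy >= gts$y_min[j] && cy < gts$y_max[j]) {
          hit <- TRUE
          detected[j] <- TRUE
        }
      }
      if (!hit) n_fp <- n_fp + 1
    }
  }
  list(sensitivity = sum(detected) / nrow(gts),
       fpi = n_fp / length(image_ids), n_hit = sum(detected), n_fp = n_fp)
}

oracle_froc <- function(preds, gts, image_ids) {
  thrs <- c(Inf, sort(unique(preds$score), decreasing = TRUE))
  do.call(rbind, lapply(thrs, function(t) {
    m <- oracle_match(preds, gts, t, image_ids)
    data.frame(threshold = t, fpi = m$fpi, sensitivity = m$sensitivity)
  }))
}

# random-instance generators (all take an explicit seed)
random_boxes <- function(n, seed, lim = 100, max_side = 30) {
  set.seed(seed)
  x0 <- runif(n, 0, lim - max_side)
  y0 <- runif(n, 0, lim - max_side)
  data.frame(x_min = x0, y_min = y0,
             x_max = x0 + runif(n, 1, max_side),
             y_max = y0 + runif(n, 1, max_side))
}

random_detections <- function(n, seed, lim = 100) {
  b <- random_boxes(n, seed, lim)
  set.seed(seed + 1)
  detections(b, runif(n))
}

random_eval_instance <- function(seed) {
  set.seed(seed)
  ids <- paste0("img", 1:4)
  n_gt <- sample(1:3, 1)
  gt <- data.frame(image_id = sample(ids, n_gt, replace = TRUE),
                   x_min = runif(n_gt, 0, 80), y_min = runif(n_gt, 0, 80))
  gt$x_max <- gt$x_min + runif(n_gt, 5, 20)
  gt$y_max <- gt$y_min + runif(n_gt, 5, 20)
  n_p <- sample(0:8, 1)
  p <- data.frame(image_id = sample(ids, n_p, replace = TRUE),
                  x_min = runif(n_p, 0, 90), y_min = runif(n_p, 0, 90))
  p$x_max <- p$x_min + runif(n_p, 2, 15)
  p$y_max <- p$y_min + runif(n_p, 2, 15)
  p$score <- runif(n_p)
  list(preds = p, gts = gt, ids = ids)
}

# independent center-rule matrix used by conservation checks
hit_matrix_ref <- function(preds, gts) {
  H <- matrix(FALSE, nrow(preds), nrow(gts))
  for (i in seq_len(nrow(preds))) for (j in seq_len(nrow(gts))) {
    if (preds$image_id[i] != gts$image_id[j]) next
    cx <- (preds$x_min[i] + preds$x_max[i]) / 2
    cy <- (preds$y_min[i] + preds$y_max[i]) / 2
    H[i, j] <- cx >= gts$x_min[j] && cx < gts$x_max[j] &&
      cy >= gts$y_min[j] && cy < gts$y_max[j]
  }
  H
}
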