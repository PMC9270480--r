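#' Otsu's automatic global threshold
#'
#' Maximizes between-class variance on a 256-bin histogram; robust on
#' the bimodal histograms of mammograms (dark field vs breast tissue).
#'
#' @param image numeric matrix.
#' @param n_bins histogram resolution.
#' @return threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  rng <- range(image)
  if (diff(rng) == 0) return(rng[2])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(image, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Breast foreground mask
#'
#' Thresholds the image (Otsu by default) and keeps the largest
#' 4-connected component of above-threshold pixels.  An all-background
#' image yields an all-`FALSE` mask; the caller decides how to react.
#'
#' @param image numeric matrix.
#' @param threshold fixed threshold overriding the automatic one.
#' @return logical matrix of the same shape.
#' @export
foreground_mask <- function(image, threshold = NULL) {
  if (length(image) == 0) stop("foreground_mask: empty image")
  thr <- threshold %||% otsu_threshold(image)
  above <- image > thr
  if (!any(above)) return(above)
  lab <- label_components_cpp(above)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Crop an image to its breast region
#'
#' Crops to the tight bounding box of the foreground mask, expanded by
#' `margin` pixels and clipped to the image bounds.  The returned crop
#' record lets downstream boxes be mapped back to the raw frame exactly
#' (raw coordinate = cropped coordinate + offset).
#'
#' @param image numeric matrix.
#' @param margin expansion of the tight box in px (default 16; set 0
#'   for exactness tests).
#' @param mask optional precomputed foreground mask.
#' @return list with `image` (the crop) and `record`, a list
#'   `(offset_x, offset_y, height, width, raw_height, raw_width)`.
#' @export
crop_to_breast <- function(image, margin = 16, mask = NULL) {
  mask <- mask %||% foreground_mask(image)
  if (!any(mask)) stop("crop_to_breast: empty foreground mask")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  y0 <- max(1L, rows[1] - margin); y1 <- min(nrow(image), rows[2] + margin)
  x0 <- max(1L, cols[1] - margin); x1 <- min(ncol(image), cols[2] + margin)
  list(image = image[y0:y1, x0:x1, drop = FALSE],
       record = list(offset_x = x0 - 1L, offset_y = y0 - 1L,
                     height = y1 - y0 + 1L, width = x1 - x0 + 1L,
                     raw_height = nrow(image), raw_width = ncol(image)))
}

#' Shift boxes from the cropped frame back to the raw-image frame
#'
#' @param df box table in the cropped frame.
#' @param record a crop record from [crop_to_breast()].
#' @return the box table in the raw frame.
#' @export
uncrop_boxes <- function(df, record) {
  remap_to_fullres(df, frame(1, record$offset_x, record$offset_y))
}
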