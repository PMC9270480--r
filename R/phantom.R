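#' Convert a physical size in millimetres to pixels
#'
#' Digital mammograms have detector pixel pitches in the 50-100 micron
#' range; this links a lesion's physical diameter to its pixel extent.
#'
#' @param size_mm physical size in millimetres (> 0).
#' @param spacing_um pixel spacing in microns (> 0).
#' @return size in pixels (float): `size_mm * 1000 / spacing_um`.
#' @examples
#' mm_to_px(10, 100)  # 100 px
#' mm_to_px(5.8, 70)  # ~82.9 px
#' @export
mm_to_px <- function(size_mm, spacing_um) {
  if (any(!is.finite(size_mm)) || any(size_mm <= 0))
    stop("mm_to_px: size_mm must be positive")
  if (any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("mm_to_px: spacing_um must be positive")
  size_mm * 1000 / spacing_um
}

#' Specification of one synthetic mammography phantom
#'
#' The phantom stands in for annotated full-field digital mammograms:
#' a half-elliptical breast-shaped foreground flush with one lateral
#' image edge, filled with low-pass-filtered parenchyma-like texture on
#' a near-zero background, with bright raised-cosine mass lesions of
#' given physical diameter and exact tight ground-truth boxes.
#'
#' Defaults follow the nominal acquisition geometry of full-field
#' digital mammography: 3328 x 4096 px images at 70 micron pixel
#' spacing.  The sub-centimetre lesion regime of interest has mean
#' diameter around 5.8 mm.
#'
#' @param height,width image dimensions in pixels.
#' @param pixel_spacing detector pixel pitch in microns.
#' @param n_lesions number of masses to insert (0 allowed).
#' @param lesion_diameters physical diameters in mm, recycled to
#'   `n_lesions`.
#' @param lesion_contrast peak intensity boost at the lesion centre as a
#'   fraction of the 16-bit dynamic range, in (0, 1].
#' @param background_texture_sigma Gaussian low-pass radius (px) of the
#'   parenchymal texture.
#' @param spiculation if `TRUE`, add 4-8 thin radial line segments of
#'   length 1-2 lesion radii to each mass margin.
#' @param seed integer RNG seed; output is bit-identical for a fixed
#'   spec.
#' @return a list of class `mammotile_phantom_spec`.
#' @export
phantom_spec <- function(height = 4096, width = 3328, pixel_spacing = 70,
                         n_lesions = 3, lesion_diameters = 5.8,
                         lesion_contrast = 0.3,
                         background_texture_sigma = 8,
                         spiculation = FALSE, seed = 1) {
  if (height <= 0 || width <= 0) stop("phantom_spec: dimensions must be positive")
  if (pixel_spacing <= 0) stop("phantom_spec: pixel_spacing must be positive")
  if (n_lesions < 0) stop("phantom_spec: n_lesions must be >= 0")
  if (any(lesion_diameters <= 0)) stop("phantom_spec: lesion diameters must be positive")
  if (lesion_contrast <= 0 || lesion_contrast > 1)
    stop("phantom_spec: lesion_contrast must be in (0, 1]")
  lesion_diameters <- if (n_lesions > 0)
    rep_len(as.numeric(lesion_diameters), n_lesions) else numeric(0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 pixel_spacing = as.numeric(pixel_spacing),
                 n_lesions = as.integer(n_lesions),
                 lesion_diameters = lesion_diameters,
                 lesion_contrast = as.numeric(lesion_contrast),
                 background_texture_sigma = as.numeric(background_texture_sigma),
                 spiculation = isTRUE(spiculation),
                 seed = as.integer(seed)),
            class = "mammotile_phantom_spec")
}

DYNAMIC_RANGE <- 65535

# Analytic membership test for the half-ellipse breast model.  The
# breast is flush with the left (side = 1) or right (side = -1) image
# edge; (a, b) are the semi-axes in px, cy the vertical centre.
breast_params <- function(spec) {
  # semi-axes drawn so the foreground occupies ~40-70% of the image and
  # spans the full long axis (as the breast does on a mammogram: the
  # vertical semi-axis exceeds H/2, so the ellipse is clipped at the
  # top and bottom edges)
  a <- stats::runif(1, 0.62, 0.80) * spec$width
  b <- stats::runif(1, 0.52, 0.58) * spec$height
  side <- sample(c(1L, -1L), 1)
  list(a = a, b = b, cy = spec$height / 2, side = side)
}

breast_inside <- function(x, y, bp, width) {
  xx <- if (bp$side == 1L) x else width - x
  (xx / bp$a)^2 + ((y - bp$cy) / bp$b)^2 <= 1
}

breast_mask_matrix <- function(bp, height, width) {
  x <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  y <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  breast_inside(x, y, bp, width)
}

# Raised-cosine tapered disc: intensity boost contrast*DR at the centre,
# falling smoothly to 0 at radius R.  Soft edges mimic mammographic
# masses and give the detector smoothly varying scores.
draw_lesion <- function(img, cx, cy, radius, contrast) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(1L, floor(cx - radius)); x1 <- min(w, ceiling(cx + radius))
  y0 <- max(1L, floor(cy - radius)); y1 <- min(h, ceiling(cy + radius))
  xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
  r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  boost <- ifelse(r < radius,
                  contrast * DYNAMIC_RANGE * 0.5 * (1 + cos(pi * r / radius)), 0)
  img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] + boost
  img
}

draw_spiculations <- function(img, cx, cy, radius, contrast) {
  n_spic <- sample(4:8, 1)
  angles <- stats::runif(n_spic, 0, 2 * pi)
  lens <- stats::runif(n_spic, 1, 2) * radius
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(n_spic)) {
    tt <- seq(0.8 * radius, 0.8 * radius + lens[i], by = 0.5)
    px <- floor(cx + tt * cos(angles[i])) + 1L
    py <- floor(cy + tt * sin(angles[i])) + 1L
    taper <- 1 - seq(0, 1, length.out = length(tt))
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    idx <- cbind(py[ok], px[ok])
    img[idx] <- img[idx] + 0.5 * contrast * DYNAMIC_RANGE * taper[ok]
  }
  img
}

#' Generate one synthetic mammography phantom
#'
#' Deterministic given the spec (including its seed): two calls with the
#' same spec produce bit-identical images and ground truth.  Lesion
#' centres are placed by rejection sampling inside the breast (discs
#' must fit entirely inside the foreground, with a minimum pairwise
#' centre distance of 3 lesion diameters, up to 1000 retries per
#' lesion).
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `mammotile_phantom` with elements
#'   \describe{
#'     \item{image}{numeric matrix (rows = y), integer values in the
#'       16-bit range `[0, 65535]`.}
#'     \item{gt}{data frame of tight ground-truth boxes
#'       (`x_min,y_min,x_max,y_max,size_mm`) in the full-resolution
#'       frame.}
#'     \item{breast_mask}{logical matrix of the foreground model.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "mammotile_phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    bp <- breast_params(spec)
    mask <- breast_mask_matrix(bp, h, w)

    # parenchymal texture: low-pass-filtered white noise in a mid-gray band
    noise <- matrix(stats::rnorm(h * w), h, w)
    tex <- gaussian_blur_cpp(noise, spec$background_texture_sigma)
    tex <- tex / max(stats::sd(tex), 1e-12)
    img <- matrix(0, h, w)
    img[mask] <- clamp(0.35 * DYNAMIC_RANGE + 0.03 * DYNAMIC_RANGE * tex[mask],
                       0.15 * DYNAMIC_RANGE, 0.60 * DYNAMIC_RANGE)
    # faint dark-field noise outside the breast (stays ~0)
    img[!mask] <- abs(stats::rnorm(sum(!mask), 0, 60))

    radii <- mm_to_px(spec$lesion_diameters, spec$pixel_spacing) / 2
    centers <- matrix(numeric(0), 0, 2)
    gt <- data.frame(x_min = numeric(0), y_min = numeric(0),
                     x_max = numeric(0), y_max = numeric(0),
                     size_mm = numeric(0))
    for (i in seq_len(spec$n_lesions)) {
      R <- radii[i]
      placed <- FALSE
      for (try in seq_len(1000)) {
        cx <- stats::runif(1, R + 1, w - R - 1)
        cy <- stats::runif(1, R + 1, h - R - 1)
        # disc must fit inside the breast: test 8 boundary points analytically
        ang <- seq(0, 2 * pi, length.out = 9)[-9]
        if (!all(breast_inside(cx + (R + 2) * cos(ang),
                               cy + (R + 2) * sin(ang), bp, w))) next
        if (nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
          mind <- 3 * pmax(2 * R, 2 * radii[seq_len(nrow(centers))])
          if (any(d < mind)) next
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("generate_phantom: could not place lesion ", i,
             " after 1000 retries (breast region too small)")
      centers <- rbind(centers, c(cx, cy))
      img <- draw_lesion(img, cx, cy, R, spec$lesion_contrast)
      if (spec$spiculation)
        img <- draw_spiculations(img, cx, cy, R, spec$lesion_contrast)
      gt <- rbind(gt, data.frame(x_min = cx - R, y_min = cy - R,
                                 x_max = cx + R, y_max = cy + R,
                                 size_mm = spec$lesion_diameters[i]))
    }
    img <- round(clamp(img, 0, DYNAMIC_RANGE))
    structure(list(image = img, gt = gt, breast_mask = mask, spec = spec),
              class = "mammotile_phantom")
  })
}

#' @export
print.mammotile_phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d px, %d lesion(s), seed %d>\n",
              x$spec$height, x$spec$width, nrow(x$gt), x$spec$seed))
  invisible(x)
}

#' Generate a seeded phantom dataset with a single ground-truth table
#'
#' Builds `n_images` phantoms whose per-image seeds are derived
#' deterministically from `seed`; lesion diameters are drawn per lesion
#' from `size_mix`.  The combined ground truth carries one row per
#' lesion keyed by `image_id`.
#'
#' @param n_images number of phantoms (> 0).
#' @param size_mix numeric vector of candidate lesion diameters (mm);
#'   sampled uniformly with replacement.  A single value gives a
#'   fixed-size dataset.
#' @param seed master RNG seed.
#' @param base a [phantom_spec()] template supplying every field other
#'   than `lesion_diameters` and `seed`.
#' @return list with elements `images` (named list of matrices), `gt`
#'   (data frame `image_id,x_min,y_min,x_max,y_max,size_mm`),
#'   `image_ids`, and `phantoms` (the full phantom objects).
#' @export
generate_dataset <- function(n_images, size_mix, seed = 1,
                             base = phantom_spec()) {
  if (n_images <= 0) stop("generate_dataset: n_images must be positive")
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max, n_images),
    diam = matrix(as.numeric(size_mix)[sample.int(length(size_mix),
                                                  n_images * base$n_lesions,
                                                  replace = TRUE)],
                  nrow = n_images)
  ))
  ids <- sprintf("phantom_%03d", seq_len(n_images))
  phantoms <- vector("list", n_images)
  gt_all <- list()
  for (i in seq_len(n_images)) {
    sp <- base
    sp$seed <- draws$seeds[i]
    sp$lesion_diameters <- if (base$n_lesions > 0)
      draws$diam[i, ] else numeric(0)
    ph <- generate_phantom(sp)
    phantoms[[i]] <- ph
    if (nrow(ph$gt) > 0)
      gt_all[[length(gt_all) + 1]] <- cbind(image_id = ids[i], ph$gt,
                                            stringsAsFactors = FALSE)
  }
  gt <- if (length(gt_all) > 0) do.call(rbind, gt_all) else
    data.frame(image_id = character(0), x_min = numeric(0),
               y_min = numeric(0), x_max = numeric(0), y_max = numeric(0),
               size_mm = numeric(0))
  rownames(gt) <- NULL
  images <- lapply(phantoms, `[[`, "image")
  names(images) <- ids
  list(images = images, gt = gt, image_ids = ids, phantoms = phantoms)
}
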