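#' Rescale an image to a pyramid level
#'
#' Area-average (anti-aliased) resampling to `round(scale * dims)`.
#' Scale 1 returns the input unchanged, bit for bit.
#'
#' @param image numeric matrix.
#' @param scale factor in `(0, 1]`.
#' @return resampled matrix.
#' @export
rescale <- function(image, scale) {
  if (!is.finite(scale) || scale <= 0 || scale > 1)
    stop("rescale: scale must be in (0, 1]")
  if (scale == 1) return(image)
  resize_area_cpp(image, max(1L, round(scale * nrow(image))),
                  max(1L, round(scale * ncol(image))))
}

#' Upsample an image by a factor >= 1
#'
#' Bilinear interpolation to `round(factor * dims)` (or to explicit
#' target dimensions).  Used by the resolution-negation harness that
#' rebuilds the upper pyramid levels from the coarsest one.
#'
#' @param image numeric matrix.
#' @param factor upsampling factor (>= 1); ignored when `out_dim` given.
#' @param out_dim optional explicit `(height, width)` target.
#' @return resampled matrix.
#' @export
upsample <- function(image, factor = 1, out_dim = NULL) {
  if (is.null(out_dim)) {
    if (!is.finite(factor) || factor < 1)
      stop("upsample: factor must be >= 1")
    if (factor == 1) return(image)
    out_dim <- c(round(factor * nrow(image)), round(factor * ncol(image)))
  }
  resize_bilinear_cpp(image, as.integer(out_dim[1]), as.integer(out_dim[2]))
}

#' Systematic full-coverage tile plan
#'
#' Tiles are full-width strips along the image's long axis, of length
#' `tile_len` (1024 px at the nominal geometry, i.e. 0.25 of the 4096-px
#' long axis).  Offsets advance by `tile_len`; the final strip is
#' anchored at `L - tile_len` so it may overlap its predecessor but no
#' pixel is ever left uncovered.  If the long axis is shorter than
#' `tile_len` a single full-image tile is produced — at the 0.25X scale
#' this is the maximum-context crop that sees the whole breast.
#'
#' @param scaled_size `(height, width)` of the scaled image in px.
#' @param tile_len strip length along the long axis (> 0).
#' @param scale pyramid scale recorded in the plan (for frames).
#' @return a list of class `mammotile_tileplan` with elements `scale`,
#'   `size`, `tile_len` and `tiles`, a data frame
#'   `(offset_x, offset_y, width, height)`.
#' @examples
#' plan_tiles(c(4096, 3328), 1024)$tiles  # 4 strips at y = 0,1024,2048,3072
#' @export
plan_tiles <- function(scaled_size, tile_len, scale = 1) {
  if (tile_len <= 0) stop("plan_tiles: tile_len must be positive")
  h <- as.integer(scaled_size[1]); w <- as.integer(scaled_size[2])
  long_is_y <- h >= w
  L <- if (long_is_y) h else w
  S <- if (long_is_y) w else h
  if (L <= tile_len) {
    offs <- 0L
    len <- L
  } else {
    n <- ceiling(L / tile_len)
    offs <- as.integer((seq_len(n) - 1) * tile_len)
    offs[n] <- as.integer(L - tile_len)
    len <- as.integer(tile_len)
  }
  tiles <- if (long_is_y)
    data.frame(offset_x = 0L, offset_y = offs, width = S, height = len)
  else
    data.frame(offset_x = offs, offset_y = 0L, width = len, height = S)
  structure(list(scale = scale, size = c(height = h, width = w),
                 tile_len = as.integer(tile_len), tiles = tiles),
            class = "mammotile_tileplan")
}

#' @export
print.mammotile_tileplan <- function(x, ...) {
  cat(sprintf("<tile plan: %dx%d px at scale %g, %d tile(s) of len %d>\n",
              x$size[1], x$size[2], x$scale, nrow(x$tiles), x$tile_len))
  invisible(x)
}

#' Extract the tiles of a plan as sub-images with frames
#'
#' @param image numeric matrix whose dimensions match the plan.
#' @param plan a [plan_tiles()] result.
#' @return list of `list(image, frame)` pairs; each frame carries the
#'   plan's scale and the tile's offset.
#' @export
extract_tiles <- function(image, plan) {
  stopifnot(inherits(plan, "mammotile_tileplan"))
  if (nrow(image) != plan$size[1] || ncol(image) != plan$size[2])
    stop(sprintf("extract_tiles: image is %dx%d but plan expects %dx%d",
                 nrow(image), ncol(image), plan$size[1], plan$size[2]))
  lapply(seq_len(nrow(plan$tiles)), function(i) {
    t <- plan$tiles[i, ]
    sub <- image[(t$offset_y + 1):(t$offset_y + t$height),
                 (t$offset_x + 1):(t$offset_x + t$width), drop = FALSE]
    list(image = sub, frame = frame(plan$scale, t$offset_x, t$offset_y))
  })
}
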