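#' Axis-aligned pixel boxes
#'
#' Boxes are the universal geometric unit of the pipeline: 0-based,
#' half-open `[min, max)` pixel rectangles with y growing downward.
#' Coordinates are stored as doubles because remapping a box out of a
#' reduced-scale frame by `1/scale` produces fractional pixels; rounding
#' happens only at rasterization, never in geometry.
#'
#' `boxes()` builds a validated data frame of boxes (one row per box).
#'
#' @param x_min,y_min,x_max,y_max numeric vectors of equal length, pixel
#'   coordinates with `x_min < x_max` and `y_min < y_max`.
#' @return A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' b <- boxes(0, 0, 10, 10)
#' box_center(b)
#' @export
boxes <- function(x_min, y_min, x_max, y_max) {
  df <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_boxes(df)
  df
}

#' Validate a box table
#'
#' Checks that `df` carries the four corner columns, that all coordinates
#' are finite, and that every box has positive extent.
#'
#' @param df a data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @param where label used in error messages (e.g. a file name).
#' @return `df`, invisibly.
#' @export
validate_boxes <- function(df, where = "boxes") {
  need <- c("x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing columns: %s", where, paste(miss, collapse = ", ")))
  if (nrow(df) == 0) return(invisible(df))
  bad <- !is.finite(df$x_min) | !is.finite(df$y_min) |
    !is.finite(df$x_max) | !is.finite(df$y_max) |
    df$x_min >= df$x_max | df$y_min >= df$y_max
  if (any(bad))
    stop(sprintf("%s: invalid box on row(s) %s (need x_min < x_max, y_min < y_max)",
                 where, paste(which(bad), collapse = ", ")))
  invisible(df)
}

#' Coordinate frame of a detection
#'
#' A frame identifies where a box's coordinates live: a scale factor `s`
#' of the scale pyramid (1 is full resolution) and the offset of the tile
#' origin within that scaled image.  A box at coordinate `c` in the frame
#' maps to `(c + offset) / s` at full resolution.
#'
#' @param scale positive scale factor of the pyramid level.
#' @param offset_x,offset_y non-negative pixel offsets of the tile origin
#'   in the scaled image.
#' @return A list of class `mammotile_frame`.
#' @export
frame <- function(scale = 1, offset_x = 0, offset_y = 0) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0)
    stop("invalid frame: scale must be a positive number")
  if (offset_x < 0 || offset_y < 0)
    stop("invalid frame: tile offsets must be non-negative")
  structure(list(scale = as.numeric(scale),
                 offset_x = as.numeric(offset_x),
                 offset_y = as.numeric(offset_y)),
            class = "mammotile_frame")
}

#' @export
print.mammotile_frame <- function(x, ...) {
  cat(sprintf("<frame scale=%g offset=(%g, %g)>\n", x$scale, x$offset_x, x$offset_y))
  invisible(x)
}

#' Intersection over union of two boxes
#'
#' Vectorized elementwise over rows when `a` and `b` have equal row
#' counts (or either has one row).  Degenerate (non-overlapping) pairs
#' return 0.
#'
#' @param a,b box tables (see [boxes()]).
#' @return numeric vector of IoU values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  un <- area_a + area_b - inter
  ifelse(un > 0, inter / un, 0)
}

#' IoU matrix between two box tables
#'
#' @param a,b box tables with `na` and `nb` rows.
#' @return an `na x nb` matrix of pairwise IoU values.
#' @export
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(numeric(0), na, nb))
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  un <- outer(area_a, area_b, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Box centers
#'
#' @param df a box table.
#' @return a two-column matrix `(cx, cy)` of box centers.
#' @export
box_center <- function(df) {
  cbind(cx = (df$x_min + df$x_max) / 2, cy = (df$y_min + df$y_max) / 2)
}

#' Remap boxes from a tile/scale frame into the full-resolution frame
#'
#' Each coordinate `c` becomes `(c + offset) / scale`.  This is the
#' transform that lets per-scale, per-tile predictions be pooled before
#' fusion: it is exactly invertible (see [remap_from_fullres()]).
#'
#' @param df a box table in the frame `frm`.
#' @param frm a [frame()].
#' @return the box table with coordinates in the full-resolution frame.
#' @export
remap_to_fullres <- function(df, frm) {
  stopifnot(inherits(frm, "mammotile_frame"))
  out <- df
  out$x_min <- (df$x_min + frm$offset_x) / frm$scale
  out$x_max <- (df$x_max + frm$offset_x) / frm$scale
  out$y_min <- (df$y_min + frm$offset_y) / frm$scale
  out$y_max <- (df$y_max + frm$offset_y) / frm$scale
  out
}

#' Remap boxes from the full-resolution frame into a tile/scale frame
#'
#' Exact inverse of [remap_to_fullres()]: `c -> c * scale - offset`.
#'
#' @inheritParams remap_to_fullres
#' @return the box table with coordinates in frame `frm`.
#' @export
remap_from_fullres <- function(df, frm) {
  stopifnot(inherits(frm, "mammotile_frame"))
  out <- df
  out$x_min <- df$x_min * frm$scale - frm$offset_x
  out$x_max <- df$x_max * frm$scale - frm$offset_x
  out$y_min <- df$y_min * frm$scale - frm$offset_y
  out$y_max <- df$y_max * frm$scale - frm$offset_y
  out
}

#' Detection tables
#'
#' A detection is a box plus a confidence score and provenance: the frame
#' its coordinates currently live in (`scale`, `offset_x`, `offset_y`)
#' and the pyramid scale it originated from (`source_scale`, preserved
#' across remapping so fusion and per-scale analysis can attribute every
#' box).  Detections are plain data frames so they compose with the
#' usual table tools.
#'
#' @param df a box table.
#' @param score numeric vector of confidences in `[0, 1]`.
#' @param frm the [frame()] the coordinates are expressed in.
#' @param source_scale originating pyramid scale (defaults to
#'   `frm$scale`).
#' @return a detection data frame with columns `x_min`, `y_min`, `x_max`,
#'   `y_max`, `score`, `scale`, `offset_x`, `offset_y`, `source_scale`.
#' @export
detections <- function(df, score, frm = frame(), source_scale = frm$scale) {
  validate_boxes(df, "detections")
  score <- as.numeric(score)
  if (nrow(df) > 0 && (any(!is.finite(score)) || any(score < 0) || any(score > 1)))
    stop("detections: scores must lie in [0, 1]")
  out <- df[, c("x_min", "y_min", "x_max", "y_max"), drop = FALSE]
  out$score <- score
  out$scale <- frm$scale
  out$offset_x <- frm$offset_x
  out$offset_y <- frm$offset_y
  out$source_scale <- source_scale
  out
}

#' @rdname detections
#' @export
empty_detections <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), score = numeric(0), scale = numeric(0),
             offset_x = numeric(0), offset_y = numeric(0),
             source_scale = numeric(0))
}

#' Remap a detection table to the full-resolution frame
#'
#' Applies [remap_to_fullres()] using each row's own frame columns and
#' resets the frame columns to the identity frame; `source_scale` is
#' preserved.
#'
#' @param det a detection table (see [detections()]).
#' @return the detection table in the full-resolution frame.
#' @export
detections_to_fullres <- function(det) {
  if (nrow(det) == 0) return(det)
  out <- det
  out$x_min <- (det$x_min + det$offset_x) / det$scale
  out$x_max <- (det$x_max + det$offset_x) / det$scale
  out$y_min <- (det$y_min + det$offset_y) / det$scale
  out$y_max <- (det$y_max + det$offset_y) / det$scale
  out$scale <- 1
  out$offset_x <- 0
  out$offset_y <- 0
  out
}
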