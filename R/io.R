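#' Read and write 16-bit PGM images
#'
#' The on-disk image format is netpbm PGM with a 16-bit sample depth:
#' binary `P5` (big-endian, the netpbm convention) by default, or ASCII
#' `P2`.  No pre-installed R package writes 16-bit PNG/TIFF, and the
#' pipeline's intensity model is 16-bit, so PGM is the supported
#' interchange format; it converts losslessly to PNG/TIFF with any
#' netpbm-aware tool.
#'
#' @param image numeric matrix with values in `[0, 65535]` (rounded on
#'   write).
#' @param path file path.
#' @param ascii write ASCII `P2` instead of binary `P5`.
#' @return `read_pgm` returns a numeric matrix; `write_pgm` returns
#'   `path` invisibly.
#' @export
write_pgm <- function(image, path, ascii = FALSE) {
  v <- round(clamp(image, 0, 65535))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)), "65535"),
               con)
    # row-major raster order
    write(t(v), file = con, ncolumns = ncol(image))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n65535\n", ncol(image), nrow(image)), con,
              eos = NULL)
    writeBin(as.integer(t(v)), con, size = 2, endian = "big")
  }
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("read_pgm: unexpected end of file")
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("^[ \t\r\n]$", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("read_pgm: not a PGM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  if (magic == "P5") {
    vals <- readBin(con, "integer", n = n, size = if (maxval > 255) 2 else 1,
                    signed = FALSE, endian = "big")
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[ \t\r\n]+")[[1]])
    if (length(vals) > n) vals <- vals[seq_len(n)]
  }
  if (length(vals) != n) stop("read_pgm: truncated raster in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a prediction table as CSV
#'
#' Columns `image_id,scale,x_min,y_min,x_max,y_max,score` in the
#' full-resolution frame (`scale` records the originating pyramid
#' scale; `NA` for cross-scale fused boxes).  Floats survive the round
#' trip exactly.  Malformed rows are rejected with their line numbers.
#'
#' @param det detection table with an `image_id` column.
#' @param path file path.
#' @return `read_detections_csv` returns a detection table;
#'   `write_detections_csv` returns `path` invisibly.
#' @export
write_detections_csv <- function(det, path) {
  out <- data.frame(image_id = as.character(det$image_id),
                    scale = fmt_num(det$source_scale),
                    x_min = fmt_num(det$x_min), y_min = fmt_num(det$y_min),
                    x_max = fmt_num(det$x_max), y_max = fmt_num(det$y_max),
                    score = fmt_num(det$score))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  need <- c("image_id", "scale", "x_min", "y_min", "x_max", "y_max", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  check_rows(df, path, scored = TRUE)
  out <- data.frame(image_id = df$image_id,
                    x_min = df$x_min, y_min = df$y_min,
                    x_max = df$x_max, y_max = df$y_max,
                    score = df$score, scale = 1, offset_x = 0, offset_y = 0,
                    source_scale = df$scale)
  out
}

# line-numbered row validation (line 1 is the header)
check_rows <- function(df, path, scored = FALSE) {
  if (nrow(df) == 0) return(invisible(df))
  bad <- !is.finite(df$x_min) | !is.finite(df$y_min) |
    !is.finite(df$x_max) | !is.finite(df$y_max) |
    df$x_min >= df$x_max | df$y_min >= df$y_max
  if (scored) bad <- bad | !is.finite(df$score) | df$score < 0 | df$score > 1
  if (any(bad))
    stop(path, ": invalid row(s) at line ",
         paste(which(bad) + 1, collapse = ", "),
         " (need x_min < x_max, y_min < y_max",
         if (scored) ", 0 <= score <= 1", ")")
  invisible(df)
}

#' Write / read a ground-truth table as CSV
#'
#' Columns `image_id,x_min,y_min,x_max,y_max,size_mm`.
#'
#' @param gt ground-truth table.
#' @param path file path.
#' @export
write_gt_csv <- function(gt, path) {
  out <- data.frame(image_id = as.character(gt$image_id),
                    x_min = fmt_num(gt$x_min), y_min = fmt_num(gt$y_min),
                    x_max = fmt_num(gt$x_max), y_max = fmt_num(gt$y_max),
                    size_mm = fmt_num(gt$size_mm))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gt_csv
#' @export
read_gt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  check_rows(df, path)
  df
}

#' COCO-style box conversion
#'
#' Converts between corner boxes and COCO `[x, y, width, height]`
#' lists; the conversion is lossless in floating point.
#' `write_coco_json`/`read_coco_json` serialize a ground-truth table to
#' a COCO-style annotation file (categories: a single "mass" class).
#'
#' @param df box table.
#' @return `boxes_to_coco`: matrix with columns `x,y,width,height`;
#'   `coco_to_boxes`: box table.
#' @export
boxes_to_coco <- function(df) {
  cbind(x = df$x_min, y = df$y_min,
        width = df$x_max - df$x_min, height = df$y_max - df$y_min)
}

#' @rdname boxes_to_coco
#' @param m matrix or data frame with columns `x,y,width,height`.
#' @export
coco_to_boxes <- function(m) {
  m <- as.data.frame(m)
  boxes(m$x, m$y, m$x + m$width, m$y + m$height)
}

#' @rdname boxes_to_coco
#' @param gt ground-truth table with `image_id` (and optionally
#'   `size_mm`).
#' @param path file path.
#' @export
write_coco_json <- function(gt, path) {
  ids <- unique(as.character(gt$image_id))
  ann <- lapply(seq_len(nrow(gt)), function(i) {
    a <- list(id = i, image_id = match(as.character(gt$image_id[i]), ids),
              category_id = 1,
              bbox = as.numeric(boxes_to_coco(gt[i, , drop = FALSE])),
              area = (gt$x_max[i] - gt$x_min[i]) * (gt$y_max[i] - gt$y_min[i]))
    if ("size_mm" %in% names(gt)) a$size_mm <- gt$size_mm[i]
    a
  })
  obj <- list(images = lapply(seq_along(ids), function(i)
    list(id = i, file_name = ids[i])),
    annotations = ann,
    categories = list(list(id = 1, name = "mass")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname boxes_to_coco
#' @export
read_coco_json <- function(path) {
  obj <- jsonlite::read_json(path)
  imgs <- vapply(obj$images, function(x) as.character(x$file_name), "")
  names(imgs) <- vapply(obj$images, function(x) as.character(x$id), "")
  rows <- lapply(obj$annotations, function(a) {
    b <- as.numeric(unlist(a$bbox))
    data.frame(image_id = imgs[[as.character(a$image_id)]],
               x_min = b[1], y_min = b[2],
               x_max = b[1] + b[3], y_max = b[2] + b[4],
               size_mm = if (!is.null(a$size_mm)) as.numeric(a$size_mm)
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_boxes(out, path)
  out
}

#' Write an FROC curve to CSV / a summary to JSON
#'
#' @param curve a [froc()] result.
#' @param path file path.
#' @param fpi_list FPI operating points for the summary.
#' @export
write_froc_csv <- function(curve, path) {
  utils::write.csv(data.frame(threshold = fmt_num(curve$points$threshold),
                              fpi = fmt_num(curve$points$fpi),
                              sensitivity = fmt_num(curve$points$sensitivity)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_froc_csv
#' @export
froc_summary <- function(curve, fpi_list = c(0.1, 0.15, 0.2, 0.3)) {
  list(n_images = curve$n_images, n_gt = curve$n_gt,
       sensitivity_at_fpi = stats::setNames(
         lapply(fpi_list, function(f) sensitivity_at_fpi(curve, f)),
         sprintf("fpi_%g", fpi_list)))
}
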