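#' Read a YOLO-style detection text file
#'
#' One whitespace-delimited row per box: `class cx cy w h conf`, with centre
#' and size normalized to the image dimensions. Rows failing the range checks
#' (`0 <= cx, cy <= 1`, `w, h > 0`, `conf` in \[0, 1\]) abort the parse with
#' their line numbers.
#'
#' @param path Path to the text file.
#' @return Data frame with columns `class`, `cx`, `cy`, `w`, `h`, `conf`;
#'   zero rows for an empty file.
#' @export
read_yolo_file <- function(path) {
  lines <- readLines(path)
  lines_kept <- which(nzchar(trimws(lines)))
  if (length(lines_kept) == 0) {
    return(data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), conf = numeric()))
  }
  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 6) {
      stop(sprintf("line %d: expected 6 fields, got %d", i, length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric field", i))
    v
  }
  m <- t(vapply(lines_kept, parse_row, numeric(6)))
  out <- data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                    w = m[, 4], h = m[, 5], conf = m[, 6])
  bad <- which(out$cx < 0 | out$cx > 1 | out$cy < 0 | out$cy > 1 |
               out$w <= 0 | out$h <= 0 | out$conf < 0 | out$conf > 1)
  if (length(bad) > 0) {
    stop(sprintf("out-of-range box on line(s): %s",
                 paste(lines_kept[bad], collapse = ", ")))
  }
  out
}

#' Write detections in the YOLO text dialect
#'
#' @param boxes Data frame with columns `class`, `cx`, `cy`, `w`, `h`,
#'   `conf` (extra columns are dropped).
#' @param path Output path.
#' @export
write_yolo_file <- function(boxes, path) {
  cols <- c("class", "cx", "cy", "w", "h", "conf")
  stopifnot(all(cols %in% names(boxes)))
  lines <- apply(boxes[, cols, drop = FALSE], 1, function(r) {
    paste(c(format(as.integer(r[1])),
            formatC(as.numeric(r[-1]), format = "f", digits = 6)),
          collapse = " ")
  })
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Intersection over union of two centre-format boxes
#'
#' @param a,b Boxes as list/row with `cx`, `cy`, `w`, `h` in a common
#'   normalized frame.
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- pmax(0, pmin(ax1, bx1) - pmax(ax0, bx0))
  ih <- pmax(0, pmin(ay1, by1) - pmax(ay0, by0))
  inter <- iw * ih
  union <- a$w * a$h + b$w * b$h - inter
  ifelse(union > 0, inter / union, 0)
}

#' Convert 0-based pixel bounding boxes to normalized centre format
#'
#' @param truth Data frame with `x0`, `y0`, `x1`, `y1` (0-based, inclusive).
#' @param image_dim (rows, cols) of the image.
#' @return Data frame with `cx`, `cy`, `w`, `h`.
#' @export
px_box_to_norm <- function(truth, image_dim) {
  data.frame(
    cx = (truth$x0 + truth$x1 + 1) / 2 / image_dim[2],
    cy = (truth$y0 + truth$y1 + 1) / 2 / image_dim[1],
    w = (truth$x1 - truth$x0 + 1) / image_dim[2],
    h = (truth$y1 - truth$y0 + 1) / image_dim[1]
  )
}

#' Match detection boxes to vertebrae and reduce to one score each
#'
#' Every detection is assigned to the vertebra whose reference box it
#' overlaps most, provided the IoU reaches `iou_min`; a detection never goes
#' to more than one vertebra. The per-vertebra confidence is the maximum over
#' its assigned boxes, or 0 when none match (treated downstream as "no
#' detection"). The default `iou_min` of 0.25 targets vertebra-level
#' attribution rather than localization quality.
#'
#' @param boxes Data frame of detections (`cx`, `cy`, `w`, `h`, `conf`).
#' @param truth_boxes Data frame of reference boxes per vertebra:
#'   `vertebra`, `cx`, `cy`, `w`, `h`, same normalized frame.
#' @param iou_min Minimum IoU for attribution.
#' @return Data frame `vertebra`, `confidence`, `n_boxes`; unassigned
#'   detections are listed in the `unassigned` attribute (row indices into
#'   `boxes`).
#' @export
match_boxes <- function(boxes, truth_boxes, iou_min = 0.25) {
  stopifnot(all(c("cx", "cy", "w", "h") %in% names(truth_boxes)),
            "vertebra" %in% names(truth_boxes))
  out <- data.frame(vertebra = truth_boxes$vertebra,
                    confidence = 0, n_boxes = 0L)
  unassigned <- integer()
  for (i in seq_len(nrow(boxes))) {
    ious <- box_iou(boxes[i, ], truth_boxes)
    j <- which.max(ious)
    if (length(j) == 1 && ious[j] >= iou_min) {
      out$confidence[j] <- max(out$confidence[j], boxes$conf[i])
      out$n_boxes[j] <- out$n_boxes[j] + 1L
    } else {
      unassigned <- c(unassigned, i)
    }
  }
  attr(out, "unassigned") <- unassigned
  out
}

#' Aggregate per-slice vertebra scores across a 3D stack
#'
#' A fracture visible on any sagittal slice counts: the vertebra confidence
#' is the maximum across slices.
#'
#' @param score_tables List of per-slice score data frames from
#'   [match_boxes()].
#' @return One score data frame with the slice-wise maximum confidence.
#' @export
aggregate_slice_scores <- function(score_tables) {
  stopifnot(length(score_tables) >= 1)
  out <- score_tables[[1]][, c("vertebra", "confidence")]
  for (s in score_tables[-1]) {
    stopifnot(identical(s$vertebra, out$vertebra))
    out$confidence <- pmax(out$confidence, s$confidence)
  }
  out
}
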