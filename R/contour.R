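#' Extract the vertebral contour band from a binary mask
#'
#' The detector input representation: the ring of pixels obtained by dilating
#' the vertebra mask and subtracting the original mask. Dilation uses an
#' elementary 3x3 structuring element iterated `radius_px` times, so the band
#' is at most `radius_px` wide along any axis of the element; dilation is
#' clipped at the image bounds.
#'
#' @param mask Binary matrix (logical or 0/1).
#' @param radius_px Dilation radius in pixels, integer >= 1.
#' @param element_shape `"box"` (3x3 square, default) or `"diamond"`
#'   (4-connected cross).
#' @return Integer matrix of the same shape, class `contour_band`, with the
#'   dilation radius and element recorded as attributes.
#' @examples
#' m <- matrix(0L, 12, 12); m[4:9, 4:9] <- 1L
#' sum(make_contour_band(m, 1)) # one-pixel ring
#' @export
make_contour_band <- function(mask, radius_px = 1L, element_shape = c("box", "diamond")) {
  element_shape <- match.arg(element_shape)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  fg <- matrix(as_binary(mask, "mask"), nrow(mask), ncol(mask))
  radius_px <- as.integer(radius_px)
  if (is.na(radius_px) || radius_px < 1L) stop("radius_px must be an integer >= 1")
  dil <- dilate_binary(fg, radius_px, element_shape)
  band <- matrix(as.integer(dil & !fg), nrow(mask), ncol(mask))
  structure(band, class = c("contour_band", class(band)),
            radius_px = radius_px, element = element_shape)
}

# r iterations of the elementary 3x3 element == radius-r dilation
dilate_binary <- function(fg, radius_px, element_shape) {
  kern <- EBImage::makeBrush(3L, shape = if (element_shape == "box") "box" else "diamond")
  out <- fg * 1
  for (i in seq_len(radius_px)) out <- EBImage::dilate(out, kern)
  out > 0
}

erode_binary <- function(fg, radius_px, element_shape = "box") {
  kern <- EBImage::makeBrush(3L, shape = element_shape)
  out <- fg * 1
  for (i in seq_len(radius_px)) out <- EBImage::erode(out, kern)
  out > 0
}

#' @export
print.contour_band <- function(x, ...) {
  cat(sprintf("contour band: %d px set, radius %d, %s element, %d x %d raster\n",
              sum(x), attr(x, "radius_px"), attr(x, "element"),
              nrow(x), ncol(x)))
  invisible(x)
}
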