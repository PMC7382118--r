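#' Read an RGB image as an integer array
#'
#' Reads an 8-bit RGB PNG or JPEG into an `H x W x 3` integer array with
#' values in 0--255, rows top to bottom.
#'
#' @param path image path.
#' @return integer array of dimension `c(height, width, 3)`.
#' @export
read_rgb_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) != 3L || dim(d)[3] < 3L)
    stop("malformed image: expected a 3-channel RGB image: ", path)
  arr <- round(aperm(d[, , 1:3], c(2, 1, 3)) * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Split an RGB image into its channel planes
#'
#' @param img `H x W x 3` array of intensities in 0--255 (see
#'   [read_rgb_image()]).
#' @return named list with matrices `R`, `G`, `B`; stacking them
#'   reproduces the input exactly.
#' @export
split_channels <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("malformed image: expected an H x W x 3 array")
  list(R = img[, , 1], G = img[, , 2], B = img[, , 3])
}

#' Segment the carrot from the blue channel
#'
#' Thresholds the blue plane and returns the foreground mask. On a bright
#' background the carrot is dark in blue, so foreground pixels are those
#' *below* the threshold; pass `invert = TRUE` for rigs with the opposite
#' polarity. The threshold actually used is recorded as the `"threshold"`
#' attribute of the result.
#'
#' @param blue numeric matrix of blue intensities in 0--255.
#' @param threshold `"otsu"` (default) for Otsu's method, or a fixed
#'   numeric threshold in 0--255.
#' @param invert if `TRUE`, foreground = pixels above the threshold.
#' @return logical mask with attribute `threshold`.
#' @export
segment_blue <- function(blue, threshold = "otsu", invert = FALSE) {
  blue <- as.matrix(blue)
  if (any(blue < 0 | blue > 255)) stop("blue plane values must be in 0-255")
  if (diff(range(blue)) == 0)
    stop("degenerate image: constant blue plane, no threshold separates it")
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(t(blue) / 255), range = c(0, 1)) * 255
  } else {
    as.numeric(threshold)
  }
  mask <- if (invert) blue > thr else blue < thr
  attr(mask, "threshold") <- thr
  mask
}

#' Fill interior holes of a binary mask
#'
#' Every background component not connected to the image border (4-connected
#' flood) is set to foreground. Foreground never shrinks; the operation is
#' idempotent.
#'
#' @param mask logical mask.
#' @return logical mask with holes filled (attributes preserved).
#' @export
fill_holes <- function(mask) {
  m <- as_mask(mask)
  out <- matrix(as.logical(EBImage::fillHull(m * 1L) > 0), nrow(m), ncol(m))
  attributes(out) <- attributes(mask)
  out
}

#' Remove noise specks and marginal artifacts from a mask
#'
#' First clears any 8-connected foreground component that touches the image
#' border while occupying less than half of the total foreground (frame and
#' marginal-line artifacts), then keeps only the largest remaining
#' component. Components smaller than `min_area_fraction` times the largest
#' are thereby removed as well.
#'
#' @param mask logical mask with at least one foreground pixel.
#' @param min_area_fraction components smaller than this fraction of the
#'   largest component are treated as noise (default 0.05; subsumed by the
#'   keep-largest rule but part of the declared contract).
#' @return logical mask containing a single 8-connected component.
#' @export
remove_noise <- function(mask, min_area_fraction = 0.05) {
  m <- as_mask(mask)
  if (!any(m)) stop("no object: mask has empty foreground")
  lab <- label_components(m)
  areas <- component_areas(lab)
  total <- sum(areas)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0L]
  marginal <- as.integer(names(areas)) %in% border_labs & areas < 0.5 * total
  keep_areas <- areas
  keep_areas[marginal] <- 0
  keep_areas[keep_areas < min_area_fraction * max(keep_areas)] <- 0
  if (all(keep_areas == 0)) stop("no object: all components removed as noise")
  best <- as.integer(names(keep_areas)[which.max(keep_areas)])
  out <- lab == best
  attributes(out) <- attributes(mask)
  dim(out) <- dim(m)
  out
}

#' Segment a carrot image into a clean silhouette mask
#'
#' Full preprocessing chain: extract the blue channel, threshold it
#' ([segment_blue()]), fill holes, and remove noise and marginal artifacts,
#' yielding a single 8-connected hole-free silhouette. The chain is
#' idempotent: re-running fill/clean on its output changes nothing.
#'
#' @param img an `H x W x 3` RGB array (0--255), or a path to a PNG/JPEG.
#' @inheritParams segment_blue
#' @inheritParams remove_noise
#' @return logical mask with attribute `threshold`.
#' @export
segment_carrot <- function(img, threshold = "otsu", invert = FALSE,
                           min_area_fraction = 0.05) {
  if (is.character(img)) img <- read_rgb_image(img)
  ch <- split_channels(img)
  mask <- segment_blue(ch$B, threshold = threshold, invert = invert)
  thr <- attr(mask, "threshold")
  mask <- fill_holes(remove_noise(fill_holes(mask),
                                  min_area_fraction = min_area_fraction))
  attr(mask, "threshold") <- thr
  mask
}
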