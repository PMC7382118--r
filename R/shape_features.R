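#' @title Whole-silhouette shape descriptors
#' @name shape_features
#'
#' @description Classical region descriptors of a binary silhouette:
#' principal-axis length and width, area, perimeter, extent, eccentricity,
#' centroid, moment-ellipse axes, and the dimensionless ratios roundness
#' `Ro = 4*pi*A/p^2`, compactness `Co = p^2/A` and elongation `El = a/b`.
NULL

# Principal-axis frame of the foreground: second-moment orientation and
# pixel coordinates rotated so the major axis is horizontal. Second moments
# include the 1/12 unit-pixel variance term (pixels treated as unit
# squares, as in the common region-properties convention).
axis_frame <- function(mask) {
  mask <- as_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no object: mask has empty foreground")
  y <- as.numeric(idx[, 1]); x <- as.numeric(idx[, 2])
  xb <- mean(x); yb <- mean(y)
  xc <- x - xb; yc <- y - yb
  mu20 <- mean(xc^2) + 1 / 12
  mu02 <- mean(yc^2) + 1 / 12
  mu11 <- mean(xc * yc)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  u <- xc * cos(theta) + yc * sin(theta)
  v <- -xc * sin(theta) + yc * cos(theta)
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + disc
  l2 <- (mu20 + mu02) / 2 - disc
  list(x = x, y = y, u = u, v = v, theta = theta,
       centroid = c(row = yb - 1, col = xb - 1),
       area = length(x), lambda1 = l1, lambda2 = l2)
}

# Perimeter of the (single-component) silhouette: length of the closed
# boundary-pixel chain smoothed with a circular moving average (window 5)
# to undo staircase quantisation, plus pi for the outward half-pixel offset
# of a pixel-centre contour. Calibrated on discs and squares.
perimeter_mask <- function(mask, window = 5L) {
  mask <- as_mask(mask)
  lab <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  oc <- EBImage::ocontour(lab)[[1]]
  n <- nrow(oc)
  if (n < 8L) return(max(4, 2 * n))
  w <- min(window, n)
  sm <- apply(oc, 2, function(z) {
    zz <- c(tail(z, w), z, head(z, w))
    stats::filter(zz, rep(1 / w, w), sides = 2)[(w + 1):(w + n)]
  })
  d <- diff(rbind(sm, sm[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2))) + pi
}

#' Roundness of a region
#'
#' `Ro = 4*pi*A / p^2`: the isoperimetric ratio, 1 for a perfect circle and
#' smaller for any other shape.
#'
#' @param area region area in px^2.
#' @param perimeter region perimeter in px.
#' @return dimensionless roundness.
#' @export
roundness <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("domain error: area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Compactness of a region
#'
#' `Co = p^2 / A`: the inverse isoperimetric ratio, minimised at `4*pi` by
#' the circle. `roundness(A, p) * compactness(A, p) == 4*pi` identically.
#'
#' @inheritParams roundness
#' @return dimensionless compactness.
#' @export
compactness <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("domain error: area and perimeter must be positive")
  perimeter^2 / area
}

#' Elongation of a region
#'
#' `El = a / b`: silhouette length over width, at least 1.
#'
#' @param length_px length `a` along the principal axis, px.
#' @param width_px width `b` across the principal axis, px.
#' @return dimensionless elongation.
#' @export
elongation <- function(length_px, width_px) {
  if (any(width_px <= 0)) stop("domain error: width must be positive")
  if (any(length_px < width_px)) stop("domain error: length must be >= width")
  length_px / width_px
}

#' Basic region properties of a silhouette
#'
#' Computes area (foreground pixel count), perimeter (smoothed contour
#' length), centroid (0-based row/col), principal-axis orientation, length
#' `a` and width `b` as the bounding extents along and across the principal
#' axis, extent `A/(a*b)`, the moment-equivalent ellipse axes and
#' eccentricity, and the roundness / compactness / elongation ratios.
#'
#' @param mask logical silhouette mask (single component, holes filled).
#' @return one-row `data.frame` of named descriptors.
#' @export
basic_region_properties <- function(mask) {
  fr <- axis_frame(mask)
  a <- diff(range(fr$u)) + 1
  b <- diff(range(fr$v)) + 1
  if (b > a) { tmp <- a; a <- b; b <- tmp }   # near-square discretisation
  p <- perimeter_mask(mask)
  A <- fr$area
  data.frame(
    length = a,
    width = b,
    area = A,
    perimeter = p,
    extent = A / (a * b),
    eccentricity = sqrt(max(0, 1 - fr$lambda2 / fr$lambda1)),
    centroid_row = unname(fr$centroid["row"]),
    centroid_col = unname(fr$centroid["col"]),
    major_axis = 4 * sqrt(fr$lambda1),
    minor_axis = 4 * sqrt(fr$lambda2),
    orientation = fr$theta,
    roundness = roundness(A, p),
    compactness = compactness(A, p),
    elongation = elongation(a, b)
  )
}

#' Extract the full shape-feature row for one silhouette
#'
#' Combines [basic_region_properties()] with the partitioned
#' nonhomogeneity descriptors and root count from
#' [partition_silhouette()], giving the complete named feature vector used
#' by the classifier.
#'
#' @param mask logical silhouette mask.
#' @param n_parts number of slices along the principal axis (default 7).
#' @return one-row `data.frame`; columns `Fc1..Fc7` (without `Fc4`),
#'   `Fb1..Fb7` (without `Fb4`), `b4`, `Fct`, `Fbt`, `N`, `broken` follow
#'   the basic descriptors.
#' @export
extract_features <- function(mask, n_parts = 7L) {
  basic <- basic_region_properties(mask)
  prof <- partition_silhouette(mask, n_parts = n_parts)
  nh <- nonhomogeneity_features(prof)
  n_roots <- count_roots(mask, prof)
  cbind(basic, nh, data.frame(N = n_roots))
}

#' Names of the default classifier candidate features
#'
#' All extracted descriptors except absolute position (centroid) and
#' orientation, which depend on where the carrot lies in the frame rather
#' than on its shape, and the `broken` bookkeeping flag.
#'
#' @return character vector of column names.
#' @export
candidate_features <- function() {
  c("length", "width", "area", "perimeter", "extent", "eccentricity",
    "major_axis", "minor_axis", "roundness", "compactness", "elongation",
    "Fc1", "Fc2", "Fc3", "Fc5", "Fc6", "Fc7",
    "Fb1", "Fb2", "Fb3", "Fb5", "Fb6", "Fb7",
    "b4", "Fct", "Fbt", "N")
}

#' Write / read a feature table as CSV
#'
#' Column order is fixed so identical inputs produce byte-identical files.
#'
#' @param features `data.frame` of feature rows.
#' @param path CSV path.
#' @return `path` invisibly; `read_features` returns the `data.frame`.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
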