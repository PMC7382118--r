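#' @title Binary silhouette masks
#'
#' @description A binary mask is represented as a logical matrix with rows as
#' image rows (top to bottom) and columns as image columns (left to right);
#' `TRUE` marks carrot foreground. Pixel coordinates are 0-based
#' pixel-centre coordinates with the origin at the top-left corner, used
#' consistently across the package.
#'
#' @name masks
NULL

# Coerce any numeric/logical matrix-like to a logical mask matrix.
as_mask <- function(x) {
  if (is.list(x) && !is.null(x$mask)) x <- x$mask
  m <- as.matrix(x)
  storage.mode(m) <- "logical"
  m
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged with a union-find pass.
label_components <- function(mask) {
  mask <- as_mask(mask)
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1L)),
                nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  dr <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))   # down-right
  dl <- cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))   # down-left
  pairs <- rbind(dr, dl)
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  newid <- match(root, sort(unique(root)))
  out <- lab
  nz <- lab > 0L
  out[nz] <- newid[lab[nz]]
  out
}

# Areas of labelled components, named by label.
component_areas <- function(lab) {
  tab <- tabulate(lab[lab > 0L])
  stats::setNames(tab, seq_along(tab))
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Any pixel above half intensity is treated as foreground.
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) d <- d[, , 1]
  t(d) > 0.5
}
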