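#' @title Partitioned nonhomogeneity descriptors
#' @name partition_features
#'
#' @description The silhouette is cut into seven equal-length slices along
#' its principal axis. Per-slice centroids and maximum widths yield the
#' partial centroid nonhomogeneity `Fc_i = |c_i - c_4|` (perpendicular
#' offset of slice centroids from the central slice, capturing curvature)
#' and partial width nonhomogeneity `Fb_i = |b_i - b_4|` (capturing bulges,
#' forks and breaks), for `i` in 1..7 excluding the reference slice 4.
#' Totals are normalised by the biggest slice width `bm`:
#' `Fct = sum(Fc_i)/bm`, `Fbt = sum(Fb_i)/bm`.
NULL

#' Partition a silhouette into equal-length slices along its axis
#'
#' The silhouette is rotated (in coordinate space) so its principal axis is
#' horizontal, then cut into `n_parts` slices of equal length. Slices are
#' indexed from the thick end (the end with the larger terminal slice
#' width), so part numbering does not depend on how the carrot was laid
#' down. For each slice the centroid and the maximum width (foreground
#' extent perpendicular to the axis, maximised over axis-aligned columns)
#' are recorded.
#'
#' @param mask logical silhouette mask.
#' @param n_parts number of slices (default 7).
#' @return object of class `partition_profile`: list with `n_parts`,
#'   per-pixel slice assignment `part`, axis coordinates `u`, `v`, pixel
#'   grid coordinates `x`, `y`, per-slice perpendicular centroids `c_perp`,
#'   along-axis centroids `c_along`, widths `b`, the biggest width `bm`,
#'   `empty` flags for slices with no pixels, and `reversed` noting whether
#'   slice order was flipped to put the thick end first.
#' @export
partition_silhouette <- function(mask, n_parts = 7L) {
  n_parts <- as.integer(n_parts)
  fr <- axis_frame(mask)
  len <- diff(range(fr$u)) + 1
  if (len < n_parts)
    stop("too small: silhouette length (", round(len, 1),
         " px) is below the number of parts")
  edges <- min(fr$u) - 0.5 + len * (0:n_parts) / n_parts
  part <- findInterval(fr$u, edges, rightmost.closed = TRUE)
  part <- pmin(pmax(part, 1L), n_parts)

  col_id <- round(fr$u)
  c_perp <- c_along <- b <- rep(NA_real_, n_parts)
  for (i in seq_len(n_parts)) {
    sel <- part == i
    if (!any(sel)) { b[i] <- 0; next }
    c_perp[i] <- mean(fr$v[sel])
    c_along[i] <- mean(fr$u[sel])
    ext <- tapply(fr$v[sel], col_id[sel], function(z) diff(range(z)) + 1)
    b[i] <- max(ext)
  }
  empty <- is.na(c_perp)

  reversed <- FALSE
  first_b <- b[which(!empty)[1]]
  last_b <- b[rev(which(!empty))[1]]
  if (isTRUE(last_b > first_b)) {
    reversed <- TRUE
    part <- n_parts + 1L - part
    c_perp <- rev(c_perp); c_along <- rev(c_along)
    b <- rev(b); empty <- rev(empty)
  }

  # empty slices (broken silhouettes): take the centroid of the nearest
  # non-empty slice so Fc stays defined; width stays 0
  if (any(empty)) {
    ok <- which(!empty)
    for (i in which(empty)) {
      nearest <- ok[which.min(abs(ok - i))]
      c_perp[i] <- c_perp[nearest]
      c_along[i] <- c_along[nearest]
    }
  }

  structure(list(n_parts = n_parts, part = part, u = fr$u, v = fr$v,
                 x = fr$x, y = fr$y, theta = fr$theta,
                 c_perp = c_perp, c_along = c_along, b = b,
                 bm = max(b), empty = empty, reversed = reversed),
            class = "partition_profile")
}

#' @export
print.partition_profile <- function(x, ...) {
  cat("Partition profile:", x$n_parts, "slices",
      if (x$reversed) "(order reversed: thick end first)" else "", "\n")
  cat("  widths b_i:", paste(round(x$b, 1), collapse = ", "),
      " (bm =", round(x$bm, 1), "px)\n")
  cat("  perpendicular centroids:",
      paste(round(x$c_perp, 2), collapse = ", "), "\n")
  if (any(x$empty)) cat("  empty slices:", which(x$empty), "\n")
  invisible(x)
}

#' Partial centroid nonhomogeneity
#'
#' `Fc_i = |c_i - c_4|` for `i != 4`, where `c_i` is the coordinate of the
#' i-th slice centroid perpendicular to the principal axis (px). Zero for a
#' straight symmetric silhouette; grows with curvature.
#'
#' @param profile a [partition_silhouette()] result (7 parts).
#' @return named numeric vector `Fc1, Fc2, Fc3, Fc5, Fc6, Fc7`.
#' @export
partial_centroid_nonhomogeneity <- function(profile) {
  stopifnot(inherits(profile, "partition_profile"))
  ref <- (profile$n_parts + 1L) %/% 2L
  i <- setdiff(seq_len(profile$n_parts), ref)
  stats::setNames(abs(profile$c_perp[i] - profile$c_perp[ref]),
                  paste0("Fc", i))
}

#' Partial width nonhomogeneity
#'
#' `Fb_i = |b_i - b_4|` for `i != 4`, where `b_i` is the maximum width of
#' slice `i` (px). An empty slice contributes its width as 0.
#'
#' @inheritParams partial_centroid_nonhomogeneity
#' @return named numeric vector `Fb1, Fb2, Fb3, Fb5, Fb6, Fb7`.
#' @export
partial_width_nonhomogeneity <- function(profile) {
  stopifnot(inherits(profile, "partition_profile"))
  ref <- (profile$n_parts + 1L) %/% 2L
  i <- setdiff(seq_len(profile$n_parts), ref)
  stats::setNames(abs(profile$b[i] - profile$b[ref]), paste0("Fb", i))
}

#' Total nonhomogeneity
#'
#' Sums the six partial nonhomogeneities and normalises by the biggest
#' slice width `bm`, making the totals scale-invariant.
#'
#' @param partials numeric vector of six partial nonhomogeneities (px).
#' @param bm biggest slice width (px), positive.
#' @return dimensionless total.
#' @export
total_nonhomogeneity <- function(partials, bm) {
  if (bm <= 0) stop("domain error: bm must be positive")
  sum(partials) / bm
}

# All partition-derived feature columns as a one-row data.frame.
nonhomogeneity_features <- function(profile) {
  fc <- partial_centroid_nonhomogeneity(profile)
  fb <- partial_width_nonhomogeneity(profile)
  ref <- (profile$n_parts + 1L) %/% 2L
  out <- c(as.list(fc), as.list(fb),
           list(b4 = profile$b[ref],
                Fct = total_nonhomogeneity(fc, profile$bm),
                Fbt = total_nonhomogeneity(fb, profile$bm),
                broken = as.integer(any(profile$empty))))
  as.data.frame(out)
}

#' Count the number of root tips
#'
#' The root count `N` is the larger number of 8-connected foreground
#' components found in the two terminal slices of the partition: 1 for a
#' single-root carrot, 2 or 3 when the root forks into separate tips before
#' the terminal slice.
#'
#' @param mask logical silhouette mask.
#' @param profile matching [partition_silhouette()] result; computed from
#'   `mask` when missing.
#' @return integer root count, at least 1.
#' @export
count_roots <- function(mask, profile = NULL) {
  mask <- as_mask(mask)
  if (is.null(profile)) profile <- partition_silhouette(mask)
  counts <- vapply(c(1L, profile$n_parts), function(i) {
    sel <- profile$part == i
    if (!any(sel)) return(0L)
    sub <- matrix(FALSE, nrow(mask), ncol(mask))
    sub[cbind(profile$y[sel], profile$x[sel])] <- TRUE
    max(label_components(sub))
  }, integer(1))
  max(1L, counts)
}
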