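#' @title Synthetic carrot silhouettes with analytic ground truth
#' @name synthetic_carrots
#'
#' @description A parametric generator of single-carrot silhouettes
#' emulating the morphologies seen on a grading line: regular carrots
#' (straight, tapered, single root) and irregular ones (curved, double or
#' triple rooted, or broken with a blunt end). Each sample carries its
#' analytic midline and width profile, so pipeline measurements can be
#' checked against closed-form ground truth. Default parameter ranges live
#' in `inst/extdata/silhouette_ranges.yaml`.
NULL

#' Default generator parameter ranges
#'
#' @param path optional path to a YAML ranges file; defaults to the
#'   configuration shipped with the package.
#' @return nested list of ranges.
#' @export
silhouette_ranges <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "silhouette_ranges.yaml",
                        package = "carrotshape")
  yaml::read_yaml(path)
}

#' Construct and validate a silhouette specification
#'
#' The geometry is a tapered tube around a quadratic-arc midline:
#' width profile `w(x) = base_width * (1 - x/length)^taper` and midline
#' offset `f(x) = 4 * curvature * length * t * (1 - t)` with `t = x/length`
#' (peak offset `curvature * length` at mid-shape). Forked roots duplicate
#' the distal midline with symmetric angular offsets from `branch_point`;
#' broken carrots are truncated with a flat cut at `branch_point`.
#'
#' Class invariants: a regular spec must have curvature at most 0.02, a
#' single root and no break; an irregular spec must violate at least one of
#' these (curvature above 0.05, 2--3 roots, or broken).
#'
#' @param class `"regular"` or `"irregular"`.
#' @param length silhouette length, px (must exceed `base_width`).
#' @param base_width width at the thick end, px.
#' @param taper taper exponent (1 = linear taper).
#' @param curvature peak midline offset as a fraction of length.
#' @param n_branches number of root tips rendered (1--3).
#' @param branch_point fork or break position as a fraction of length.
#' @param broken truncate the root at `branch_point` with a blunt cut.
#' @param angle orientation of the principal axis in the image, degrees.
#' @param noise_sd Gaussian intensity noise of the RGB rendering (0--255
#'   units).
#' @param branch_spread_deg angular offset between forked tips, degrees.
#' @return object of class `silhouette_spec`.
#' @export
silhouette_spec <- function(class = c("regular", "irregular"),
                            length = 400, base_width = 75, taper = 1,
                            curvature = 0, n_branches = 1L,
                            branch_point = 0.55, broken = FALSE,
                            angle = 0, noise_sd = 5,
                            branch_spread_deg = 14) {
  class <- match.arg(class)
  spec <- list(class = class, length = length, base_width = base_width,
               taper = taper, curvature = curvature,
               n_branches = as.integer(n_branches),
               branch_point = branch_point, broken = broken, angle = angle,
               noise_sd = noise_sd, branch_spread_deg = branch_spread_deg)
  if (length <= base_width)
    stop("invalid spec: length must exceed base_width")
  if (n_branches < 1L || n_branches > 3L)
    stop("invalid spec: n_branches must be 1-3")
  if (branch_point <= 0 || branch_point >= 1)
    stop("invalid spec: branch_point must be in (0, 1)")
  if (class == "regular" &&
      (curvature > 0.02 || n_branches > 1L || broken))
    stop("invalid spec: a regular carrot must be straight ",
         "(curvature <= 0.02), single-rooted and unbroken")
  if (class == "irregular" &&
      !(curvature > 0.05 || n_branches >= 2L || broken))
    stop("invalid spec: an irregular carrot must be curved ",
         "(curvature > 0.05), multi-rooted or broken")
  structure(spec, class = "silhouette_spec")
}

#' @export
print.silhouette_spec <- function(x, ...) {
  cat(sprintf(
    "Silhouette spec [%s]: L=%.0f px, w0=%.0f px, taper=%.2f, curv=%.3f",
    x$class, x$length, x$base_width, x$taper, x$curvature))
  if (x$n_branches > 1L)
    cat(sprintf(", %d roots (fork at %.2f)", x$n_branches, x$branch_point))
  if (x$broken) cat(sprintf(", broken at %.2f", x$branch_point))
  cat(sprintf(", angle=%.0f deg\n", x$angle))
  invisible(x)
}

#' Render a silhouette spec to a mask (and optionally an RGB image)
#'
#' Rasterises the spec's analytic geometry onto a pixel grid: a pixel is
#' foreground when its centre lies within half the width profile of one of
#' the midlines. The RGB rendering places a dark-in-blue carrot (blue
#' around 50) on a bright background (blue around 230) with additive
#' Gaussian intensity noise, for end-to-end segmentation tests.
#'
#' @param spec a [silhouette_spec()].
#' @param rgb also render the noisy RGB image (default `TRUE`).
#' @param margin background margin around the shape, px.
#' @param ranges generator configuration (for RGB colours).
#' @return object of class `carrot_silhouette`: the `spec`, the logical
#'   `mask`, the RGB `image` (or `NULL`), analytic `midline` and
#'   `width_profile` functions of the along-axis coordinate, and the true
#'   root count `true_N`.
#' @export
render_silhouette <- function(spec, rgb = TRUE, margin = 12,
                              ranges = silhouette_ranges()) {
  stopifnot(inherits(spec, "silhouette_spec"))
  L <- spec$length; bw <- spec$base_width
  f <- function(x) 4 * spec$curvature * L * (x / L) * (1 - x / L)
  # rendered width is clipped at 2 px so the digitised tip stays a single
  # 8-connected stroke instead of fragmenting into sub-pixel specks
  w <- function(x) pmax(bw * pmax(0, 1 - x / L)^spec$taper, 2)
  Le <- if (spec$broken) spec$branch_point * L else L
  xb <- spec$branch_point * L
  dirs <- switch(spec$n_branches, 0, c(-1, 1), c(-1, 0, 1))
  slope <- tan(spec$branch_spread_deg * pi / 180)

  member <- function(x, y) {
    inside <- x >= 0 & x <= Le
    if (spec$n_branches == 1L) {
      hit <- abs(y - f(x)) <= w(x) / 2
    } else {
      trunk <- x <= xb & abs(y - f(x)) <= w(x) / 2
      hit <- trunk
      for (d in dirs) {
        br <- x > xb & abs(y - (f(x) + d * slope * (x - xb))) <= w(x) / 2
        hit <- hit | br
      }
    }
    inside & hit
  }

  # canvas: bounding box of the rotated shape
  xs <- seq(0, Le, length.out = 512)
  ymax <- max(abs(f(xs)) + w(xs) / 2,
              if (spec$n_branches > 1L)
                max(abs(f(xs) + slope * pmax(0, xs - xb)) + w(xs) / 2)
              else 0)
  al <- spec$angle * pi / 180
  ca <- cos(al); sa <- sin(al)
  Wc <- ceiling(Le * abs(ca) + 2 * ymax * abs(sa)) + 2 * margin
  Hc <- ceiling(Le * abs(sa) + 2 * ymax * abs(ca)) + 2 * margin
  px <- matrix(rep(seq_len(Wc), each = Hc), Hc, Wc) - (Wc + 1) / 2
  py <- matrix(rep(seq_len(Hc), times = Wc), Hc, Wc) - (Hc + 1) / 2
  x <- ca * px + sa * py + Le / 2
  y <- -sa * px + ca * py
  mask <- member(x, y)
  dim(mask) <- c(Hc, Wc)

  img <- NULL
  if (rgb) {
    fg <- unlist(ranges$rgb$carrot)
    bg <- unlist(ranges$rgb$background)
    img <- array(0, c(Hc, Wc, 3))
    for (ch in 1:3)
      img[, , ch] <- ifelse(mask, fg[ch], bg[ch]) +
        rnorm(Hc * Wc, 0, spec$noise_sd)
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
  }

  structure(list(spec = spec, mask = mask, image = img,
                 midline = f, width_profile = w,
                 effective_length = Le,
                 true_N = if (spec$broken) 1L else spec$n_branches),
            class = "carrot_silhouette")
}

# Draw one spec from the configured ranges for the given class.
draw_spec <- function(class, ranges) {
  r1 <- function(r) runif(1, r[[1]], r[[2]])
  base <- list(length = r1(ranges$length),
               base_width = r1(ranges$base_width),
               taper = r1(ranges$taper),
               angle = r1(ranges$angle),
               noise_sd = ranges$noise_sd,
               branch_spread_deg = ranges$irregular$branch_spread_deg)
  if (class == "regular") {
    extra <- list(class = "regular",
                  curvature = r1(ranges$regular$curvature),
                  type = "regular")
  } else {
    wts <- unlist(ranges$irregular$type_weights)
    type <- sample(names(wts), 1L, prob = wts)
    extra <- switch(type,
      curved = list(curvature = r1(ranges$irregular$curved_curvature)),
      forked = list(curvature = r1(ranges$irregular$residual_curvature),
                    n_branches = sample(ranges$irregular$n_branches[[1]]:
                                        ranges$irregular$n_branches[[2]], 1L),
                    branch_point = r1(ranges$irregular$fork_point)),
      broken = list(curvature = r1(ranges$irregular$residual_curvature),
                    broken = TRUE,
                    branch_point = r1(ranges$irregular$break_point)))
    extra$class <- "irregular"
    extra$type <- type
  }
  args <- c(base, extra)
  type <- args$type; args$type <- NULL
  spec <- do.call(silhouette_spec, args)
  attr(spec, "type") <- type
  spec
}

#' Generate a ground-truthed dataset of synthetic carrots
#'
#' Draws silhouette specs uniformly from the configured per-class ranges
#' (regular: straight single roots; irregular: curved, forked or broken in
#' the configured proportions), renders each, and returns the samples with
#' a ground-truth table. Deterministic for a fixed seed; the caller's RNG
#' stream is left untouched.
#'
#' @param n_regular,n_irregular class sample counts (defaults 56 and 79,
#'   the standard 135-sample fixture).
#' @param ranges generator configuration, see [silhouette_ranges()].
#' @param seed integer seed (default 2020, the standard fixture).
#' @param rgb render noisy RGB images as well as masks.
#' @param outdir optional directory; when given, writes `img_*.png`,
#'   `mask_*.png` and `ground_truth.csv` there.
#' @return object of class `carrot_dataset`: list of rendered `samples`
#'   and the `truth` data.frame (id, class, subtype, generative parameters,
#'   true root count).
#' @export
generate_dataset <- function(n_regular = 56L, n_irregular = 79L,
                             ranges = silhouette_ranges(), seed = 2020L,
                             rgb = TRUE, outdir = NULL) {
  if (n_regular < 1L || n_irregular < 1L)
    stop("invalid config: need at least one sample per class")
  restore <- local_rng(seed)
  on.exit(restore())
  classes <- rep(c("regular", "irregular"), c(n_regular, n_irregular))
  # draw all specs first so the geometry stream is independent of whether
  # RGB noise is rendered afterwards
  specs <- lapply(classes, draw_spec, ranges = ranges)
  samples <- vector("list", length(classes))
  rows <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    spec <- specs[[i]]
    sil <- render_silhouette(spec, rgb = rgb, ranges = ranges)
    samples[[i]] <- sil
    rows[[i]] <- data.frame(
      id = sprintf("carrot_%03d", i), shape_class = spec$class,
      subtype = attr(spec, "type"), length = spec$length,
      base_width = spec$base_width, taper = spec$taper,
      curvature = spec$curvature, n_branches = spec$n_branches,
      branch_point = spec$branch_point, broken = spec$broken,
      angle = spec$angle, true_N = sil$true_N)
  }
  truth <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(samples)) {
      if (rgb)
        EBImage::writeImage(
          EBImage::Image(aperm(samples[[i]]$image, c(2, 1, 3)) / 255,
                         colormode = "Color"),
          file.path(outdir, paste0(truth$id[i], ".png")))
      write_mask(samples[[i]]$mask,
                 file.path(outdir, paste0(truth$id[i], "_mask.png")))
    }
    write.csv(truth, file.path(outdir, "ground_truth.csv"),
              row.names = FALSE)
  }
  structure(list(samples = samples, truth = truth, seed = seed),
            class = "carrot_dataset")
}

#' @export
print.carrot_dataset <- function(x, ...) {
  cat("Synthetic carrot dataset:", nrow(x$truth), "samples (seed",
      x$seed, ")\n")
  print(table(x$truth$shape_class, x$truth$subtype))
  invisible(x)
}
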