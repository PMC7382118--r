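# Shape fixtures built in code: simple rasterised geometries with known
# closed-form properties, plus small wrappers around the generator.

# Axis-aligned filled rectangle of height h x width w inside a padded canvas.
make_rect <- function(h, w, pad = 5L) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# Filled disc of radius r (pixel-centre membership); canvas_r sets the
# canvas size so discs of different radii can share a grid.
make_disc <- function(r, pad = 5L, canvas_r = r) {
  n <- 2L * (canvas_r + pad) + 1L
  ctr <- canvas_r + pad + 1L
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix((g$row - ctr)^2 + (g$col - ctr)^2 <= r^2, n, n)
  m
}

# Rasterise an arbitrary membership function member(x, y) on a grid, with
# x along columns and y along rows, both centred.
rasterise <- function(member, width, height) {
  xs <- matrix(rep(seq_len(width), each = height), height, width) -
    (width + 1) / 2
  ys <- matrix(rep(seq_len(height), times = width), height, width) -
    (height + 1) / 2
  m <- member(xs, ys)
  dim(m) <- c(height, width)
  m
}

# Rectangle of side a x b rotated by angle (degrees), rendered analytically.
make_rot_rect <- function(a, b, angle, pad = 8L) {
  th <- angle * pi / 180
  size <- ceiling(a * abs(cos(th)) + b * abs(sin(th))) + 2 * pad
  hsize <- ceiling(a * abs(sin(th)) + b * abs(cos(th))) + 2 * pad
  rasterise(function(x, y) {
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    abs(u) <= a / 2 & abs(v) <= b / 2
  }, size, hsize)
}

# A quick regular tapered carrot mask with no curvature.
straight_carrot <- function(length = 400, base_width = 80, taper = 1,
                            angle = 0) {
  spec <- silhouette_spec("regular", length = length,
                          base_width = base_width, taper = taper,
                          curvature = 0, angle = angle)
  render_silhouette(spec, rgb = FALSE)
}

# Labelled two-class Gaussian feature table.
gaussian_table <- function(n1 = 50, n2 = 50, shift = 3, p = 2, sd2 = 1,
                           seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p, mean = shift, sd = sd2), n2, p))
  d <- as.data.frame(X)
  names(d) <- paste0("f", seq_len(p))
  d$shape_class <- factor(rep(c("a", "b"), c(n1, n2)), levels = c("a", "b"))
  d
}
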