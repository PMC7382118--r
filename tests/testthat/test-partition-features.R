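test_that("a uniform rectangle partitions into seven identical slices", {
  m <- make_rect(10, 70)
  prof <- partition_silhouette(m)
  expect_identical(prof$n_parts, 7L)
  expect_equal(as.integer(table(prof$part)), rep(100L, 7))
  expect_equal(prof$b, rep(10, 7))
  expect_equal(prof$bm, 10)
  # all slice centroids on the midline
  expect_equal(prof$c_perp, rep(prof$c_perp[1], 7))
  expect_true(all(partial_centroid_nonhomogeneity(prof) == 0))
  expect_true(all(partial_width_nonhomogeneity(prof) == 0))
  # along-axis centroids at slice centres, 10 px apart
  expect_equal(diff(prof$c_along), rep(10, 6), tolerance = 1e-8)
})

test_that("slices tile the silhouette", {
  sil <- render_silhouette(silhouette_spec("irregular", curvature = 0.15,
                                           angle = 20), rgb = FALSE)
  prof <- partition_silhouette(sil$mask)
  expect_identical(length(prof$part), sum(sil$mask))
  expect_identical(sum(table(prof$part)), sum(sil$mask))
})

test_that("partition rejects silhouettes shorter than the part count", {
  m <- make_rect(3, 4)
  expect_error(partition_silhouette(m, n_parts = 7L), "too small")
})

test_that("slice widths follow a linear taper, thick end first", {
  # analytic trapezoid: width 80 at the left end shrinking to 20
  L <- 350
  m <- rasterise(function(x, y) {
    t <- (x + L / 2) / L
    t >= 0 & t <= 1 & abs(y) <= (80 - 60 * t) / 2
  }, L + 20, 110)
  prof <- partition_silhouette(m)
  expect_true(all(diff(prof$b) < 0))
  # analytic maximum width of slice i is at its left edge
  expected <- 80 - 60 * (0:6) / 7
  expect_lt(max(abs(prof$b - expected)), 2)

  # flipped rendering gives the same ordering (thick end first)
  prof2 <- partition_silhouette(m[, rev(seq_len(ncol(m)))])
  expect_true(prof2$reversed)
  expect_equal(prof2$b, prof$b, tolerance = 1e-8)
})

test_that("arc-bent silhouettes match the analytic slice-mean midline", {
  for (curv in c(0.08, 0.15)) {
    spec <- silhouette_spec("irregular", curvature = curv, taper = 0,
                            length = 350, base_width = 60, angle = 0)
    sil <- render_silhouette(spec, rgb = FALSE)
    prof <- partition_silhouette(sil$mask)
    fc <- partial_centroid_nonhomogeneity(prof)
    # oracle: mean midline offset per slice by numeric integration
    L <- spec$length
    fbar <- vapply(0:6, function(i) {
      stats::integrate(sil$midline, L * i / 7, L * (i + 1) / 7)$value /
        (L / 7)
    }, numeric(1))
    oracle <- abs(fbar[-4] - fbar[4])
    expect_lt(max(abs(fc - oracle)), 1)
  }
})

test_that("width nonhomogeneity follows the stated arithmetic", {
  prof <- structure(list(n_parts = 7L, b = c(80, 70, 60, 50, 40, 30, 20),
                         c_perp = rep(0, 7), bm = 80,
                         empty = rep(FALSE, 7)),
                    class = "partition_profile")
  fb <- partial_width_nonhomogeneity(prof)
  expect_equal(unname(fb), c(30, 20, 10, 10, 20, 30))
  expect_equal(total_nonhomogeneity(fb, 80), 1.5)
  expect_equal(total_nonhomogeneity(rep(0, 6), 50), 0)
  expect_error(total_nonhomogeneity(fb, 0), "domain")
})

test_that("generator width profiles are recovered within 2 px", {
  sil <- straight_carrot(length = 420, base_width = 84, taper = 1)
  prof <- partition_silhouette(sil$mask)
  L <- sil$spec$length
  expected <- sil$width_profile(L * (0:6) / 7)
  expect_lt(max(abs(prof$b - expected)), 2)
})

test_that("nonhomogeneity features are translation-invariant", {
  sil <- render_silhouette(silhouette_spec("irregular", curvature = 0.2),
                           rgb = FALSE)
  m <- sil$mask
  big <- matrix(FALSE, nrow(m) + 40, ncol(m) + 60)
  big[31 + seq_len(nrow(m)) - 1, 17 + seq_len(ncol(m)) - 1] <- m
  f1 <- nonhomogeneity_features(partition_silhouette(m))
  f2 <- nonhomogeneity_features(partition_silhouette(big))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("nonhomogeneity totals are invariant to 180-degree rotation", {
  sil <- render_silhouette(silhouette_spec("irregular", curvature = 0.18,
                                           taper = 0.9), rgb = FALSE)
  m <- sil$mask
  rot <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  f1 <- nonhomogeneity_features(partition_silhouette(m))
  f2 <- nonhomogeneity_features(partition_silhouette(rot))
  expect_equal(f1$Fct, f2$Fct, tolerance = 1e-6)
  expect_equal(f1$Fbt, f2$Fbt, tolerance = 1e-6)
})

test_that("nonhomogeneity totals are scale-invariant", {
  s1 <- render_silhouette(silhouette_spec("irregular", curvature = 0.12,
                                          length = 250, base_width = 50),
                          rgb = FALSE)
  s2 <- render_silhouette(silhouette_spec("irregular", curvature = 0.12,
                                          length = 500, base_width = 100),
                          rgb = FALSE)
  f1 <- nonhomogeneity_features(partition_silhouette(s1$mask))
  f2 <- nonhomogeneity_features(partition_silhouette(s2$mask))
  expect_lt(abs(f1$Fct - f2$Fct) / f2$Fct, 0.05)
  expect_lt(abs(f1$Fbt - f2$Fbt) / f2$Fbt, 0.05)
})

test_that("regular straight shapes have tiny Fct and a single root", {
  for (seed in 1:5) {
    set.seed(seed)
    sil <- straight_carrot(length = runif(1, 350, 450),
                           base_width = runif(1, 60, 90),
                           taper = runif(1, 0.8, 1.4),
                           angle = runif(1, -25, 25))
    prof <- partition_silhouette(sil$mask)
    fc <- partial_centroid_nonhomogeneity(prof)
    expect_lt(total_nonhomogeneity(fc, prof$bm), 0.1)
    expect_identical(count_roots(sil$mask, prof), 1L)
  }
})

test_that("Fct increases strictly with the curvature dial", {
  grid <- c(0.02, 0.08, 0.15, 0.25)
  fct <- vapply(grid, function(cv) {
    spec <- silhouette_spec(if (cv > 0.02) "irregular" else "regular",
                            curvature = cv, length = 400, base_width = 75,
                            taper = 1, angle = 0)
    sil <- render_silhouette(spec, rgb = FALSE)
    extract_features(sil$mask)$Fct
  }, numeric(1))
  expect_true(all(diff(fct) > 0))
})

test_that("root tips are counted in the terminal slices", {
  one <- straight_carrot(400, 80)
  expect_identical(count_roots(one$mask), 1L)
  for (nb in 2:3) {
    spec <- silhouette_spec("irregular", n_branches = nb,
                            branch_point = 0.55, length = 400,
                            base_width = 80, angle = 10)
    sil <- render_silhouette(spec, rgb = FALSE)
    expect_identical(count_roots(sil$mask), as.integer(nb))
  }
})

test_that("empty slices raise the broken flag and stay finite", {
  # two blocks with a gap spanning the middle slice
  m <- matrix(FALSE, 30, 140)
  m[10:20, 1:55] <- TRUE
  m[10:20, 86:140] <- TRUE
  prof <- partition_silhouette(m)
  expect_true(any(prof$empty))
  expect_true(any(prof$b == 0))
  f <- nonhomogeneity_features(prof)
  expect_identical(f$broken, 1L)
  expect_true(all(is.finite(unlist(f))))
})
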