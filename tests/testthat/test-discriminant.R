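test_that("the linear boundary sits midway between equal-variance classes", {
  d <- data.frame(shape_class = factor(rep(c("a", "b"), each = 3),
                                       levels = c("a", "b")),
                  f1 = c(-1, 0, 1, 1, 2, 3))
  fit <- shape_discriminant(shape_class ~ f1, d, kind = "linear", ridge = 0)
  expect_equal(as.character(predict(fit, data.frame(f1 = 0.99))), "a")
  expect_equal(as.character(predict(fit, data.frame(f1 = 1.01))), "b")
  # exactly on the boundary: tie goes to the lower class index
  expect_equal(as.character(predict(fit, data.frame(f1 = 1))), "a")
  co <- coef(fit)
  expect_equal(co$threshold / co$weights[["f1"]], 1)
})

test_that("the quadratic rule matches density comparison in 1-D", {
  set.seed(3)
  d <- data.frame(shape_class = factor(rep(c("a", "b"), each = 60),
                                       levels = c("a", "b")),
                  f1 = c(rnorm(60, 0, 1), rnorm(60, 2, 2)))
  fit <- shape_discriminant(shape_class ~ f1, d, kind = "quadratic",
                            ridge = 0, standardize = FALSE)
  grid <- data.frame(f1 = seq(-6, 8, by = 0.25))
  expect_identical(predict(fit, grid), oracle_predict(d, grid, "quadratic"))
  # unequal variances produce a non-monotone (two-boundary) rule
  pred <- as.character(predict(fit, data.frame(f1 = c(-5, 1, 20))))
  expect_equal(pred, c("b", "a", "b"))
})

test_that("duplicated features are singular without a ridge", {
  d <- gaussian_table()
  d$f3 <- d$f1
  expect_error(
    shape_discriminant(shape_class ~ f1 + f2 + f3, d, ridge = 0),
    "singular")
  # and fit fine with the default ridge
  fit <- shape_discriminant(shape_class ~ f1 + f2 + f3, d)
  expect_s3_class(fit, "shape_discriminant")
})

test_that("predictions equal the density oracle on random problems", {
  set.seed(17)
  for (rep in 1:25) {
    p <- sample(1:3, 1)
    n <- sample(c(25, 40, 60), 1)
    mu2 <- rnorm(p, 1.5)
    A1 <- matrix(rnorm(p * p), p); A2 <- matrix(rnorm(p * p), p)
    X <- rbind(matrix(rnorm(n * p), n, p),
               matrix(rnorm(n * p), n, p) %*% A2 + rep(mu2, each = n))
    d <- as.data.frame(X); names(d) <- paste0("f", 1:p)
    d$shape_class <- factor(rep(c("a", "b"), each = n))
    test <- as.data.frame(matrix(rnorm(10 * p, 0.5, 2), 10, p))
    names(test) <- paste0("f", 1:p)
    for (kind in c("linear", "quadratic")) {
      fit <- shape_discriminant(shape_class ~ ., d, kind = kind, ridge = 0,
                                standardize = FALSE)
      expect_identical(predict(fit, test), oracle_predict(d, test, kind))
    }
  }
})

test_that("predictions agree with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(23)
  d <- gaussian_table(n1 = 70, n2 = 90, shift = 1.2, p = 3, sd2 = 1.6)
  test <- gaussian_table(n1 = 100, n2 = 100, shift = 0.6, p = 3, seed = 5)
  ours_l <- predict(shape_discriminant(shape_class ~ ., d, kind = "linear",
                                       ridge = 0), test)
  ref_l <- predict(MASS::lda(shape_class ~ ., d), test)$class
  expect_identical(as.character(ours_l), as.character(ref_l))
  ours_q <- predict(shape_discriminant(shape_class ~ ., d,
                                       kind = "quadratic", ridge = 0), test)
  ref_q <- predict(MASS::qda(shape_class ~ ., d), test)$class
  expect_identical(as.character(ours_q), as.character(ref_q))
})

test_that("a row at a class mean is assigned to that class", {
  d <- gaussian_table(shift = 2)
  fit <- shape_discriminant(shape_class ~ ., d, kind = "quadratic",
                            prior = c(a = 0.5, b = 0.5))
  mu_b <- colMeans(d[d$shape_class == "b", c("f1", "f2")])
  expect_equal(as.character(predict(fit, as.data.frame(t(mu_b)))), "b")
})

test_that("predictions are invariant to per-feature rescaling", {
  d <- gaussian_table(n1 = 60, n2 = 60, shift = 1, p = 3)
  test <- gaussian_table(n1 = 40, n2 = 40, shift = 1, p = 3, seed = 9)
  scl <- c(1000, 0.01, 7)
  d2 <- d; test2 <- test
  for (j in 1:3) {
    d2[[j]] <- d2[[j]] * scl[j]
    test2[[j]] <- test2[[j]] * scl[j]
  }
  for (kind in c("linear", "quadratic")) {
    p1 <- predict(shape_discriminant(shape_class ~ ., d, kind = kind,
                                     ridge = 0), test)
    p2 <- predict(shape_discriminant(shape_class ~ ., d2, kind = kind,
                                     ridge = 0), test2)
    expect_identical(p1, p2)
  }
})

test_that("quadratic agrees with linear when covariances truly are equal", {
  set.seed(31)
  d <- gaussian_table(n1 = 400, n2 = 400, shift = 1.5, p = 2)
  test <- gaussian_table(n1 = 250, n2 = 250, shift = 1.5, p = 2, seed = 12)
  pl <- predict(shape_discriminant(shape_class ~ ., d, kind = "linear"), test)
  pq <- predict(shape_discriminant(shape_class ~ ., d, kind = "quadratic"),
                test)
  expect_gte(mean(pl == pq), 0.95)
})

test_that("input validation catches bad tables and schemas", {
  d <- gaussian_table()
  fit <- shape_discriminant(shape_class ~ ., d)
  expect_error(predict(fit, d["f1"]), "schema")
  one <- d[c(1, 2, 51), ]
  expect_error(shape_discriminant(shape_class ~ ., one), "two samples")
  dna <- d; dna$f1[3] <- NA
  expect_error(shape_discriminant(shape_class ~ ., dna))
})

test_that("confusion matrices report the stated CCRs", {
  lev <- c("regular", "irregular")
  truth <- factor(rep(lev, c(56, 79)), levels = lev)
  cm_perfect <- confusion_matrix(truth, truth)
  expect_equal(cm_perfect$ccr, 100)

  # 53/56 and 72/79 correct
  pred <- truth
  pred[c(1:3)] <- "irregular"
  pred[56 + (1:7)] <- "regular"
  cm <- confusion_matrix(truth, pred)
  expect_equal(round(cm$ccr, 2), 92.59)
  expect_equal(as.vector(cm$counts), c(53, 7, 3, 72))

  # 56/56 and 74/79 correct
  pred2 <- truth
  pred2[56 + (1:5)] <- "regular"
  expect_equal(round(confusion_matrix(truth, pred2)$ccr, 2), 96.30)

  expect_error(confusion_matrix(factor(character(0)), factor(character(0))),
               "no data")
})

test_that("leave-one-out CV equals an explicit refit loop", {
  d <- gaussian_table(n1 = 18, n2 = 22, shift = 1.5)
  cv <- cross_validate(shape_class ~ ., d, kind = "quadratic",
                       scheme = "loo")
  manual <- vapply(seq_len(nrow(d)), function(i) {
    fit <- shape_discriminant(shape_class ~ ., d[-i, ], kind = "quadratic")
    as.character(predict(fit, d[i, ]))
  }, character(1))
  expect_equal(cv$ccr, 100 * mean(manual == as.character(d$shape_class)))
})

test_that("LOO separates well-separated Gaussians perfectly", {
  d <- gaussian_table(n1 = 20, n2 = 20, shift = 10)
  cv <- cross_validate(shape_class ~ ., d, kind = "linear", scheme = "loo")
  expect_equal(cv$ccr, 100)
})

test_that("k-fold CV is stratified, deterministic and leak-free", {
  d <- gaussian_table(n1 = 30, n2 = 45, shift = 1.5)
  cv1 <- cross_validate(shape_class ~ ., d, kind = "linear", k = 5, seed = 42)
  cv2 <- cross_validate(shape_class ~ ., d, kind = "linear", k = 5, seed = 42)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$ccr, cv2$ccr)
  # every fold carries both classes in proportion
  for (f in 1:5) {
    tab <- table(d$shape_class[cv1$folds == f])
    expect_equal(as.integer(tab), c(6, 9))
  }
  expect_error(cross_validate(shape_class ~ ., d[c(1:3, 31:60), ],
                              kind = "linear", k = 5, seed = 1),
               "stratification")
})

test_that("models survive a JSON round trip", {
  d <- gaussian_table(n1 = 40, n2 = 40, shift = 1, p = 3)
  test <- gaussian_table(n1 = 60, n2 = 60, shift = 1, p = 3, seed = 8)
  for (kind in c("linear", "quadratic")) {
    fit <- shape_discriminant(shape_class ~ ., d, kind = kind)
    tf <- tempfile(fileext = ".json")
    write_model(fit, tf)
    back <- read_model(tf)
    expect_identical(predict(back, test), predict(fit, test))
    expect_equal(back$means, fit$means, tolerance = 1e-12)
  }
})

test_that("print and summary produce informative output", {
  d <- gaussian_table()
  fit <- shape_discriminant(shape_class ~ ., d, kind = "linear")
  expect_output(print(fit), "Gaussian discriminant")
  expect_output(print(summary(fit)), "Resubstitution")
  expect_output(print(evaluate_model(fit, d, label = "shape_class")),
                "Correct classification rate")
})
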