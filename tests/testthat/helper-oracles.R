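# Independent density-comparison oracle for the discriminant classifiers:
# recompute class means, covariances and priors from the table with base R,
# then pick the class maximising log prior + log multivariate normal
# density. Shares no code with the package's prediction path.
oracle_predict <- function(train, test, kind) {
  y <- train$shape_class
  X <- as.matrix(train[setdiff(names(train), "shape_class")])
  lev <- levels(y)
  mus <- lapply(lev, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  if (kind == "linear") {
    pooled <- Reduce(`+`, lapply(lev, function(cl) {
      Xc <- scale(X[y == cl, , drop = FALSE], center = TRUE, scale = FALSE)
      crossprod(Xc)
    })) / (nrow(X) - length(lev))
    Ss <- rep(list(pooled), length(lev))
  } else {
    Ss <- lapply(lev, function(cl) cov(X[y == cl, , drop = FALSE]))
  }
  pri <- as.numeric(table(y)) / nrow(X)
  Xt <- as.matrix(test[colnames(X)])
  ll <- sapply(seq_along(lev), function(j) {
    dev <- sweep(Xt, 2, mus[[j]])
    -0.5 * log(det(Ss[[j]])) -
      0.5 * rowSums((dev %*% solve(Ss[[j]])) * dev) + log(pri[j])
  })
  ll <- matrix(ll, nrow = nrow(Xt))
  factor(lev[max.col(ll, ties.method = "first")], levels = lev)
}

# Table with two informative features (class means shifted by `shift` SDs)
# and `n_noise` pure-noise features.
selection_table <- function(n = 200, shift = 3, n_noise = 8, seed = 1) {
  set.seed(seed)
  half <- n / 2
  d <- data.frame(inf1 = c(rnorm(half), rnorm(half, shift)),
                  inf2 = c(rnorm(half), rnorm(half, shift)))
  for (j in seq_len(n_noise)) d[[paste0("noise", j)]] <- rnorm(n)
  d$shape_class <- factor(rep(c("a", "b"), each = half))
  d
}
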