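#' Fit a Gaussian discriminant shape classifier (LDA / QDA)
#'
#' Fits linear or quadratic discriminant analysis from scratch: per-class
#' Gaussian densities with a pooled within-class covariance (linear, giving
#' a linear decision boundary) or per-class covariances (quadratic). Class
#' priors default to class frequencies. Features are standardised
#' (centre/scale from the training data) before covariance estimation,
#' which stabilises inversion when features span several orders of
#' magnitude without changing the unregularised decision rule, and a small
#' ridge is added to covariance diagonals so near-constant features (such
#' as root count within the regular class) do not make the model singular.
#'
#' @param formula model formula, e.g. `shape_class ~ Fct + Fbt + N` or
#'   `shape_class ~ .`; the response must have at least two classes with at
#'   least two samples each.
#' @param data `data.frame` of features and labels; no missing values.
#' @param kind `"linear"` (pooled covariance) or `"quadratic"` (per-class).
#' @param ridge nonnegative ridge added to covariance diagonals, on the
#'   standardised scale. Default `1e-6` times the mean diagonal variance.
#'   With `ridge = 0` a singular covariance is an error.
#' @param standardize centre and scale features before fitting.
#' @param prior optional named class priors (summing to 1); defaults to
#'   training class frequencies.
#' @return an object of class `shape_discriminant` with `print`,
#'   `summary`, `predict` and (for linear fits) `coef` methods.
#' @examples
#' set.seed(1)
#' d <- data.frame(
#'   shape_class = factor(rep(c("regular", "irregular"), each = 30),
#'                        levels = c("regular", "irregular")),
#'   Fct = c(rnorm(30, 0.2, 0.1), rnorm(30, 1.5, 0.5)),
#'   elongation = c(rnorm(30, 5, 1), rnorm(30, 4, 1.5)))
#' fit <- shape_discriminant(shape_class ~ ., d, kind = "quadratic")
#' table(predict(fit, d), d$shape_class)
#' @export
shape_discriminant <- function(formula, data,
                               kind = c("linear", "quadratic"),
                               ridge = NULL, standardize = TRUE,
                               prior = NULL) {
  kind <- match.arg(kind)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- factor(stats::model.response(mf))
  X <- as.matrix(mf[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("all features must be numeric")
  lev <- levels(y)
  counts <- table(y)
  if (length(lev) < 2L) stop("need at least two classes")
  if (any(counts < 2L)) stop("need at least two samples per class")
  n <- nrow(X); p <- ncol(X); k <- length(lev)

  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, p); scl <- rep(1, p)
  }
  names(center) <- names(scl) <- colnames(X)
  Z <- scale(X, center, scl)

  means <- do.call(rbind, lapply(lev, function(cl)
    colMeans(Z[y == cl, , drop = FALSE])))
  rownames(means) <- lev

  covs <- lapply(lev, function(cl) {
    Zc <- sweep(Z[y == cl, , drop = FALSE], 2, means[cl, ])
    crossprod(Zc)
  })
  if (kind == "linear") {
    Sigma <- Reduce(`+`, covs) / (n - k)
    cov_list <- stats::setNames(rep(list(Sigma), k), lev)
  } else {
    cov_list <- stats::setNames(
      Map(function(S, cl) S / (counts[[cl]] - 1), covs, lev), lev)
  }

  if (is.null(ridge))
    ridge <- 1e-6 * mean(vapply(cov_list, function(S) mean(diag(S)),
                                numeric(1)))
  cov_list <- lapply(cov_list, function(S) S + diag(ridge, p))

  dec <- lapply(cov_list, function(S) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps))) {
      ev <- eigen(S, symmetric = TRUE)
      bad <- which(abs(ev$vectors[, p]) > 0.1)
      stop("singular covariance (ridge = ", format(ridge),
           "); offending feature combination: ",
           paste(colnames(X)[bad], collapse = " + "))
    }
    ch
  })

  if (is.null(prior)) {
    prior <- as.numeric(counts) / n
    names(prior) <- lev
  } else {
    prior <- prior[lev]
    if (abs(sum(prior) - 1) > 1e-8) stop("priors must sum to 1")
  }

  obj <- structure(list(
    kind = kind, levels = lev, counts = as.numeric(counts),
    prior = prior, means = means, cov = cov_list, chol = dec,
    ridge = ridge, center = center, scale = scl,
    feature_names = colnames(X), call = match.call()),
    class = "shape_discriminant")
  obj$fitted <- predict(obj, data.frame(X, check.names = FALSE))
  obj$training_labels <- y
  obj
}

# Discriminant scores: log prior - 0.5 log|Sigma_c| - 0.5 Mahalanobis^2.
.discriminant_scores <- function(object, Z) {
  k <- length(object$levels)
  scores <- matrix(NA_real_, nrow(Z), k,
                   dimnames = list(NULL, object$levels))
  for (j in seq_len(k)) {
    ch <- object$chol[[j]]
    dev <- sweep(Z, 2, object$means[j, ])
    w <- backsolve(ch, t(dev), transpose = TRUE)
    maha <- colSums(w^2)
    scores[, j] <- log(object$prior[j]) - sum(log(diag(ch))) - 0.5 * maha
  }
  scores
}

#' Predict method for shape discriminant models
#'
#' @param object a [shape_discriminant()] fit.
#' @param newdata `data.frame` (or matrix) containing the model's feature
#'   columns; extra columns are ignored, missing ones are an error.
#' @param type `"class"` for predicted labels (default), `"score"` for the
#'   per-class discriminant scores (log prior + log density up to a
#'   constant), `"posterior"` for normalised class posteriors.
#' @param ... unused.
#' @return factor of class labels, or a numeric matrix for scores and
#'   posteriors. Exact ties are broken toward the lower class index.
#' @export
predict.shape_discriminant <- function(object, newdata,
                                       type = c("class", "score",
                                                "posterior"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing))
    stop("schema error: missing feature columns: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Z <- scale(X, object$center, object$scale)
  scores <- .discriminant_scores(object, Z)
  if (type == "score") return(scores)
  if (type == "posterior") {
    m <- apply(scores, 1, max)
    e <- exp(scores - m)
    return(e / rowSums(e))
  }
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.shape_discriminant <- function(x, ...) {
  cat("Gaussian discriminant shape classifier (",
      if (x$kind == "linear") "LDA" else "QDA", ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n")
  cat("Classes:", paste0(x$levels, " (n=", x$counts, ")", collapse = ", "),
      "\n")
  cat("Features (", length(x$feature_names), "): ",
      paste(x$feature_names, collapse = ", "), "\n", sep = "")
  cat("Priors:", paste(sprintf("%s=%.3f", x$levels, x$prior),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.shape_discriminant <- function(object, ...) {
  cm <- confusion_matrix(object$training_labels, object$fitted)
  structure(list(model = object, resubstitution = cm),
            class = "summary.shape_discriminant")
}

#' @export
print.summary.shape_discriminant <- function(x, ...) {
  print(x$model)
  means <- sweep(sweep(x$model$means, 2, x$model$scale, `*`),
                 2, x$model$center, `+`)
  cat("\nClass means (original units):\n")
  print(round(means, 3))
  cat("\nResubstitution performance:\n")
  print(x$resubstitution)
  invisible(x)
}

#' Coefficients of a linear discriminant fit
#'
#' For a two-class linear fit, returns the discriminant weight vector `w`
#' and threshold `c` (original feature units): the rule predicts the second
#' class when `w'x > c`. Not defined for quadratic fits.
#'
#' @param object a linear [shape_discriminant()] fit with two classes.
#' @param ... unused.
#' @return named list with `weights` and `threshold`.
#' @export
coef.shape_discriminant <- function(object, ...) {
  if (object$kind != "linear")
    stop("coefficients are only defined for linear discriminants")
  if (length(object$levels) != 2L)
    stop("coefficients are only defined for two classes")
  S <- object$cov[[1]]
  dmu <- object$means[2, ] - object$means[1, ]
  w_std <- solve(S, dmu)
  mid <- (object$means[1, ] + object$means[2, ]) / 2
  thr_std <- sum(w_std * mid) - log(object$prior[2] / object$prior[1])
  w <- w_std / object$scale
  list(weights = stats::setNames(as.numeric(w), object$feature_names),
       threshold = as.numeric(thr_std + sum(w * object$center)))
}

#' Confusion matrix and correct classification rate
#'
#' @param truth factor (or vector) of true class labels.
#' @param predicted factor of predicted labels on the same levels.
#' @return object of class `confusion_matrix`: the count table (`counts`,
#'   rows = true class), per-class `recall`, and the overall correct
#'   classification rate `ccr` in percent (trace over total).
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) == 0L) stop("no data: empty evaluation set")
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  counts <- table(true = truth, predicted = predicted)
  structure(list(counts = counts,
                 recall = diag(counts) / pmax(1, rowSums(counts)),
                 ccr = 100 * sum(diag(counts)) / sum(counts),
                 n = sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true class):\n")
  print(x$counts)
  cat(sprintf("Correct classification rate: %.2f%% (%d/%d)\n",
              x$ccr, sum(diag(x$counts)), x$n))
  invisible(x)
}

#' Evaluate a fitted discriminant on a labelled table
#'
#' @param model a [shape_discriminant()] fit.
#' @param data labelled `data.frame` containing the model's features and
#'   the label column named in `label`.
#' @param label name of the class-label column.
#' @return a [confusion_matrix()].
#' @export
evaluate_model <- function(model, data, label = "shape_class") {
  if (nrow(data) == 0L) stop("no data: empty evaluation set")
  confusion_matrix(factor(data[[label]], levels = model$levels),
                   predict(model, data))
}

#' Cross-validated evaluation of a discriminant classifier
#'
#' Leave-one-out or stratified k-fold cross-validation; standardisation and
#' model fitting happen inside each training fold only, so no information
#' leaks from held-out samples. Each sample is predicted exactly once.
#'
#' @inheritParams shape_discriminant
#' @param scheme `"loo"` or `"kfold"`.
#' @param k folds for `"kfold"` (default 5).
#' @param seed integer seed controlling the fold assignment (required for
#'   `"kfold"`); fold assignment is identical across runs for a fixed seed.
#' @return object of class `cv_result`: overall pooled `ccr` (percent),
#'   pooled confusion matrix, per-fold confusion matrices, the fold
#'   assignment, and the scheme parameters.
#' @export
cross_validate <- function(formula, data, kind = c("linear", "quadratic"),
                           scheme = c("kfold", "loo"), k = 5L, seed = NULL,
                           ridge = NULL, standardize = TRUE) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  lab_col <- all.vars(formula)[1]
  y <- factor(data[[lab_col]])
  n <- nrow(data)
  folds <- if (scheme == "loo") seq_len(n) else {
    if (is.null(seed)) stop("k-fold cross-validation needs a seed")
    make_folds(y, k, seed)
  }
  nf <- max(folds)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_cms <- vector("list", nf)
  for (f in seq_len(nf)) {
    test <- folds == f
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L || any(table(ytr) < 2L))
      stop("stratification error: a training fold has too few class samples")
    fit <- shape_discriminant(formula, data[!test, , drop = FALSE],
                              kind = kind, ridge = ridge,
                              standardize = standardize)
    pred[test] <- predict(fit, data[test, , drop = FALSE])
    if (scheme == "kfold")
      fold_cms[[f]] <- confusion_matrix(y[test], pred[test])
  }
  structure(list(ccr = 100 * mean(pred == y),
                 confusion = confusion_matrix(y, pred),
                 fold_confusions = if (scheme == "kfold") fold_cms,
                 folds = folds,
                 scheme = list(scheme = scheme, k = if (scheme == "kfold") k,
                               seed = seed, kind = kind)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (%s): CCR = %.2f%%\n",
              if (x$scheme$scheme == "loo") "Leave-one-out" else
                paste0("Stratified ", x$scheme$k, "-fold"),
              x$scheme$kind, x$ccr))
  print(x$confusion)
  invisible(x)
}

# Stratified fold assignment: within each class, shuffle then deal into k
# folds round-robin. Deterministic for a fixed seed.
make_folds <- function(y, k, seed) {
  y <- factor(y)
  if (any(table(y) < k))
    stop("stratification error: a class has fewer samples than folds")
  folds <- integer(length(y))
  rng <- local_rng(seed)
  on.exit(rng())
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Run code under a private RNG state, restoring the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
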