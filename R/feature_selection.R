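#' Sequential forward feature selection by cross-validated QDA
#'
#' Greedy wrapper selection: starting from the empty set, each step adds
#' the candidate feature that maximises the cross-validated correct
#' classification rate of the target discriminant. The first feature is
#' selected only if it strictly beats the majority-class baseline; after
#' that, a step is accepted while the best candidate does not *degrade*
#' the running CV score by more than `delta`, and selection stops when
#' every remaining candidate hurts. Features that neither help nor hurt
#' the wrapper are therefore retained — the selected set serves both the
#' quadratic wrapper and any downstream (e.g. linear) classifier fit on
#' it, and a score plateau carries no evidence against a feature. Fold
#' assignment is fixed once per run (stratified, seeded) and reused for
#' every candidate evaluation, making the result deterministic; ties are
#' broken by candidate column order.
#'
#' @param data labelled `data.frame`.
#' @param label name of the class-label column (default `"shape_class"`).
#' @param candidates candidate feature columns; defaults to the
#'   intersection of [candidate_features()] with the table's columns, or to
#'   all numeric non-label columns if that intersection is empty.
#' @param kind discriminant used inside the wrapper (default quadratic).
#' @param k folds of the stratified cross-validation (default 5).
#' @param seed fold-assignment seed (required).
#' @param delta tolerated CCR degradation (percentage points) when adding
#'   a feature after the first; default 0 (a feature may not lower the
#'   score). The first feature must exceed the baseline by more than
#'   `delta`.
#' @param max_features optional cap on the number of selected features.
#' @return object of class `selection_result`: `selected` (in inclusion
#'   order), the step-by-step `path` with CV scores, the `baseline`
#'   majority-class CCR, and the scheme parameters.
#' @export
select_features <- function(data, label = "shape_class", candidates = NULL,
                            kind = c("quadratic", "linear"), k = 5L,
                            seed = 1L, delta = 0, max_features = Inf) {
  kind <- match.arg(kind)
  y <- factor(data[[label]])
  if (is.null(candidates)) {
    candidates <- intersect(candidate_features(), names(data))
    if (length(candidates) == 0L)
      candidates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], label)
  }
  if (length(candidates) < 1L) stop("no candidate features")
  folds <- make_folds(y, k, seed)

  score_set <- function(cols) {
    f <- stats::reformulate(sprintf("`%s`", cols), response = label)
    pred <- factor(rep(NA_character_, nrow(data)), levels = levels(y))
    for (fd in seq_len(max(folds))) {
      test <- folds == fd
      fit <- shape_discriminant(f, data[!test, , drop = FALSE], kind = kind)
      pred[test] <- predict(fit, data[test, , drop = FALSE])
    }
    100 * mean(pred == y)
  }

  baseline <- 100 * max(table(y)) / length(y)
  selected <- character(0)
  remaining <- candidates
  path <- data.frame(step = integer(0), feature = character(0),
                     cv_ccr = numeric(0))
  best_score <- baseline
  while (length(remaining) > 0L && length(selected) < max_features) {
    scores <- vapply(remaining, function(cand)
      score_set(c(selected, cand)), numeric(1))
    j <- which.max(scores)   # first maximum: ties by candidate order
    accept <- if (length(selected) == 0L) scores[j] > baseline + delta
              else scores[j] >= best_score - delta
    if (!accept) break
    selected <- c(selected, remaining[j])
    best_score <- max(best_score, scores[j])
    path <- rbind(path, data.frame(step = length(selected),
                                   feature = remaining[j],
                                   cv_ccr = scores[j]))
    remaining <- remaining[-j]
  }
  structure(list(selected = selected, path = path, baseline = baseline,
                 scheme = list(kind = kind, k = k, seed = seed,
                               delta = delta),
                 candidates = candidates),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Forward selection (%s, %d-fold CV, seed %d): %d of %d features\n",
    x$scheme$kind, x$scheme$k, x$scheme$seed, length(x$selected),
    length(x$candidates)))
  cat(sprintf("Majority-class baseline: %.2f%%\n", x$baseline))
  if (nrow(x$path)) {
    for (i in seq_len(nrow(x$path)))
      cat(sprintf("  %2d. + %-12s CV CCR %.2f%%\n", x$path$step[i],
                  x$path$feature[i], x$path$cv_ccr[i]))
  } else cat("  (no feature beat the baseline)\n")
  invisible(x)
}

#' Per-feature two-class screening report
#'
#' For each candidate feature: class means, standard deviations, the
#' coefficient of variation (population SD over mean, in percent) per
#' class, and a Welch two-sample t-test p-value comparing the two classes;
#' features with `p < 0.05` are flagged as discriminative. A feature with
#' zero variance in both classes has an undefined test and is flagged `NA`
#' rather than raising an error.
#'
#' @inheritParams select_features
#' @return `data.frame` with one row per feature: `mean_1`, `sd_1`,
#'   `cv_1`, `mean_2`, `sd_2`, `cv_2` (classes in level order), `p_value`
#'   and logical `flagged`.
#' @export
per_feature_screen <- function(data, label = "shape_class",
                               candidates = NULL) {
  y <- factor(data[[label]])
  if (nlevels(y) != 2L) stop("screening expects exactly two classes")
  if (is.null(candidates)) {
    candidates <- intersect(candidate_features(), names(data))
    if (length(candidates) == 0L)
      candidates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], label)
  }
  pop_sd <- function(z) sd(z) * sqrt((length(z) - 1) / length(z))
  rows <- lapply(candidates, function(f) {
    x1 <- data[[f]][y == levels(y)[1]]
    x2 <- data[[f]][y == levels(y)[2]]
    p <- tryCatch(t.test(x1, x2)$p.value, error = function(e) NA_real_)
    data.frame(feature = f,
               mean_1 = mean(x1), sd_1 = sd(x1),
               cv_1 = 100 * pop_sd(x1) / mean(x1),
               mean_2 = mean(x2), sd_2 = sd(x2),
               cv_2 = 100 * pop_sd(x2) / mean(x2),
               p_value = p,
               flagged = if (is.na(p)) NA else p < 0.05)
  })
  out <- do.call(rbind, rows)
  attr(out, "classes") <- levels(y)
  out
}
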