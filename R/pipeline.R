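#' Configuration for a full grading pipeline run
#'
#' @param input `"fixture"` to generate the standard synthetic fixture,
#'   `"images"` to segment RGB images from `image_dir` (expects a
#'   `ground_truth.csv` with `id` and `shape_class` there), or `"masks"`
#'   to read precomputed masks from `mask_dir`.
#' @param image_dir,mask_dir input directories for the respective modes.
#' @param n_regular,n_irregular,fixture_seed fixture parameters (defaults:
#'   the standard 56 + 79 sample fixture, seed 2020).
#' @param use_masks for `input = "fixture"`: featurise the generator's
#'   ground-truth masks directly instead of segmenting the rendered RGB
#'   images.
#' @param threshold,invert,min_area_fraction segmentation options, see
#'   [segment_carrot()].
#' @param n_parts partition slice count (default 7).
#' @param folds,cv_seed stratified cross-validation scheme used for feature
#'   selection and for the reported cross-validated CCRs.
#' @param kinds classifiers to fit (default both `"linear"` and
#'   `"quadratic"`).
#' @param ranges generator configuration.
#' @param outdir optional output directory for `features.csv`,
#'   `selection.json`, `model_<kind>.json` and `report.json`.
#' @return a `run_config` list.
#' @export
run_config <- function(input = c("fixture", "images", "masks"),
                       image_dir = NULL, mask_dir = NULL,
                       n_regular = 56L, n_irregular = 79L,
                       fixture_seed = 2020L, use_masks = FALSE,
                       threshold = "otsu", invert = FALSE,
                       min_area_fraction = 0.05, n_parts = 7L,
                       folds = 5L, cv_seed = 1L,
                       kinds = c("linear", "quadratic"),
                       ranges = silhouette_ranges(), outdir = NULL) {
  input <- match.arg(input)
  if (input == "images" && (is.null(image_dir) || !dir.exists(image_dir)))
    stop("invalid config: image_dir must exist for input = 'images'")
  if (input == "masks" && (is.null(mask_dir) || !dir.exists(mask_dir)))
    stop("invalid config: mask_dir must exist for input = 'masks'")
  structure(list(input = input, image_dir = image_dir, mask_dir = mask_dir,
                 n_regular = n_regular, n_irregular = n_irregular,
                 fixture_seed = fixture_seed, use_masks = use_masks,
                 threshold = threshold, invert = invert,
                 min_area_fraction = min_area_fraction, n_parts = n_parts,
                 folds = folds, cv_seed = cv_seed, kinds = kinds,
                 ranges = ranges, outdir = outdir),
            class = "run_config")
}

#' Run the full grading pipeline
#'
#' Orchestrates segment, featurise, screen, select, train and evaluate as
#' one reproducible run: acquires silhouettes (synthetic fixture, image
#' directory or mask directory), extracts the full feature table, selects
#' features by the cross-validated QDA wrapper, fits the requested
#' discriminants on the selected features, and evaluates each both by
#' resubstitution and by stratified cross-validation. All randomness flows
#' from the two seeds in the configuration, so a repeated run produces an
#' identical report.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_report`: the feature table, selection
#'   result, fitted models, confusion matrices and CCRs per classifier,
#'   plus the parameters used. Written as JSON/CSV when `config$outdir` is
#'   set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  acquire <- switch(config$input,
    fixture = {
      ds <- generate_dataset(config$n_regular, config$n_irregular,
                             ranges = config$ranges,
                             seed = config$fixture_seed,
                             rgb = !config$use_masks)
      masks <- lapply(ds$samples, function(s) {
        if (config$use_masks)
          fill_holes(remove_noise(fill_holes(s$mask),
                                  min_area_fraction = config$min_area_fraction))
        else segment_carrot(s$image, threshold = config$threshold,
                            invert = config$invert,
                            min_area_fraction = config$min_area_fraction)
      })
      list(masks = masks, labels = ds$truth$shape_class,
           ids = ds$truth$id)
    },
    images = {
      gt <- read.csv(file.path(config$image_dir, "ground_truth.csv"))
      masks <- lapply(gt$id, function(id)
        segment_carrot(file.path(config$image_dir, paste0(id, ".png")),
                       threshold = config$threshold,
                       invert = config$invert,
                       min_area_fraction = config$min_area_fraction))
      list(masks = masks, labels = gt$shape_class, ids = gt$id)
    },
    masks = {
      gt <- read.csv(file.path(config$mask_dir, "ground_truth.csv"))
      masks <- lapply(gt$id, function(id) {
        p <- file.path(config$mask_dir, paste0(id, "_mask.png"))
        if (!file.exists(p))
          p <- file.path(config$mask_dir, paste0(id, ".png"))
        fill_holes(remove_noise(fill_holes(read_mask(p)),
                                min_area_fraction = config$min_area_fraction))
      })
      list(masks = masks, labels = gt$shape_class, ids = gt$id)
    })

  features <- do.call(rbind, lapply(seq_along(acquire$masks), function(i) {
    row <- tryCatch(extract_features(acquire$masks[[i]],
                                     n_parts = config$n_parts),
                    error = function(e)
                      stop("feature stage failed for sample ",
                           acquire$ids[i], ": ", conditionMessage(e)))
    cbind(data.frame(id = acquire$ids[i]), row)
  }))
  features$shape_class <- factor(acquire$labels,
                                 levels = c("regular", "irregular"))
  thresholds <- vapply(acquire$masks, function(m) {
    th <- attr(m, "threshold"); if (is.null(th)) NA_real_ else th
  }, numeric(1))

  screen <- per_feature_screen(features)
  selection <- select_features(features, k = config$folds,
                               seed = config$cv_seed)
  sel <- selection$selected
  if (length(sel) == 0L) sel <- selection$candidates
  form <- stats::reformulate(sprintf("`%s`", sel),
                             response = "shape_class")

  models <- list(); evals <- list()
  for (kind in config$kinds) {
    fit <- shape_discriminant(form, features, kind = kind)
    resub <- evaluate_model(fit, features)
    cv <- cross_validate(form, features, kind = kind, scheme = "kfold",
                         k = config$folds, seed = config$cv_seed)
    models[[kind]] <- fit
    evals[[kind]] <- list(resubstitution = resub, cv = cv)
  }

  report <- structure(list(
    parameters = config[c("input", "n_regular", "n_irregular",
                          "fixture_seed", "use_masks", "threshold",
                          "invert", "min_area_fraction", "n_parts",
                          "folds", "cv_seed", "kinds")],
    package_version = as.character(utils::packageVersion("carrotshape")),
    n_samples = nrow(features),
    thresholds = thresholds,
    features = features,
    screen = screen,
    selection = selection,
    models = models,
    evaluation = evals), class = "pipeline_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Carrot grading pipeline report (", x$n_samples, " samples)\n",
      sep = "")
  cat("Selected features:",
      paste(x$selection$selected, collapse = ", "), "\n\n")
  for (kind in names(x$evaluation)) {
    cat("==", toupper(substr(kind, 1, 1)), kind, "discriminant ==\n")
    cat("Resubstitution:\n")
    print(x$evaluation[[kind]]$resubstitution)
    cat(sprintf("Cross-validated CCR: %.2f%%\n\n",
                x$evaluation[[kind]]$cv$ccr))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `features.csv`, `selection.json`, one `model_<kind>.json` per
#' fitted classifier, and `report.json` with parameters, selection path,
#' confusion matrices and CCRs. Files contain no timestamps, so identical
#' runs produce byte-identical output.
#'
#' @param report a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_features(report$features, file.path(outdir, "features.csv"))
  jsonlite::write_json(
    list(selected = report$selection$selected,
         path = report$selection$path,
         baseline = report$selection$baseline,
         scheme = report$selection$scheme),
    file.path(outdir, "selection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (kind in names(report$models))
    write_model(report$models[[kind]],
                file.path(outdir, paste0("model_", kind, ".json")))
  cm_json <- function(cm)
    list(counts = unclass(as.matrix(cm$counts)),
         classes = rownames(cm$counts),
         recall = as.numeric(cm$recall), ccr = cm$ccr, n = cm$n)
  jsonlite::write_json(
    list(parameters = report$parameters,
         package_version = report$package_version,
         n_samples = report$n_samples,
         selected = report$selection$selected,
         evaluation = lapply(report$evaluation, function(e)
           list(resubstitution = cm_json(e$resubstitution),
                cv_ccr = e$cv$ccr, cv = cm_json(e$cv$confusion)))),
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
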