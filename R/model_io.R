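#' Serialise a discriminant model to JSON
#'
#' Writes kind, class levels, priors, means, covariances, standardisation
#' parameters, ridge and feature names, so the model can be reloaded and
#' used for prediction elsewhere.
#'
#' @param model a [shape_discriminant()] fit.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    format = "carrotshape-discriminant",
    version = 1L,
    kind = model$kind,
    levels = model$levels,
    counts = model$counts,
    prior = as.numeric(model$prior),
    feature_names = model$feature_names,
    center = as.numeric(model$center),
    scale = as.numeric(model$scale),
    ridge = model$ridge,
    means = unname(model$means),
    covariances = lapply(model$cov, unname))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a discriminant model from JSON
#'
#' @param path JSON path written by [write_model()].
#' @return a `shape_discriminant` object usable with [predict()].
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "carrotshape-discriminant"))
    stop("not a carrotshape model file: ", path)
  p <- length(j$feature_names)
  means <- matrix(j$means, ncol = p, dimnames = list(j$levels, j$feature_names))
  covs <- j$covariances
  if (is.array(covs) && length(dim(covs)) == 3L) {
    covs <- lapply(seq_len(dim(covs)[1]), function(i) covs[i, , ])
  }
  covs <- lapply(covs, function(S)
    matrix(unlist(S), p, p, dimnames = list(j$feature_names, j$feature_names)))
  names(covs) <- j$levels
  obj <- structure(list(
    kind = j$kind, levels = j$levels, counts = j$counts,
    prior = stats::setNames(j$prior, j$levels), means = means,
    cov = covs, chol = lapply(covs, chol), ridge = j$ridge,
    center = stats::setNames(j$center, j$feature_names),
    scale = stats::setNames(j$scale, j$feature_names),
    feature_names = j$feature_names, call = call("read_model", path)),
    class = "shape_discriminant")
  obj
}
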