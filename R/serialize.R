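# JSON (de)serialization for scalers, PCA models and trait models, so fitted
# pipelines are reproducible artifacts on disk.

#' Write a fitted model to JSON
#'
#' Supported classes: `feature_scaler`, `pca_model`, `chaffy_cluster_model`,
#' `hyperplane_model`, `hrr_model`, or a plain named list of those (a model
#' bundle).
#'
#' @param model fitted model object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- serialize_model(model)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

serialize_model <- function(model) {
  if (inherits(model, "feature_scaler") || inherits(model, "pca_model") ||
      inherits(model, "chaffy_cluster_model") ||
      inherits(model, "hyperplane_model") || inherits(model, "hrr_model")) {
    out <- lapply(unclass(model), function(v) if (is.matrix(v)) {
      list(.matrix = TRUE, nrow = nrow(v), data = as.numeric(v))
    } else v)
    out$.class <- class(model)[1]
    out
  } else if (is.list(model)) {
    lapply(model, serialize_model)
  } else model
}

#' Read a model written by [write_model()]
#'
#' @param path JSON path.
#' @return the reconstructed model object (or bundle list).
#' @export
read_model <- function(path) {
  deserialize_model(jsonlite::read_json(path, simplifyVector = TRUE))
}

deserialize_model <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(x$.class)) {
    cls <- x$.class
    x$.class <- NULL
    x <- lapply(x, function(v) {
      if (is.list(v) && isTRUE(v$.matrix)) {
        matrix(as.numeric(v$data), nrow = v$nrow)
      } else v
    })
    # restore name vectors lost by JSON on named numerics
    structure(x, class = cls)
  } else {
    lapply(x, deserialize_model)
  }
}
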