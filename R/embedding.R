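#' Feature subsets used by the three trait models
#'
#' Chaffiness uses all eight descriptors; chalky-kernel classification uses
#' the grey-value statistics (f2, f3, f4, f6); head-rice-recovery uses size,
#' weight and shape descriptors (f1, f3, f4, f5, f7).
#'
#' @param trait one of `"chaffiness"`, `"crk"`, `"hrr"`.
#' @return character vector of feature names.
#' @export
trait_feature_subset <- function(trait = c("chaffiness", "crk", "hrr")) {
  switch(match.arg(trait),
         chaffiness = paste0("f", 1:8),
         crk = c("f2", "f3", "f4", "f6"),
         hrr = c("f1", "f3", "f4", "f5", "f7"))
}

#' Fit a z-transform scaler
#'
#' Stores per-column mean and population standard deviation of the training
#' table, so `f' = (f - mu) / sigma`. Zero-variance columns get sigma = 1 and
#' therefore scale to all zeros rather than dividing by zero.
#'
#' @param table data.frame of features.
#' @param feature_subset columns to use (default: all `f*` columns present).
#' @return object of class `feature_scaler`.
#' @export
fit_scaler <- function(table, feature_subset = NULL) {
  feats <- feature_subset %||% grep("^f[0-9]+$", names(table), value = TRUE)
  missing <- setdiff(feats, names(table))
  if (length(missing)) stopf("missing feature columns: %s",
                             paste(missing, collapse = ", "))
  x <- as.matrix(table[feats])
  if (nrow(x) < 2L) stopf("need at least 2 rows to fit a scaler")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2L, mu)^2))   # population SD
  sigma[sigma < 1e-12] <- 1
  structure(list(feature_names = feats, mu = mu, sigma = sigma),
            class = "feature_scaler")
}

#' Apply a scaler to a feature table
#'
#' @param scaler a `feature_scaler`.
#' @param table data.frame containing the scaler's feature columns.
#' @return numeric matrix of z-scored features.
#' @export
scale_features <- function(scaler, table) {
  missing <- setdiff(scaler$feature_names, names(table))
  if (length(missing)) stopf("missing feature columns: %s",
                             paste(missing, collapse = ", "))
  x <- as.matrix(table[scaler$feature_names])
  sweep(sweep(x, 2L, scaler$mu), 2L, scaler$sigma, `/`)
}

#' Fit a principal component analysis on scaled features
#'
#' Eigendecomposition of the population covariance of the (already z-scored)
#' table. The sign convention makes each component's largest-magnitude
#' loading positive, so serialized models reload to identical projections.
#' If the matrix rank falls below `n_components` a warning is raised and the
#' explained-variance ratios are padded with zeros.
#'
#' @param scaled numeric matrix from [scale_features()].
#' @param n_components number of components retained (default 3, as used by
#'   all three trait models).
#' @return object of class `pca_model` with orthonormal `component_matrix`
#'   (p x k loadings), `center`, and `explained_variance_ratio`.
#' @export
fit_pca <- function(scaled, n_components = 3L) {
  x <- as.matrix(scaled)
  if (nrow(x) < n_components + 1L)
    stopf("need at least %d rows for %d components", n_components + 1L,
          n_components)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  cov_pop <- crossprod(xc) / nrow(xc)
  eig <- eigen(cov_pop, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  total <- sum(evals)
  k <- min(n_components, ncol(x))
  rank_ok <- sum(evals > 1e-12 * max(evals, 1e-300))
  if (rank_ok < n_components)
    warning(sprintf("covariance rank %d below %d requested components",
                    rank_ok, n_components))
  load <- eig$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  ratio <- if (total > 0) evals[seq_len(k)] / total else rep(0, k)
  if (k < n_components) ratio <- c(ratio, rep(0, n_components - k))
  structure(list(feature_names = colnames(x),
                 component_matrix = load, center = ctr,
                 explained_variance_ratio = ratio,
                 eigenvalues = evals),
            class = "pca_model")
}

#' Project features into PC coordinates
#'
#' Applies the scaler then the PCA loadings; rows map to the coordinates used
#' by every trait classifier.
#'
#' @param scaler a `feature_scaler`.
#' @param pca a `pca_model`.
#' @param feature_table data.frame with the scaler's feature columns, or a
#'   pre-scaled matrix when `scaler` is `NULL`.
#' @return n x k coordinate matrix.
#' @export
project_features <- function(scaler, pca, feature_table) {
  xs <- if (is.null(scaler)) as.matrix(feature_table)
        else scale_features(scaler, feature_table)
  sweep(xs, 2L, pca$center) %*% pca$component_matrix
}
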