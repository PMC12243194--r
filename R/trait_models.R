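# The three trait classifiers operating in PC space, plus evaluation
# helpers and the head-rice-recovery ground-truth formula.

HRR_CLASSES <- c(100, 80, 60, 40, 20)

#' Fit the non-chaffy reference cluster
#'
#' The non-chaffy grains form one multivariate-Gaussian-like cluster in the
#' normalized PC space, characterized by its sample mean and covariance. A
#' grain is later called chaffy when its Mahalanobis distance from this
#' cluster exceeds `theta` (default 17, the published operating threshold in
#' normalized PCA units). Near-singular covariances are ridged
#' (`1e-8 * tr(S)/p` on the diagonal) with a warning.
#'
#' @param coords n x k PC coordinates of non-chaffy training grains (n >= 4).
#' @param theta decision threshold on the Mahalanobis distance.
#' @return object of class `chaffy_cluster_model` with `mean_pc`,
#'   `covariance_pc`, `theta_chaffy` and the covariance condition number.
#' @export
fit_chaffy_cluster <- function(coords, theta = 17) {
  x <- as.matrix(coords)
  if (nrow(x) < 4L) stopf("need at least 4 grains to fit the cluster")
  if (theta <= 0) stopf("theta must be positive")
  mu <- colMeans(x)
  S <- stats::cov(x)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    warning("near-singular cluster covariance: adding ridge")
    S <- S + diag(1e-8 * sum(diag(S)) / ncol(S), ncol(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  }
  structure(list(mean_pc = mu, covariance_pc = S, theta_chaffy = theta,
                 condition_number = max(ev) / min(ev)),
            class = "chaffy_cluster_model")
}

#' Mahalanobis distance from the non-chaffy cluster
#'
#' `sqrt((x - mean)' S^-1 (x - mean))`, computed via the Cholesky factor of
#' the cluster covariance.
#'
#' @param x length-k vector or n x k matrix of PC coordinates.
#' @param model a `chaffy_cluster_model`.
#' @return numeric vector of distances (>= 0).
#' @export
mahalanobis_distance <- function(x, model) {
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  R <- tryCatch(chol(model$covariance_pc),
                error = function(e) stopf("singular cluster covariance"))
  z <- backsolve(R, t(sweep(xm, 2L, model$mean_pc)), transpose = TRUE)
  sqrt(colSums(z^2))
}

#' Classify grains as chaffy
#'
#' A grain is chaffy iff its Mahalanobis distance from the non-chaffy cluster
#' is strictly greater than the model threshold (a distance exactly at the
#' threshold stays non-chaffy).
#'
#' @param coords n x k PC coordinates.
#' @param model a `chaffy_cluster_model`.
#' @return list with logical `chaffy`, numeric `distance`, integer
#'   `chaffy_count`.
#' @export
classify_chaffy <- function(coords, model) {
  d <- mahalanobis_distance(coords, model)
  flag <- d > model$theta_chaffy
  list(chaffy = flag, distance = d, chaffy_count = sum(flag))
}

#' Virtual de-husking shift
#'
#' Translates whole-grain feature vectors so that their population mean
#' coincides with the de-husked kernel ground-truth mean:
#' `x_kernel = x_grain + (mu_GT - mu_grain)`. With `mu_GT = mu_grain` this is
#' the identity; after shifting the training population its mean equals
#' `mu_GT` exactly. (The additive orientation is chosen so the shift performs
#' its stated purpose; see the methods vignette.)
#'
#' @param grain_features n x p matrix or data.frame of whole-grain features
#'   (ordered as `mu_gt`).
#' @param mu_gt per-feature mean of the kernel (de-husked) ground truth.
#' @param mu_grain per-feature mean of the whole-grain population.
#' @return shifted feature matrix.
#' @export
virtual_dehusk <- function(grain_features, mu_gt, mu_grain) {
  x <- as.matrix(grain_features)
  if (length(mu_gt) != ncol(x) || length(mu_grain) != ncol(x))
    stopf("shift vectors must match the feature columns")
  sweep(x, 2L, as.numeric(mu_gt) - as.numeric(mu_grain), `+`)
}

#' Fit the chalky/non-chalky separating hyperplane
#'
#' Maximum-margin linear separator (soft margin, fixed C) in PC space,
#' oriented so positive decision values mean chalky.
#'
#' @param kernel_coords n x k PC coordinates of kernel (de-husked) training
#'   data.
#' @param chalky logical (or 0/1) labels.
#' @param C soft-margin cost.
#' @param dehusk_shift optional per-feature shift `mu_GT - mu_grain` over the
#'   chalkiness features, stored for later whole-grain classification.
#' @return object of class `hyperplane_model` with `normal_pc`, `offset`,
#'   `C`, `dehusk_shift`.
#' @export
fit_chalky_hyperplane <- function(kernel_coords, chalky, C = 1,
                                  dehusk_shift = NULL) {
  y <- if (is.logical(chalky)) chalky else chalky > 0
  if (length(unique(y)) < 2L) stopf("both chalky and non-chalky grains required")
  fit <- svm_linear(as.matrix(kernel_coords), ifelse(y, 1, -1), C = C)
  structure(list(normal_pc = fit$w, offset = fit$b, C = C,
                 dehusk_shift = dehusk_shift),
            class = "hyperplane_model")
}

#' Classify grains as chalky and compute the sample CRK%
#'
#' Whole-grain features are first translated by the model's virtual
#' de-husking shift, then z-scored, projected into PC space and classified by
#' the sign of the hyperplane decision function (exactly 0 counts as
#' non-chalky). `crk_percent = 100 * n_chalky / n_total`.
#'
#' @param grain_features data.frame with the embedding's feature columns
#'   (whole-grain measurements).
#' @param model a `hyperplane_model`.
#' @param scaler,pca the chalkiness embedding fitted on kernel ground truth.
#' @param dehusk apply the stored de-husking shift (set `FALSE` when the
#'   inputs are already de-husked kernels).
#' @return list with logical `chalky`, numeric `decision`, `crk_percent`.
#' @export
classify_chalky <- function(grain_features, model, scaler, pca,
                            dehusk = TRUE) {
  x <- as.matrix(grain_features[scaler$feature_names])
  if (dehusk) {
    if (is.null(model$dehusk_shift))
      stopf("model carries no de-husking shift; fit it or set dehusk = FALSE")
    x <- sweep(x, 2L, as.numeric(model$dehusk_shift), `+`)
  }
  tab <- as.data.frame(x)
  names(tab) <- scaler$feature_names
  pc <- project_features(scaler, pca, tab)
  d <- as.numeric(pc %*% model$normal_pc + model$offset)
  flag <- d > 0
  list(chalky = flag, decision = d,
       crk_percent = 100 * sum(flag) / length(flag))
}

#' Fit the five-class head-rice-recovery model
#'
#' One-vs-rest linear SVMs in PC space, one per HRR class (100/80/60/40/20%),
#' each with Platt sigmoid calibration so every grain gets five class
#' membership probabilities.
#'
#' @param coords n x k PC coordinates.
#' @param classes per-grain HRR class values (subset labels from the 20 g
#'   milling subsets); at least two distinct classes required.
#' @param C soft-margin cost.
#' @return object of class `hrr_model`.
#' @export
fit_hrr_model <- function(coords, classes, C = 1) {
  x <- as.matrix(coords)
  cls <- as.numeric(classes)
  if (!all(cls %in% HRR_CLASSES)) stopf("classes must be within 100/80/60/40/20")
  present <- HRR_CLASSES[HRR_CLASSES %in% cls]
  if (length(present) < 2L) stopf("need at least two HRR classes to fit")
  per_class <- lapply(HRR_CLASSES, function(v) {
    if (!v %in% cls) return(NULL)
    y <- ifelse(cls == v, 1, -1)
    fit <- svm_linear(x, y, C = C)
    calib <- platt_calibrate(svm_decision(fit, x), y)
    list(w = fit$w, b = fit$b, A = calib$A, B = calib$B)
  })
  names(per_class) <- as.character(HRR_CLASSES)
  structure(list(class_values = HRR_CLASSES, per_class = per_class, C = C),
            class = "hrr_model")
}

#' Per-grain HRR class probabilities
#'
#' @param model an `hrr_model`.
#' @param coords n x k PC coordinates.
#' @return n x 5 matrix of probabilities, columns named by class value;
#'   absent classes get probability 0.
#' @export
predict_hrr_probs <- function(model, coords) {
  x <- as.matrix(coords)
  p <- sapply(as.character(model$class_values), function(nm) {
    m <- model$per_class[[nm]]
    if (is.null(m) || !length(m)) return(rep(0, nrow(x)))  # class absent
    platt_prob(list(A = m$A, B = m$B), as.numeric(x %*% m$w + m$b))
  })
  matrix(p, nrow = nrow(x),
         dimnames = list(NULL, as.character(model$class_values)))
}

#' Max-probability HRR class decision
#'
#' Selects the class with the highest membership probability; the selected
#' probability is reported as the prediction reliability (percent). Ties go
#' to the lowest class value (conservative recovery estimate).
#'
#' @param probabilities length-5 vector or n x 5 matrix of class
#'   probabilities ordered as (100, 80, 60, 40, 20)% HRR; values in `[0, 1]`
#'   or percent.
#' @return data.frame with `class_value` and `reliability` (percent).
#' @export
predict_grain_hrr <- function(probabilities) {
  p <- if (is.matrix(probabilities)) probabilities
       else matrix(probabilities, nrow = 1L)
  if (ncol(p) != 5L) stopf("expected 5 class probabilities")
  scale_pct <- if (max(p) > 1) 1 else 100
  if (any(p < 0) || any(p * scale_pct > 100 + 1e-9))
    stopf("probabilities must lie in [0, 1] (or [0, 100] percent)")
  cls <- apply(p, 1L, function(row) {
    best <- which(row == max(row))
    # HRR_CLASSES is decreasing, so the last tied index is the lowest class
    HRR_CLASSES[best[length(best)]]
  })
  rel <- apply(p, 1L, max) * scale_pct
  data.frame(class_value = cls, reliability = rel)
}

#' Sample-level HRR% from per-grain classes
#'
#' Arithmetic mean of the per-grain class values.
#'
#' @param per_grain_classes numeric vector of class values.
#' @return scalar HRR percent.
#' @export
aggregate_sample_hrr <- function(per_grain_classes) {
  if (!length(per_grain_classes)) stopf("no grains to aggregate")
  mean(as.numeric(per_grain_classes))
}

#' Head-rice-recovery ground-truth formula
#'
#' `HRR% = 100 * W_pg / W_op`, the polished-grain mass (kernels retaining
#' more than 75% of their length after milling) over the original paddy mass.
#'
#' @param W_pg polished grain weight, grams.
#' @param W_op original paddy weight, grams (> 0).
#' @return HRR percent.
#' @export
hrr_ground_truth <- function(W_pg, W_op) {
  if (any(W_op <= 0)) stopf("W_op must be positive")
  if (any(W_pg < 0) || any(W_pg > W_op)) stopf("W_pg must lie in [0, W_op]")
  100 * W_pg / W_op
}

#' Agreement metrics between predicted and observed trait values
#'
#' Ordinary least squares of `predicted` on `observed`; reports the fit's
#' coefficient of determination, the root-mean-square prediction error
#' `sqrt(mean((predicted - observed)^2))`, and the regression slope and
#' intercept.
#'
#' @param predicted,observed numeric vectors of equal length >= 2.
#' @return list with `r_squared`, `rmse`, `slope`, `intercept`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2L)
  if (stats::sd(observed) == 0) stopf("observed values are constant: R^2 undefined")
  fit <- stats::lm(predicted ~ observed)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  list(r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       rmse = sqrt(mean((predicted - observed)^2)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
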