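# Linear soft-margin SVM via dual coordinate descent (Hsieh et al. 2008,
# L1-loss), with the bias handled by feature augmentation. Deterministic:
# fixed sweep order, no shuffling.

#' Train a linear soft-margin SVM
#'
#' Solves the L2-regularized hinge-loss problem in the dual with coordinate
#' descent. Suitable for the low-dimensional PC-space separators used by the
#' trait models; the regularization constant is recorded in the model.
#'
#' @param x n x p matrix.
#' @param y labels in \{-1, +1\} (or logical / 0-1, coerced).
#' @param C soft-margin cost (default 1, fixed for reproducibility).
#' @param max_iter maximum passes over the data.
#' @param tol convergence tolerance on the projected gradient spread.
#' @return object of class `linear_svm` with `w` (length p), `b`, `C`.
#' @export
svm_linear <- function(x, y, C = 1, max_iter = 5000L, tol = 1e-9) {
  x <- as.matrix(x)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (all(y %in% c(0, 1))) y <- ifelse(y > 0, 1, -1)
  if (!all(y %in% c(-1, 1))) stopf("labels must be binary")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  xa <- cbind(x, bias = 1)           # augmented bias (regularized)
  n <- nrow(xa); p <- ncol(xa)
  alpha <- numeric(n)
  w <- numeric(p)
  qii <- rowSums(xa^2)
  for (iter in seq_len(max_iter)) {
    pg_max <- -Inf; pg_min <- Inf
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * xa[i, ]) - 1
      pg <- g
      if (alpha[i] <= 0) pg <- min(g, 0)
      else if (alpha[i] >= C) pg <- max(g, 0)
      pg_max <- max(pg_max, pg); pg_min <- min(pg_min, pg)
      if (abs(pg) > 1e-14) {
        a_new <- min(max(alpha[i] - g / qii[i], 0), C)
        d <- a_new - alpha[i]
        if (d != 0) {
          w <- w + d * y[i] * xa[i, ]
          alpha[i] <- a_new
        }
      }
    }
    if (pg_max - pg_min < tol) break
  }
  structure(list(w = unname(w[seq_len(p - 1L)]), b = unname(w[p]), C = C,
                 iterations = iter), class = "linear_svm")
}

#' SVM decision values
#'
#' @param model a `linear_svm`.
#' @param x n x p matrix.
#' @return numeric vector `x %*% w + b`.
#' @export
svm_decision <- function(model, x) {
  as.numeric(as.matrix(x) %*% model$w + model$b)
}

#' Platt sigmoid calibration of decision values
#'
#' Fits `P(y = 1 | d) = 1 / (1 + exp(A d + B))` by minimizing the
#' cross-entropy with Platt's smoothed targets, which keeps the fit finite on
#' separable data.
#'
#' @param decision decision values on training data.
#' @param y binary labels (logical or -1/+1).
#' @return list with `A`, `B`.
#' @export
platt_calibrate <- function(decision, y) {
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  pos <- y > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  t <- ifelse(pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    f <- par[1] * decision + par[2]
    # stable log(1 + exp(f)) and cross-entropy
    lse <- ifelse(f > 30, f, log1p(exp(pmin(f, 30))))
    sum(t * lse + (1 - t) * (lse - f))
  }
  fit <- stats::optim(c(A = -1, B = 0), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

platt_prob <- function(calib, decision) {
  1 / (1 + exp(calib$A * decision + calib$B))
}
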