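test_that("Mahalanobis distance matches closed forms and a brute-force oracle", {
  id_model <- structure(list(mean_pc = c(0, 0, 0), covariance_pc = diag(3),
                             theta_chaffy = 17),
                        class = "chaffy_cluster_model")
  expect_equal(mahalanobis_distance(c(3, 4, 0), id_model), 5)

  dm <- id_model
  dm$covariance_pc <- diag(c(4, 1, 1))
  expect_equal(mahalanobis_distance(c(2, 0, 0), dm), 1)

  set.seed(44)
  A <- matrix(rnorm(9), 3)
  S <- crossprod(A) + diag(3) * 0.1
  mu <- rnorm(3)
  m <- structure(list(mean_pc = mu, covariance_pc = S, theta_chaffy = 17),
                 class = "chaffy_cluster_model")
  X <- matrix(rnorm(300), ncol = 3)
  d <- mahalanobis_distance(X, m)
  Sinv <- solve(S)                     # explicit-inverse oracle
  d_oracle <- apply(X, 1, function(x) sqrt(drop(t(x - mu) %*% Sinv %*% (x - mu))))
  expect_equal(d, d_oracle, tolerance = 1e-9)

  bad <- m
  bad$covariance_pc <- matrix(0, 3, 3)
  expect_error(mahalanobis_distance(c(1, 1, 1), bad), "singular")
})

test_that("chaffy classification uses a strict threshold and monotone response", {
  m <- structure(list(mean_pc = rep(0, 3), covariance_pc = diag(3),
                      theta_chaffy = 17),
                 class = "chaffy_cluster_model")
  pts <- rbind(c(16.99, 0, 0), c(17, 0, 0), c(17.01, 0, 0))
  res <- classify_chaffy(pts, m)
  expect_identical(res$chaffy, c(FALSE, FALSE, TRUE))
  expect_identical(res$chaffy_count, 1L)

  set.seed(10)
  X <- matrix(rnorm(600, 0, 8), ncol = 3)
  counts <- vapply(seq(1, 30, by = 0.5), function(th) {
    m$theta_chaffy <- th
    classify_chaffy(X, m)$chaffy_count
  }, integer(1))
  expect_true(all(diff(counts) <= 0))

  # permutation invariance of the count
  perm <- sample(nrow(X))
  expect_identical(classify_chaffy(X[perm, ], m)$chaffy_count,
                   classify_chaffy(X, m)$chaffy_count)
})

test_that("the chaffy cluster fit stores sample moments and handles degeneracy", {
  set.seed(2)
  X <- matrix(rnorm(120), ncol = 3)
  m <- fit_chaffy_cluster(X)
  expect_equal(m$mean_pc, colMeans(X))
  expect_equal(m$covariance_pc, stats::cov(X))
  expect_equal(m$theta_chaffy, 17)

  expect_equal(fit_chaffy_cluster(X[sample(40), ])$covariance_pc,
               m$covariance_pc, tolerance = 1e-12)

  planar <- cbind(rnorm(10), rnorm(10), 0)   # rank 2 in 3-D
  expect_warning(mp <- fit_chaffy_cluster(planar), "ridge")
  expect_gt(det(mp$covariance_pc), 0)

  expect_error(fit_chaffy_cluster(X[1:3, ]), "at least 4")
  expect_error(fit_chaffy_cluster(X, theta = -1), "positive")
})

test_that("virtual de-husking is the exact population alignment", {
  x <- matrix(rnorm(60, 10, 2), ncol = 4)
  mu_grain <- colMeans(x)
  mu_gt <- c(1, 2, 3, 4)
  shifted <- virtual_dehusk(x, mu_gt, mu_grain)
  expect_equal(colMeans(shifted), mu_gt, tolerance = 1e-12)
  expect_identical(virtual_dehusk(x, mu_grain, mu_grain), x)
  expect_error(virtual_dehusk(x, c(1, 2), mu_grain), "match")
})

test_that("the chalky hyperplane separates and classifies with the stated conventions", {
  # symmetric 1-D classes embedded in 3-D: boundary at 0
  x <- cbind(c(rep(-1, 20), rep(1, 20)), 0, 0)
  chalky <- rep(c(FALSE, TRUE), each = 20)
  hp <- fit_chalky_hyperplane(x, chalky)
  expect_lt(abs(-hp$offset / hp$normal_pc[1]), 1e-6)

  dup <- fit_chalky_hyperplane(rbind(x, x), c(chalky, chalky))
  expect_equal(dup$normal_pc, hp$normal_pc, tolerance = 1e-6)

  expect_error(fit_chalky_hyperplane(x, rep(TRUE, 40)), "both")

  # decision value exactly 0 counts as non-chalky; CRK% is the flagged share
  scaler <- structure(list(feature_names = c("f2", "f3", "f4", "f6"),
                           mu = rep(0, 4), sigma = rep(1, 4)),
                      class = "feature_scaler")
  pca <- structure(list(feature_names = c("f2", "f3", "f4", "f6"),
                        component_matrix = diag(4)[, 1:3], center = rep(0, 4),
                        explained_variance_ratio = c(1, 0, 0)),
                   class = "pca_model")
  model <- structure(list(normal_pc = c(1, 0, 0), offset = 0,
                          dehusk_shift = rep(0, 4)),
                     class = "hyperplane_model")
  feats <- data.frame(f2 = c(1, 1, 1, -1, -1, -1, -1, -1, -1, 0, 0, 0),
                      f3 = 0, f4 = 0, f6 = 0)
  res <- classify_chalky(feats, model, scaler, pca)
  expect_identical(sum(res$chalky), 3L)
  expect_equal(res$crk_percent, 25)          # 3 chalky of 12
  expect_false(any(res$chalky[res$decision == 0]))
})

test_that("whole-grain phantom kernels separate after virtual de-husking", {
  # strong-contrast phantom: chalk-free vs heavily chalky kernels
  acq <- small_acq(seed = 30L, noise_sd = 30)
  mk_scene <- function(seed, husk) {
    sc <- build_scene(24L, trait_mix = list(chalky = 0.5),
                      acquisition = small_acq(seed, noise_sd = 30), seed = seed,
                      geometry = list(mu_kernel_sd = 0.002))
    sc$grains <- lapply(sc$grains, function(g) {
      g$chalk_factor <- 0.55
      g$chalk_fraction <- if (g$chalk_fraction > 0.2) 0.8 else 0
      if (!husk) g$mu_husk <- 0
      g
    })
    sc
  }
  kernels <- scene_features(mk_scene(41L, husk = FALSE))$features
  grains <- scene_features(mk_scene(41L, husk = TRUE))$features
  subset <- trait_feature_subset("crk")
  scaler <- fit_scaler(kernels, subset)
  pca <- fit_pca(scale_features(scaler, kernels), 3L)
  kc <- project_features(scaler, pca, kernels)
  shift <- colMeans(as.matrix(kernels[subset])) - colMeans(as.matrix(grains[subset]))
  hp <- fit_chalky_hyperplane(kc, kernels$chalky, dehusk_shift = shift)

  # disjoint class supports: perfect training separation
  d <- as.numeric(kc %*% hp$normal_pc + hp$offset)
  expect_identical(d > 0, kernels$chalky)

  res <- classify_chalky(grains, hp, scaler, pca, dehusk = TRUE)
  expect_gte(mean(res$chalky == grains$chalky), 0.9)
})

test_that("the HRR max-probability rule reproduces the printed worked example", {
  pred <- predict_grain_hrr(c(21, 18, 66, 75, 35))
  expect_equal(pred$class_value, 40)
  expect_equal(pred$reliability, 75)

  expect_equal(predict_grain_hrr(c(1, 0, 0, 0, 0)),
               data.frame(class_value = 100, reliability = 100))

  tie <- predict_grain_hrr(rep(0.4, 5))
  expect_equal(tie$class_value, 20)          # ties -> lowest class value
  expect_equal(tie$reliability, 40)

  expect_error(predict_grain_hrr(c(0.1, 0.2, 0.3)), "5 class")
  expect_error(predict_grain_hrr(c(-0.1, 0.2, 0.3, 0.1, 0)), "lie in")
})

test_that("one-vs-rest HRR models recover well-separated classes", {
  set.seed(12)
  mk <- function(center, v, n = 40) cbind(rnorm(n, center, 0.3),
                                          rnorm(n, -center, 0.3),
                                          rnorm(n, 0, 0.3))
  train <- rbind(mk(-4), mk(4))
  cls <- rep(c(100, 20), each = 40)
  m <- fit_hrr_model(train, cls)
  test_x <- rbind(mk(-4, n = 25), mk(4, n = 25))
  test_y <- rep(c(100, 20), each = 25)
  probs <- predict_hrr_probs(m, test_x)
  expect_true(all(probs >= 0 & probs <= 1))
  pred <- predict_grain_hrr(probs)
  expect_gte(mean(pred$class_value == test_y), 0.95)

  # permuting training rows leaves class predictions unchanged
  perm <- sample(80)
  m2 <- fit_hrr_model(train[perm, ], cls[perm])
  expect_identical(predict_grain_hrr(predict_hrr_probs(m2, test_x))$class_value,
                   pred$class_value)

  expect_error(fit_hrr_model(train, rep(100, 80)), "two HRR classes")
  expect_error(fit_hrr_model(train, rep(c(95, 20), each = 40)), "within")
})

test_that("aggregation, the HRR formula and the evaluation metrics are exact", {
  expect_equal(aggregate_sample_hrr(c(40, 60, 60, 80)), 60)
  expect_equal(aggregate_sample_hrr(rep(20, 7)), 20)
  expect_equal(aggregate_sample_hrr(c(100, 80, 60, 40, 20)), 60)
  expect_error(aggregate_sample_hrr(numeric()), "no grains")

  expect_equal(hrr_ground_truth(15, 20), 75)
  expect_equal(hrr_ground_truth(0, 20), 0)
  expect_equal(hrr_ground_truth(20, 20), 100)
  expect_error(hrr_ground_truth(5, 0), "positive")
  expect_error(hrr_ground_truth(25, 20), "W_pg")

  obs <- c(1, 2, 3, 4)
  ev <- evaluate_predictions(obs, obs)
  expect_equal(unlist(ev), c(r_squared = 1, rmse = 0, slope = 1, intercept = 0))

  ev2 <- evaluate_predictions(c(1, 3, 2, 4) + c(1, -1, 1, -1), c(1, 3, 2, 4))
  expect_equal(ev2$rmse, 1)

  # closed-form OLS oracle on a small hand table
  x <- c(1, 2, 4, 5, 7)
  y <- c(2.2, 2.8, 5.1, 5.4, 8.3)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_o <- mean(y) - slope_o * mean(x)
  r2_o <- slope_o^2 * sum((x - mean(x))^2) / sum((y - mean(y))^2)
  ev3 <- evaluate_predictions(y, x)
  expect_equal(ev3$slope, slope_o, tolerance = 1e-9)
  expect_equal(ev3$intercept, int_o, tolerance = 1e-9)
  expect_equal(ev3$r_squared, r2_o, tolerance = 1e-9)

  expect_error(evaluate_predictions(c(1, 2), c(3, 3)), "constant")
})
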