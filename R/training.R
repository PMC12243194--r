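# End-to-end phantom experiments: render, normalize, segment, extract
# features, and fit the per-trait models. These are the same code paths the
# acceptance checks and the CLI use.

#' Run the image half of the pipeline on one scene
#'
#' Render (or accept) a radiograph, normalize it, segment grains and extract
#' features, then align segments with the scene ground truth by nearest true
#' center.
#'
#' @param scene a [phantom_scene].
#' @param min_area_px,struct_radius segmentation parameters.
#' @return list with `radiograph`, `attenuation`, `segments`, `features`
#'   (feature table joined with matched truth columns) and `truth`.
#' @export
scene_features <- function(scene, min_area_px = 50L, struct_radius = 1.5) {
  rad <- render_radiograph(scene)
  att <- normalize_radiograph(rad, I0 = "auto")
  segs <- segment_grains(att, min_area_px = min_area_px,
                         struct_radius = struct_radius)
  feats <- features_table(segs, att)
  truth <- scene_truth(scene)
  if (nrow(feats)) {
    ctr <- segment_centroids(segs)
    nearest <- apply(ctr, 1L, function(p)
      which.min((truth$center_row - p[1])^2 + (truth$center_col - p[2])^2))
    feats$truth_id <- truth$id[nearest]
    feats$match_dist <- sqrt((truth$center_row[nearest] - ctr[, 1])^2 +
                             (truth$center_col[nearest] - ctr[, 2])^2)
    feats$chaffy <- truth$chaffy[nearest]
    feats$chalky <- truth$chalky[nearest]
    feats$hrr_class <- truth$hrr_class[nearest]
  }
  list(radiograph = rad, attenuation = att, segments = segs,
       features = feats, truth = truth)
}

# smaller-than-default holder used by the training experiments so the
# documented phantom experiments stay desk-scale; grains remain life-size
experiment_acquisition <- function(seed, noise_sd_frac = 0.005,
                                   detector = c(660L, 2304L)) {
  acquisition_model(background_I0 = 12000L, detector_shape = detector,
                    noise_sd = noise_sd_frac * 12000, rng_seed = seed)
}

#' Train the chaffiness model on phantom scenes
#'
#' Renders training scenes with a chaffy/non-chaffy mix, embeds all eight
#' features (z-transform + 3-component PCA fitted on all training grains) and
#' fits the non-chaffy reference cluster.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param n_scenes number of training scenes.
#' @param n_grains grains per scene.
#' @param theta Mahalanobis decision threshold.
#' @return list with `scaler`, `pca`, `cluster`, and the training `features`.
#' @export
train_chaffiness_models <- function(seed = 1L, n_scenes = 2L, n_grains = 60L,
                                    theta = 17) {
  feats <- do.call(rbind, lapply(seq_len(n_scenes), function(i) {
    sc <- build_scene(n_grains, trait_mix = list(chaffy = 0.3),
                      acquisition = experiment_acquisition(seed * 1000L + i),
                      seed = seed * 100L + i)
    scene_features(sc)$features
  }))
  subset <- trait_feature_subset("chaffiness")
  scaler <- fit_scaler(feats, subset)
  pca <- fit_pca(scale_features(scaler, feats), 3L)
  coords <- project_features(scaler, pca, feats)
  cluster <- fit_chaffy_cluster(coords[!feats$chaffy, , drop = FALSE],
                                theta = theta)
  list(scaler = scaler, pca = pca, cluster = cluster, features = feats)
}

# render the same grain population de-husked: husk attenuation switched off
# (the kernel geometry is untouched), emulating the paired kernel scans used
# to calibrate the virtual de-husking shift
dehusk_scene <- function(scene) {
  scene$grains <- lapply(scene$grains, function(g) { g$mu_husk <- 0; g })
  scene
}

#' Train the chalky-kernel model with virtual de-husking
#'
#' Builds paired phantom populations (kernels without husk attenuation vs the
#' same whole grains), fits the chalkiness embedding and hyperplane on the
#' kernel ground truth, and stores the per-feature de-husking shift
#' `mu_GT - mu_grain` estimated from the pair.
#'
#' @param seed integer seed.
#' @param n_scenes training scenes.
#' @param n_grains grains per scene.
#' @param C soft-margin cost.
#' @return list with `scaler`, `pca`, `hyperplane`, plus the kernel and
#'   whole-grain training tables.
#' @export
train_crk_models <- function(seed = 1L, n_scenes = 2L, n_grains = 60L, C = 1) {
  kernel_feats <- NULL; grain_feats <- NULL
  for (i in seq_len(n_scenes)) {
    sc <- build_scene(n_grains, trait_mix = list(chalky = 0.5),
                      acquisition = experiment_acquisition(seed * 2000L + i),
                      seed = seed * 200L + i)
    grain_feats <- rbind(grain_feats, scene_features(sc)$features)
    kernel_feats <- rbind(kernel_feats, scene_features(dehusk_scene(sc))$features)
  }
  subset <- trait_feature_subset("crk")
  scaler <- fit_scaler(kernel_feats, subset)
  pca <- fit_pca(scale_features(scaler, kernel_feats), 3L)
  kc <- project_features(scaler, pca, kernel_feats)
  shift <- colMeans(as.matrix(kernel_feats[subset])) -
    colMeans(as.matrix(grain_feats[subset]))
  hyper <- fit_chalky_hyperplane(kc, kernel_feats$chalky, C = C,
                                 dehusk_shift = shift)
  list(scaler = scaler, pca = pca, hyperplane = hyper,
       kernel_features = kernel_feats, grain_features = grain_feats)
}

#' Within-subset grain geometry for HRR experiments
#'
#' A 20 g milling subset comes from one cultivar and one harvest, so its
#' grain-to-grain geometric and density variation (about 2% CV) is far
#' smaller than the across-cultivar spread of the default geometry; the
#' class-conditional size/density/mottle map then carries the between-class
#' signal.
#'
#' @return geometry override list for [build_scene()].
#' @export
hrr_subset_geometry <- function() {
  list(a_sd = 0.84, b_sd = 0.24, mu_kernel_sd = 0.002)
}

#' Train the five-class HRR model on phantom scenes
#'
#' Each training scene carries one HRR class (emulating the 20 g milling
#' subsets, whose single ground-truth value labels every grain in the
#' subset); features f1, f3, f4, f5, f7 are embedded and one-vs-rest
#' calibrated linear SVMs fitted.
#'
#' @param seed integer seed.
#' @param scenes_per_class scenes rendered per HRR class.
#' @param n_grains grains per scene.
#' @param C soft-margin cost.
#' @return list with `scaler`, `pca`, `hrr`, and the training `features`.
#' @export
train_hrr_models <- function(seed = 1L, scenes_per_class = 1L, n_grains = 40L,
                             C = 1) {
  feats <- NULL
  for (v in HRR_CLASSES) for (i in seq_len(scenes_per_class)) {
    mix <- stats::setNames(as.numeric(HRR_CLASSES == v),
                           as.character(HRR_CLASSES))
    sc <- build_scene(n_grains, trait_mix = list(hrr = mix),
                      acquisition = experiment_acquisition(seed * 3000L + v + i),
                      seed = seed * 300L + v + i,
                      geometry = hrr_subset_geometry())
    feats <- rbind(feats, scene_features(sc)$features)
  }
  subset <- trait_feature_subset("hrr")
  scaler <- fit_scaler(feats, subset)
  pca <- fit_pca(scale_features(scaler, feats), 3L)
  coords <- project_features(scaler, pca, feats)
  hrr <- fit_hrr_model(coords, feats$hrr_class, C = C)
  list(scaler = scaler, pca = pca, hrr = hrr, features = feats)
}
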