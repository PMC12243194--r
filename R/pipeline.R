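# End-to-end orchestration: simulate/load -> normalize -> segment ->
# features -> embed -> predict -> report, with YAML config and reproducible
# artifacts.

default_config <- function() {
  list(
    phantom = list(n_grains = 100L, trait_mix = list(chaffy = 0.1),
                   seed = 1L, detector = c(660L, 2304L), noise_sd_frac = 0.005),
    input = NULL,                       # alternative: path to a radiograph
    traits = c("chaffiness"),
    models = NULL,                      # named list of model-bundle paths
    train_seed = 1L,                    # used when models are trained in-run
    theta_chaffy = 17,
    min_area_px = 50L,
    struct_radius = 1.5,
    out_dir = "grainray_run"
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

#' Run the full trait pipeline
#'
#' Executes the workflow stages in order — simulate (or load), normalize,
#' segment, extract features, embed, predict the requested traits — and
#' writes every intermediate artifact plus a sample-level JSON report and a
#' per-grain CSV under `out_dir`. Model bundles are either loaded from
#' `config$models` (checked up-front, before any image processing) or trained
#' in-run from phantom experiments seeded by `config$train_seed`.
#'
#' @param config a named list (see `grainray::default` values in the
#'   vignette) or the path to a YAML file with the same structure.
#' @return the sample trait report, invisibly a list with `n_grains`,
#'   `chaffy_count`, `crk_percent`, `hrr_percent_predicted` and the
#'   `per_grain` table.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  traits <- match.arg(cfg$traits, c("chaffiness", "crk", "hrr"),
                      several.ok = TRUE)

  # resolve models before touching any image
  models <- list()
  if (!is.null(cfg$models)) {
    for (tr in traits) {
      path <- cfg$models[[tr]]
      if (is.null(path) || !file.exists(path))
        stopf("model file for trait '%s' not found: %s", tr,
              path %||% "<missing>")
      models[[tr]] <- read_model(path)
    }
  } else {
    for (tr in traits) {
      models[[tr]] <- switch(tr,
        chaffiness = train_chaffiness_models(seed = cfg$train_seed,
                                             theta = cfg$theta_chaffy),
        crk = train_crk_models(seed = cfg$train_seed),
        hrr = train_hrr_models(seed = cfg$train_seed))
      write_model(models[[tr]][setdiff(names(models[[tr]]),
                                       c("features", "kernel_features",
                                         "grain_features"))],
                  file.path(cfg$out_dir, paste0("model_", tr, ".json")))
    }
  }

  scene <- NULL
  if (!is.null(cfg$input)) {
    rad <- read_radiograph(cfg$input)
  } else {
    ph <- cfg$phantom
    scene <- build_scene(ph$n_grains, trait_mix = ph$trait_mix,
                         acquisition = acquisition_model(
                           detector_shape = as.integer(ph$detector),
                           noise_sd = ph$noise_sd_frac * 12000,
                           rng_seed = ph$seed),
                         seed = ph$seed)
    rad <- render_radiograph(scene)
    write_truth_table(scene, file.path(cfg$out_dir, "truth.csv"))
  }
  write_pgm(rad$pixels, file.path(cfg$out_dir, "radiograph.pgm"))
  write_png_preview(rad$pixels, file.path(cfg$out_dir, "radiograph_preview.png"))

  att <- normalize_radiograph(rad, I0 = "auto")
  write_float_image(att$values, file.path(cfg$out_dir, "attenuation.tsv"))

  segs <- segment_grains(att, min_area_px = cfg$min_area_px,
                         struct_radius = cfg$struct_radius)
  write_pgm(attr(segs, "label_image"),
            file.path(cfg$out_dir, "labels.pgm"))
  utils::write.csv(segments_table(segs),
                   file.path(cfg$out_dir, "segments.csv"), row.names = FALSE)

  feats <- features_table(segs, att)
  utils::write.csv(format(feats, digits = 9, trim = TRUE, scientific = FALSE),
                   file.path(cfg$out_dir, "features.csv"), row.names = FALSE,
                   quote = FALSE)

  per_grain <- data.frame(label = feats$label)
  report <- list(n_grains = nrow(feats))
  if ("chaffiness" %in% traits) {
    m <- models$chaffiness
    coords <- project_features(m$scaler, m$pca, feats)
    res <- classify_chaffy(coords, m$cluster)
    per_grain$chaffy <- res$chaffy
    per_grain$mahalanobis <- res$distance
    report$chaffy_count <- res$chaffy_count
  }
  if ("crk" %in% traits) {
    m <- models$crk
    res <- classify_chalky(feats, m$hyperplane, m$scaler, m$pca, dehusk = TRUE)
    per_grain$chalky <- res$chalky
    report$crk_percent <- res$crk_percent
  }
  if ("hrr" %in% traits) {
    m <- models$hrr
    coords <- project_features(m$scaler, m$pca, feats)
    probs <- predict_hrr_probs(m$hrr, coords)
    pred <- predict_grain_hrr(probs)
    per_grain$hrr_class <- pred$class_value
    per_grain$hrr_reliability <- pred$reliability
    report$hrr_percent_predicted <- aggregate_sample_hrr(pred$class_value)
  }
  utils::write.csv(format(per_grain, digits = 9, trim = TRUE,
                          scientific = FALSE),
                   file.path(cfg$out_dir, "per_grain.csv"),
                   row.names = FALSE, quote = FALSE)
  report$per_grain <- per_grain
  out <- report
  out$per_grain <- NULL
  jsonlite::write_json(out, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 9)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config_resolved.yaml"))
  invisible(report)
}

#' Generate the canonical test fixture suite
#'
#' Writes the fixtures used throughout the test suite — blank image, single
#' grain, touching pair, and one 100-grain scene per trait — each with a
#' truth table, plus a manifest CSV listing every file with its checksum.
#'
#' @param out_dir output directory.
#' @param seed integer seed; identical seeds give identical checksums.
#' @return data.frame manifest (file, md5), invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(scene, stem) {
    rad <- render_radiograph(scene)
    p1 <- file.path(out_dir, paste0(stem, ".pgm"))
    p2 <- file.path(out_dir, paste0(stem, "_truth.csv"))
    write_pgm(rad$pixels, p1)
    write_truth_table(scene, p2)
    files <<- c(files, p1, p2)
  }
  acq_small <- acquisition_model(detector_shape = c(200L, 300L),
                                 noise_sd = 0, rng_seed = seed)
  blank <- phantom_scene(list(), acq_small)
  emit(blank, "blank")
  single <- phantom_scene(list(grain_spec(1L, c(99.5, 149.5), c(40, 13),
                                          12.3)), acq_small)
  emit(single, "single_grain")
  emit(touching_pair_scene(acq_small), "touching_pair")
  for (tr in c("chaffiness", "crk", "hrr")) {
    mix <- switch(tr, chaffiness = list(chaffy = 0.2),
                  crk = list(chalky = 0.4),
                  hrr = list(hrr = c(`100` = 0.2, `80` = 0.2, `60` = 0.2,
                                     `40` = 0.2, `20` = 0.2)))
    sc <- build_scene(100L, trait_mix = mix,
                      acquisition = acquisition_model(
                        detector_shape = c(660L, 2304L),
                        noise_sd = 60, rng_seed = seed + 10L),
                      seed = seed)
    emit(sc, paste0("scene_", tr))
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = vapply(files, function(f) digest::digest(file = f, algo = "md5"),
                 character(1)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
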