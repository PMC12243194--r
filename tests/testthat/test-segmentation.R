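test_that("blank and constant images yield no segments", {
  blank <- attenuation_image(matrix(0, 80, 80), 12000L)
  expect_length(segment_grains(blank), 0L)
  noisy <- attenuation_image(matrix(rnorm(80 * 80, 0, 0.005), 80, 80), 12000L)
  expect_length(segment_grains(noisy), 0L)
})

test_that("non-touching grains are recovered one segment per grain", {
  sc <- build_scene(25L, trait_mix = list(chaffy = 0.2),
                    acquisition = small_acq(seed = 6L), seed = 6L)
  att <- normalize_radiograph(render_radiograph(sc))
  segs <- segment_grains(att)
  expect_length(segs, 25L)

  # centroid bijection within 2 px of the true centers
  truth <- scene_truth(sc)
  ctr <- segment_centroids(segs)
  nearest <- apply(ctr, 1L, function(p)
    which.min((truth$center_row - p[1])^2 + (truth$center_col - p[2])^2))
  expect_setequal(nearest, seq_len(25L))
  d <- sqrt((truth$center_row[nearest] - ctr[, 1])^2 +
            (truth$center_col[nearest] - ctr[, 2])^2)
  expect_lt(max(d), 2)

  # labels contiguous from 1, pixel sets pairwise disjoint, bbox-ordered
  expect_identical(vapply(segs, `[[`, integer(1), "label"), 1:25)
  keys <- lapply(segs, function(s) s$pixels[, 1] * 1e6 + s$pixels[, 2])
  expect_identical(anyDuplicated(unlist(keys)), 0L)
  origins <- t(vapply(segs, function(s) s$bbox[1:2], numeric(2)))
  expect_identical(order(origins[, 1], origins[, 2]), 1:25)
})

test_that("grain insertion order does not change the segmentation", {
  sc <- build_scene(10L, acquisition = small_acq(seed = 2L, noise_sd = 0),
                    seed = 12L)
  rev_sc <- sc
  rev_sc$grains <- rev(sc$grains)
  s1 <- segment_grains(normalize_radiograph(render_radiograph(sc)))
  s2 <- segment_grains(normalize_radiograph(render_radiograph(rev_sc)))
  expect_identical(lapply(s1, `[[`, "pixels"), lapply(s2, `[[`, "pixels"))
})

test_that("the instance watershed splits a touching pair", {
  sc <- touching_pair_scene()
  att <- normalize_radiograph(render_radiograph(sc))
  segs <- segment_grains(att)
  expect_length(segs, 2L)
  ctr <- segment_centroids(segs)
  truth <- scene_truth(sc)
  expect_lt(max(abs(sort(ctr[, 2]) - sort(truth$center_col))), 4)
})

test_that("opening-based cleanup matches a brute-force oracle", {
  # rectangle with a one-pixel spur: spur removed, rectangle intact
  mask <- matrix(FALSE, 30, 50)
  mask[8:27, 6:45] <- TRUE           # 20 x 40 solid rectangle
  mask[7, 20] <- TRUE                # spur
  mask[3, 3] <- TRUE                 # isolated single pixel
  lab <- grainray:::cpp_label_components(mask)
  segs <- grainray:::segments_from_labels(lab)
  cleaned <- clean_segments(segs, min_area_px = 50L, struct_radius = 1.5)
  expect_length(cleaned, 1L)
  expect_equal(cleaned[[1]]$area_px, 20L * 40L)

  oracle <- brute_opening(mask, 1.5)
  got <- attr(cleaned, "label_image") > 0
  # oracle keeps nothing of the isolated pixel either
  expect_identical(got, oracle & matrix(TRUE, 30, 50))
})

test_that("cleanup drops sub-threshold blobs and relabels contiguously", {
  mask <- matrix(FALSE, 40, 40)
  mask[5:14, 5:14] <- TRUE      # area 100
  mask[25:27, 25:27] <- TRUE    # area 9 -> dropped at min_area 50
  segs <- grainray:::segments_from_labels(grainray:::cpp_label_components(mask))
  expect_length(segs, 2L)
  cleaned <- clean_segments(segs, min_area_px = 50L)
  expect_length(cleaned, 1L)
  expect_identical(cleaned[[1]]$label, 1L)
})

test_that("rcpp primitives agree with small brute-force checks", {
  set.seed(42)
  mask <- matrix(runif(400) < 0.4, 20, 20)
  ed <- grainray:::cpp_edt(mask)
  # oracle: exact nearest-background distance by exhaustive search
  bg <- which(!mask, arr.ind = TRUE)
  for (idx in sample(which(mask), 25)) {
    r <- (idx - 1) %% 20 + 1; c <- (idx - 1) %/% 20 + 1
    d <- min(sqrt((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
    expect_equal(ed[r, c], d, tolerance = 1e-12)
  }
  expect_true(all(ed[!mask] == 0))

  lab <- grainray:::cpp_label_components(mask)
  expect_true(all((lab > 0) == mask))
  # 8-connected neighbours share a label
  for (r in 2:19) for (c in 2:19) if (mask[r, c]) {
    nb <- lab[(r - 1):(r + 1), (c - 1):(c + 1)]
    expect_true(all(nb[nb > 0] == lab[r, c] | !mask[r, c]))
  }
})
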