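test_that("build_scene honours trait mixes and the determinism contract", {
  acq <- small_acq()
  sc <- build_scene(20L, trait_mix = list(chaffy = 0), acquisition = acq,
                    seed = 3L)
  expect_length(sc$grains, 20L)
  expect_equal(sum(scene_truth(sc)$chaffy), 0L)

  sc2 <- build_scene(10L, trait_mix = list(chaffy = 0.5), acquisition = acq,
                     seed = 9L)
  expect_equal(sum(scene_truth(sc2)$chaffy), 5L)

  a <- build_scene(12L, trait_mix = list(chaffy = 0.25, chalky = 0.25),
                   acquisition = acq, seed = 7L)
  b <- build_scene(12L, trait_mix = list(chaffy = 0.25, chalky = 0.25),
                   acquisition = acq, seed = 7L)
  expect_identical(a, b)

  expect_error(build_scene(10000L, acquisition = acq), "capacity")
})

test_that("projected thickness matches the closed form and the root-finding oracle", {
  g <- grain_spec(1L, c(50, 50), c(10, 10), 5, husk_thickness_px = 2)
  th <- projected_thickness(g, c(50, 50))
  expect_equal(th$t_husk + th$t_kernel, 10)   # 2c at the apex
  expect_equal(th$t_kernel, 6)                # inner c = 3
  expect_equal(unlist(projected_thickness(g, c(50, 65))), c(t_husk = 0, t_kernel = 0))

  gch <- grain_spec(2L, c(50, 50), c(10, 10), 5, husk_thickness_px = 2,
                    chaffy = TRUE)
  expect_equal(projected_thickness(gch, c(50, 50))$t_kernel, 0)

  g2 <- grain_spec(3L, c(40, 60), c(14, 6), 5.5, husk_thickness_px = 1.3,
                   orientation_rad = 0.4)
  set.seed(11)
  px <- cbind(runif(1000, 20, 60), runif(1000, 40, 80))
  th <- projected_thickness(g2, px)
  co <- cos(0.4); si <- sin(0.4)
  for (i in seq_len(1000)) {
    dx <- px[i, 2] - 60; dy <- px[i, 1] - 40
    x <- dx * co + dy * si; y <- -dx * si + dy * co
    t_out <- rootfind_thickness(x, y, 14, 6, 5.5)
    t_in <- rootfind_thickness(x, y, 14 - 1.3, 6 - 1.3, 5.5 - 1.3)
    expect_equal(th$t_husk[i], t_out - t_in, tolerance = 1e-6)
    expect_equal(th$t_kernel[i], t_in, tolerance = 1e-6)
  }
})

test_that("rendering follows Beer-Lambert with deterministic noise", {
  acq <- acquisition_model(detector_shape = c(120L, 120L), noise_sd = 0)
  empty <- phantom_scene(list(), acq)
  img <- render_radiograph(empty)
  expect_true(all(img$pixels == 12000))

  g <- grain_spec(1L, c(60, 60), c(30, 10), 9.5, husk_thickness_px = 1.8)
  sc <- phantom_scene(list(g), acq)
  img <- render_radiograph(sc)
  th <- projected_thickness(g, c(60, 60))
  expected <- 12000 * exp(-(g$mu_husk * th$t_husk + g$mu_kernel * th$t_kernel))
  expect_lte(abs(img$pixels[61, 61] - expected), 0.5)

  # histogram mode of a noise-free render is exactly I0
  expect_identical(estimate_background(img), 12000L)

  # chaffy twin attenuates strictly less in total
  gch <- grain_spec(1L, c(60, 60), c(30, 10), 9.5, husk_thickness_px = 1.8,
                    chaffy = TRUE)
  img_ch <- render_radiograph(phantom_scene(list(gch), acq))
  att <- function(m) sum(-log(m$pixels / 12000))
  expect_lt(att(img_ch), att(img))

  # identical seeds give bit-identical noisy renders
  acqn <- acquisition_model(detector_shape = c(120L, 120L), noise_sd = 40,
                            rng_seed = 5L)
  r1 <- render_radiograph(phantom_scene(list(g), acqn))
  r2 <- render_radiograph(phantom_scene(list(g), acqn))
  expect_identical(r1$pixels, r2$pixels)
})

test_that("raising kernel attenuation darkens only the kernel footprint", {
  acq <- acquisition_model(detector_shape = c(120L, 120L), noise_sd = 0)
  mk <- function(mu) phantom_scene(list(
    grain_spec(1L, c(60, 60), c(30, 10), 9.5, mu_kernel = mu)), acq)
  lo <- render_radiograph(mk(0.08))$pixels
  hi <- render_radiograph(mk(0.12))$pixels
  g <- grain_spec(1L, c(60, 60), c(30, 10), 9.5)
  px <- as.matrix(expand.grid(row = 0:119, col = 0:119))
  tk <- projected_thickness(g, px)$t_kernel
  inside <- matrix(tk > 0, 120, 120)
  expect_true(all(hi[inside] < lo[inside]))
  expect_identical(hi[!inside], lo[!inside])
})

test_that("truth tables apply the strict 20% chalky-area rule", {
  acq <- small_acq()
  g1 <- grain_spec(1L, c(100, 100), c(40, 13), 12, chalk_fraction = 0.25)
  g2 <- grain_spec(2L, c(100, 400), c(40, 13), 12, chalk_fraction = 0.20)
  sc <- phantom_scene(list(g1, g2), acq)
  tr <- scene_truth(sc)
  expect_identical(tr$chalky, c(TRUE, FALSE))

  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(sc, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_identical(back$chalky, c(TRUE, FALSE))

  sc100 <- build_scene(100L, acquisition = acquisition_model(
    detector_shape = c(660L, 2304L)), seed = 2L)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(sc100, p2)
  expect_equal(nrow(utils::read.csv(p2)), 100L)
})

test_that("grain invariants are enforced", {
  expect_error(grain_spec(1L, c(5, 5), c(-1, 2), 2), "positive")
  expect_error(grain_spec(1L, c(5, 5), c(4, 3), 3, husk_thickness_px = 3.5),
               "husk_thickness")
  expect_error(grain_spec(1L, c(5, 5), c(4, 3), 3, chaffy = TRUE,
                          chalk_fraction = 0.4), "chaffy")
  expect_error(phantom_scene(list(grain_spec(1L, c(2, 2), c(40, 13), 12)),
                             small_acq()), "detector")
  overlapping <- list(grain_spec(1L, c(100, 100), c(40, 13), 12),
                      grain_spec(2L, c(100, 140), c(40, 13), 12))
  expect_error(phantom_scene(overlapping, small_acq(),
                             grid_layout = list(n_rows = 1, n_cols = 2,
                                                pitch_px = c(40, 40))),
               "overlap")
})
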