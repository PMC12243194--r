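#' Specification of a single phantom grain
#'
#' A paddy grain is modelled as two coaxial ellipsoids: an outer one bounding
#' the husk and an inner one (the outer semi-axes each reduced by
#' `husk_thickness_px`) holding the kernel. A chaffy grain has no kernel; a
#' chalky inclusion multiplies the kernel attenuation by `chalk_factor` inside
#' a sub-ellipse covering `chalk_fraction` of the kernel footprint.
#'
#' @param id positive integer grain id.
#' @param center_px numeric length-2 (row, col) in pixels.
#' @param semi_axes_px numeric length-2 (a, b): in-plane semi-axes, pixels.
#' @param depth_semi_axis_px c: semi-axis along the beam, pixels.
#' @param orientation_rad in-plane rotation of the major axis, radians.
#' @param husk_thickness_px husk shell thickness, pixels; must be positive and
#'   smaller than `min(a, b)`.
#' @param mu_husk,mu_kernel linear attenuation per pixel length (>= 0).
#' @param chaffy logical; `TRUE` means the kernel is absent.
#' @param chalk_fraction fraction of the kernel footprint occupied by the
#'   chalky inclusion, in `[0, 1]`; must be 0 for chaffy grains.
#' @param chalk_factor multiplier applied to `mu_kernel` inside the inclusion.
#' @param hrr_class one of 100, 80, 60, 40, 20 (percent head-rice recovery
#'   class) or `NA`.
#' @param mottle_sd relative SD of multiplicative within-kernel density
#'   mottle (texture heterogeneity; raises the grey-value SD feature).
#' @return an object of class `grain_spec`.
#' @export
grain_spec <- function(id, center_px, semi_axes_px, depth_semi_axis_px,
                       orientation_rad = 0, husk_thickness_px = 1.5,
                       mu_husk = 0.025, mu_kernel = 0.10,
                       chaffy = FALSE, chalk_fraction = 0,
                       chalk_factor = 0.85, hrr_class = NA_real_,
                       mottle_sd = 0) {
  stopifnot(length(center_px) == 2L, length(semi_axes_px) == 2L)
  if (any(semi_axes_px <= 0) || depth_semi_axis_px <= 0)
    stopf("grain %s: semi-axes must be strictly positive", id)
  if (husk_thickness_px <= 0 || husk_thickness_px >= min(semi_axes_px, depth_semi_axis_px))
    stopf("grain %s: husk_thickness_px must lie in (0, min(a, b, c))", id)
  if (mu_husk < 0 || mu_kernel < 0) stopf("attenuation must be >= 0")
  if (chalk_fraction < 0 || chalk_fraction > 1)
    stopf("chalk_fraction must be in [0, 1]")
  if (chaffy && chalk_fraction > 0)
    stopf("grain %s: chaffy grains cannot carry chalk", id)
  if (!is.na(hrr_class) && !hrr_class %in% c(100, 80, 60, 40, 20))
    stopf("hrr_class must be one of 100/80/60/40/20")
  structure(list(
    id = as.integer(id), center_px = as.numeric(center_px),
    semi_axes_px = as.numeric(semi_axes_px),
    depth_semi_axis_px = as.numeric(depth_semi_axis_px),
    orientation_rad = as.numeric(orientation_rad),
    husk_thickness_px = as.numeric(husk_thickness_px),
    mu_husk = as.numeric(mu_husk), mu_kernel = as.numeric(mu_kernel),
    chaffy = isTRUE(chaffy), chalk_fraction = as.numeric(chalk_fraction),
    chalk_factor = as.numeric(chalk_factor),
    hrr_class = as.numeric(hrr_class), mottle_sd = as.numeric(mottle_sd),
    # inclusion placement in normalized kernel-ellipse coordinates,
    # fixed at construction so rendering is deterministic
    chalk_offset = c(0, 0), chalk_angle = 0
  ), class = "grain_spec")
}

#' Detector and exposure model for the phantom
#'
#' Mirrors the study scanner's geometry: a 14-bit CMOS sensor with an active
#' area of 2304 x 1300 pixels. The unattenuated beam produces `background_I0`
#' counts; additive Gaussian noise with `noise_sd` counts is applied before
#' rounding and clipping to the sensor range.
#'
#' @param background_I0 background intensity in counts; must satisfy
#'   `0 < I0 <= 2^bit_depth - 1`.
#' @param detector_shape integer length-2 (rows, cols); default `c(1300, 2304)`.
#' @param bit_depth sensor bit depth (14).
#' @param noise_sd additive noise SD in counts; default 0.5% of I0.
#' @param rng_seed integer seed controlling noise and mottle.
#' @return an object of class `acquisition_model`.
#' @export
acquisition_model <- function(background_I0 = 12000L,
                              detector_shape = c(1300L, 2304L),
                              bit_depth = 14L,
                              noise_sd = 0.005 * background_I0,
                              rng_seed = 1L) {
  maxcount <- 2^bit_depth - 1
  if (background_I0 <= 0 || background_I0 > maxcount)
    stopf("background_I0 must be in (0, %d]", maxcount)
  stopifnot(length(detector_shape) == 2L, all(detector_shape >= 1))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(background_I0 = as.integer(round(background_I0)),
                 detector_shape = as.integer(detector_shape),
                 bit_depth = as.integer(bit_depth),
                 noise_sd = as.numeric(noise_sd),
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_model")
}

#' Assemble grains and an acquisition model into a phantom scene
#'
#' Validates the sample-holder invariants: every grain footprint (outer
#' ellipse) lies inside the detector, and when a grid layout is declared the
#' footprints are pairwise disjoint.
#'
#' @param grains list of [grain_spec] objects.
#' @param acquisition an [acquisition_model].
#' @param grid_layout optional list with `n_rows`, `n_cols` and `pitch_px`
#'   (length-2: row pitch, col pitch).
#' @return an object of class `phantom_scene`.
#' @export
phantom_scene <- function(grains, acquisition, grid_layout = NULL) {
  stopifnot(all(vapply(grains, inherits, TRUE, "grain_spec")))
  shape <- acquisition$detector_shape
  # tight axis-aligned extents of each rotated ellipse footprint
  ext <- t(vapply(grains, function(g) {
    a <- g$semi_axes_px[1]; b <- g$semi_axes_px[2]
    th <- g$orientation_rad
    c(row = sqrt((a * sin(th))^2 + (b * cos(th))^2),
      col = sqrt((a * cos(th))^2 + (b * sin(th))^2))
  }, numeric(2)))
  ctr <- t(vapply(grains, function(g) g$center_px, numeric(2)))
  for (i in seq_along(grains)) {
    if (ctr[i, 1] - ext[i, 1] < 0 || ctr[i, 1] + ext[i, 1] > shape[1] - 1 ||
        ctr[i, 2] - ext[i, 2] < 0 || ctr[i, 2] + ext[i, 2] > shape[2] - 1)
      stopf("grain %d footprint exceeds the detector", grains[[i]]$id)
  }
  if (!is.null(grid_layout) && length(grains) > 1L) {
    n <- length(grains)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (abs(ctr[i, 1] - ctr[j, 1]) < ext[i, 1] + ext[j, 1] &&
          abs(ctr[i, 2] - ctr[j, 2]) < ext[i, 2] + ext[j, 2])
        stopf("grain footprints overlap; holder grid requires disjoint grains")
    }
  }
  structure(list(grains = grains, acquisition = acquisition,
                 grid_layout = grid_layout),
            class = "phantom_scene")
}

# default grain geometry: life-size slender paddy grains at 49.5 um/px
# (about 8 mm x 2.4 mm), husk much less attenuating than the starchy kernel
default_grain_geometry <- function() {
  list(a_mean = 42, a_sd = 3, b_mean = 12, b_sd = 0.9, c_ratio = 0.95,
       husk_thickness = 1.8, mu_husk = 0.025, mu_husk_sd = 0.0012,
       mu_kernel = 0.10, mu_kernel_sd = 0.005, orientation_sd = 0.05)
}

# monotone map from HRR class value (100..20) to generative parameters:
# poorer-milling grains are smaller, less dense and more heterogeneous
hrr_class_params <- function(v) {
  list(size_scale = 0.86 + 0.0014 * v,
       density_scale = 0.90 + 0.0010 * v,
       mottle_sd = (100 - v) * 0.0025)
}

#' Build a deterministic phantom scene on the holder grid
#'
#' Lays `n_grains` grains on a fixed grid (pitch 2.2x the maximal grain axis
#' in each direction so grains never touch) and assigns trait labels in the
#' exact proportions of `trait_mix` using largest-remainder rounding, then
#' shuffles positions with the seeded RNG.
#'
#' @param n_grains number of grains; must not exceed grid capacity.
#' @param trait_mix list with optional entries `chaffy` (proportion of chaffy
#'   grains), `chalky` (proportion of chalky grains, i.e. chalk fraction drawn
#'   above the 20% threshold) and `hrr` (named proportions over classes
#'   "100","80","60","40","20"). Proportions must each be in `[0, 1]`;
#'   `hrr` must sum to 1.
#' @param acquisition an [acquisition_model].
#' @param seed integer seed; identical seeds give field-identical scenes.
#' @param geometry named list overriding entries of the default grain
#'   geometry (see Details in the package vignette).
#' @return a [phantom_scene].
#' @export
build_scene <- function(n_grains, trait_mix = list(),
                        acquisition = acquisition_model(), seed = 1L,
                        geometry = list()) {
  geo <- utils::modifyList(default_grain_geometry(), geometry)
  shape <- acquisition$detector_shape
  a_max <- geo$a_mean + 4 * geo$a_sd
  b_max <- geo$b_mean + 4 * geo$b_sd
  pitch <- c(2.2 * 2 * b_max, 2.2 * 2 * a_max)  # (row, col)
  margin <- c(b_max + 2, a_max + 2)
  n_rows <- floor((shape[1] - 2 * margin[1]) / pitch[1]) + 1L
  n_cols <- floor((shape[2] - 2 * margin[2]) / pitch[2]) + 1L
  capacity <- n_rows * n_cols
  if (n_grains > capacity)
    stopf("n_grains = %d exceeds holder capacity %d (%d x %d grid)",
          n_grains, capacity, n_rows, n_cols)

  p_chaffy <- trait_mix$chaffy %||% 0
  p_chalky <- trait_mix$chalky %||% 0
  stopifnot(p_chaffy >= 0, p_chaffy <= 1, p_chalky >= 0, p_chalky <= 1)
  n_chaffy <- as.integer(round(n_grains * p_chaffy))
  n_filled <- n_grains - n_chaffy
  n_chalky <- as.integer(round(n_grains * p_chalky))
  if (n_chalky > n_filled)
    stopf("chalky proportion exceeds the non-chaffy fraction")
  hrr_mix <- trait_mix$hrr
  if (!is.null(hrr_mix)) {
    if (abs(sum(hrr_mix) - 1) > 1e-9) stopf("hrr proportions must sum to 1")
    hrr_counts <- apportion(n_grains, as.numeric(hrr_mix))
    hrr_vals <- rep(as.numeric(names(hrr_mix)), hrr_counts)
  } else hrr_vals <- rep(NA_real_, n_grains)

  with_seed(seed, {
    # trait labels in fixed order, then positions shuffled
    chaffy <- c(rep(TRUE, n_chaffy), rep(FALSE, n_filled))
    chalk_fraction <- numeric(n_grains)
    filled_idx <- which(!chaffy)
    chalky_idx <- filled_idx[seq_len(n_chalky)]
    chalk_fraction[chalky_idx] <- stats::runif(n_chalky, 0.30, 0.70)
    plain_idx <- setdiff(filled_idx, chalky_idx)
    low <- stats::runif(length(plain_idx))
    chalk_fraction[plain_idx] <- ifelse(low < 0.3,
                                        stats::runif(length(plain_idx), 0, 0.15), 0)
    slots <- sample.int(capacity, n_grains)
    perm <- sample.int(n_grains)   # decouple slot order from label order
    grains <- vector("list", n_grains)
    for (i in seq_len(n_grains)) {
      slot <- slots[perm[i]]
      gr <- (slot - 1L) %/% n_cols
      gc <- (slot - 1L) %% n_cols
      center <- c(margin[1] + gr * pitch[1], margin[2] + gc * pitch[2])
      v <- hrr_vals[i]
      hp <- if (is.na(v)) list(size_scale = 1, density_scale = 1, mottle_sd = 0)
            else hrr_class_params(v)
      a <- max(stats::rnorm(1, geo$a_mean, geo$a_sd), geo$a_mean / 2) * hp$size_scale
      b <- max(stats::rnorm(1, geo$b_mean, geo$b_sd), geo$b_mean / 2) * hp$size_scale
      g <- grain_spec(
        id = i, center_px = center, semi_axes_px = c(a, b),
        depth_semi_axis_px = b * geo$c_ratio,
        orientation_rad = stats::rnorm(1, 0, geo$orientation_sd),
        husk_thickness_px = geo$husk_thickness,
        mu_husk = max(stats::rnorm(1, geo$mu_husk, geo$mu_husk_sd), 1e-4),
        mu_kernel = max(stats::rnorm(1, geo$mu_kernel, geo$mu_kernel_sd), 1e-3) *
          hp$density_scale,
        chaffy = chaffy[i], chalk_fraction = chalk_fraction[i],
        hrr_class = v, mottle_sd = hp$mottle_sd)
      if (g$chalk_fraction > 0) {
        # inclusion kept fully inside the kernel footprint
        slack <- 1 - sqrt(g$chalk_fraction)
        g$chalk_offset <- stats::runif(1, 0, slack) *
          c(cos(th <- stats::runif(1, 0, 2 * pi)), sin(th))
        g$chalk_angle <- th
      }
      grains[[i]] <- g
    }
    phantom_scene(grains, acquisition,
                  grid_layout = list(n_rows = n_rows, n_cols = n_cols,
                                     pitch_px = pitch))
  })
}

#' Projected husk and kernel thickness of one grain at given pixels
#'
#' For a parallel beam along the depth axis, the through-thickness of an
#' ellipsoid with semi-axes (a, b, c) at in-plane offset (x, y) in the grain
#' frame is `2 c sqrt(1 - x^2/a^2 - y^2/b^2)` inside the footprint and 0
#' outside. The kernel uses the inner ellipsoid (outer semi-axes each minus
#' the husk thickness); the husk thickness is outer minus inner. Chaffy grains
#' have zero kernel thickness.
#'
#' @param spec a [grain_spec].
#' @param pixel numeric length-2 (row, col) or an n x 2 matrix of pixels.
#' @return a list with numeric `t_husk` and `t_kernel` (lengths n).
#' @export
projected_thickness <- function(spec, pixel) {
  p <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2L)
  dy <- p[, 1] - spec$center_px[1]
  dx <- p[, 2] - spec$center_px[2]
  co <- cos(spec$orientation_rad); si <- sin(spec$orientation_rad)
  # grain-frame coordinates: x along the major (column-aligned) axis
  x <- dx * co + dy * si
  y <- -dx * si + dy * co
  a <- spec$semi_axes_px[1]; b <- spec$semi_axes_px[2]
  cc <- spec$depth_semi_axis_px
  h <- spec$husk_thickness_px
  ellipsoid_thickness <- function(ax, bx, cx) {
    q <- 1 - x^2 / ax^2 - y^2 / bx^2
    ifelse(q > 0, 2 * cx * sqrt(pmax(q, 0)), 0)
  }
  t_outer <- ellipsoid_thickness(a, b, cc)
  t_inner <- ellipsoid_thickness(a - h, b - h, cc - h)
  t_kernel <- if (spec$chaffy) rep(0, length(t_inner)) else t_inner
  list(t_husk = t_outer - t_inner, t_kernel = t_kernel)
}

# chalk inclusion footprint test in normalized kernel coordinates
chalk_mask_at <- function(spec, pixel) {
  if (spec$chalk_fraction <= 0) return(rep(FALSE, nrow(pixel)))
  p <- pixel
  dy <- p[, 1] - spec$center_px[1]
  dx <- p[, 2] - spec$center_px[2]
  co <- cos(spec$orientation_rad); si <- sin(spec$orientation_rad)
  x <- dx * co + dy * si
  y <- -dx * si + dy * co
  a <- spec$semi_axes_px[1] - spec$husk_thickness_px
  b <- spec$semi_axes_px[2] - spec$husk_thickness_px
  s <- sqrt(spec$chalk_fraction)
  u <- x / a - spec$chalk_offset[1]
  v <- y / b - spec$chalk_offset[2]
  (u^2 + v^2) <= s^2
}

#' Render a phantom scene to a radiograph
#'
#' Applies the Beer-Lambert forward model per pixel:
#' `counts = clip(round(I0 * exp(-sum_g mu_husk t_husk + mu_kernel' t_kernel)
#' + noise), 0, 2^14 - 1)`, where the effective kernel attenuation is scaled
#' by `chalk_factor` inside a chalky inclusion and by a per-pixel mottle field
#' for heterogeneous kernels. Noise and mottle are drawn under the
#' acquisition's `rng_seed`, so rendering is bit-reproducible.
#'
#' @param scene a [phantom_scene].
#' @return a [radiograph] with the scene attached as attribute `scene`.
#' @export
render_radiograph <- function(scene) {
  acq <- scene$acquisition
  shape <- acq$detector_shape
  att <- matrix(0, shape[1], shape[2])
  with_seed(acq$rng_seed, {
    for (g in scene$grains) {
      r <- max(g$semi_axes_px) + 1
      r0 <- max(0L, floor(g$center_px[1] - r)); r1 <- min(shape[1] - 1L, ceiling(g$center_px[1] + r))
      c0 <- max(0L, floor(g$center_px[2] - r)); c1 <- min(shape[2] - 1L, ceiling(g$center_px[2] + r))
      rows <- r0:r1; cols <- c0:c1
      px <- cbind(rep(rows, times = length(cols)),
                  rep(cols, each = length(rows)))
      th <- projected_thickness(g, px)
      mu_k <- rep(g$mu_kernel, nrow(px))
      if (g$chalk_fraction > 0)
        mu_k[chalk_mask_at(g, px)] <- g$mu_kernel * g$chalk_factor
      if (g$mottle_sd > 0) {
        inside <- th$t_kernel > 0
        mu_k[inside] <- mu_k[inside] *
          pmax(1 + stats::rnorm(sum(inside), 0, g$mottle_sd), 0.2)
      }
      contrib <- g$mu_husk * th$t_husk + mu_k * th$t_kernel
      att[rows + 1L, cols + 1L] <- att[rows + 1L, cols + 1L] +
        matrix(contrib, length(rows), length(cols))
    }
    counts <- acq$background_I0 * exp(-att)
    if (acq$noise_sd > 0)
      counts <- counts + stats::rnorm(length(counts), 0, acq$noise_sd)
    counts <- pmin(pmax(round(counts), 0), 2^acq$bit_depth - 1)
    structure(radiograph(matrix(counts, shape[1], shape[2]),
                         pixel_size_um = 49.5,
                         metadata = list(I0_true = acq$background_I0)),
              scene = scene)
  })
}

#' Ground-truth table for a phantom scene
#'
#' One row per grain: id, center, chaffy flag, chalky flag (chalk fraction
#' strictly above the 20% opaque-area threshold) and HRR class.
#'
#' @param scene a [phantom_scene].
#' @return a data.frame.
#' @export
scene_truth <- function(scene) {
  g <- scene$grains
  data.frame(
    id = vapply(g, `[[`, integer(1), "id"),
    center_row = vapply(g, function(x) x$center_px[1], numeric(1)),
    center_col = vapply(g, function(x) x$center_px[2], numeric(1)),
    chaffy = vapply(g, `[[`, logical(1), "chaffy"),
    chalky = vapply(g, function(x) x$chalk_fraction > 0.20, logical(1)),
    hrr_class = vapply(g, `[[`, numeric(1), "hrr_class")
  )
}

#' Write the scene ground truth as CSV
#'
#' @param scene a [phantom_scene].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(scene, path) {
  utils::write.csv(scene_truth(scene), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scene with one touching grain pair
#'
#' Fixture used to exercise the instance-splitting watershed: two equal
#' ellipses whose footprints overlap slightly but whose distance-transform
#' peaks are distinct.
#'
#' @param acquisition an [acquisition_model]; default a small 200 x 300
#'   detector with no noise.
#' @param gap_px centre-to-centre distance deficit relative to just-touching;
#'   positive values overlap the footprints.
#' @return a [phantom_scene] (grid invariants not enforced).
#' @export
touching_pair_scene <- function(acquisition = acquisition_model(
                                  detector_shape = c(200L, 300L),
                                  noise_sd = 0),
                                gap_px = 6) {
  a <- 40; b <- 13
  mid <- (acquisition$detector_shape - 1) / 2
  dx <- a - gap_px / 2
  g1 <- grain_spec(1L, mid + c(0, -dx), c(a, b), b * 0.95)
  g2 <- grain_spec(2L, mid + c(0, dx), c(a, b), b * 0.95)
  phantom_scene(list(g1, g2), acquisition, grid_layout = NULL)
}
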