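#' Construct a radiograph object
#'
#' A raw detector image: non-negative integer counts plus acquisition
#' metadata. The sole measured input of the trait pipeline.
#'
#' @param pixels numeric/integer matrix of counts.
#' @param pixel_size_um physical pixel pitch, micrometres.
#' @param metadata named list (voltage_kV, current_uA, exposure_ms, fod_mm...).
#' @return object of class `radiograph`.
#' @export
radiograph <- function(pixels, pixel_size_um = 49.5, metadata = list()) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0)) stopf("radiograph counts must be >= 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 metadata = metadata),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px, counts %d..%d, pixel %.1f um\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              x$pixel_size_um))
  invisible(x)
}

#' Estimate the background intensity I0 from the grey-value histogram
#'
#' The holder leaves most of the detector uncovered, so the most frequent
#' integer grey value is the unattenuated background. Ties are resolved
#' towards the largest grey value (in transmission imaging the background is
#' the brightest dominant region). Float inputs are rounded to integer grey
#' levels first.
#'
#' @param image a [radiograph] or a numeric matrix of counts.
#' @return integer scalar I0.
#' @export
estimate_background <- function(image) {
  px <- if (inherits(image, "radiograph")) image$pixels else image
  if (length(px) == 0L) stopf("empty image")
  v <- round(as.vector(px))
  if (all(v == 0)) stopf("all-zero image: background undefined")
  tab <- tabulate(v + 1L)         # grey level g counts at index g + 1
  top <- max(tab)
  as.integer(max(which(tab == top)) - 1L)
}

#' Beer-Lambert log normalization of a radiograph
#'
#' Converts counts to attenuation line integrals, `-ln(I / I0)`. Pixels equal
#' to I0 map to exactly 0; zero counts are floored to 1 before the log to
#' avoid infinities; pixels brighter than I0 (noise) keep their small negative
#' values, preserving the background noise statistics.
#'
#' @param image a [radiograph] or counts matrix.
#' @param I0 background intensity, or `"auto"` to call
#'   [estimate_background()].
#' @return object of class `attenuation_image` with fields `values` (numeric
#'   matrix) and `background_I0`.
#' @export
normalize_radiograph <- function(image, I0 = "auto") {
  px <- if (inherits(image, "radiograph")) image$pixels else image
  if (identical(I0, "auto")) I0 <- estimate_background(px)
  if (!is.numeric(I0) || length(I0) != 1L || I0 <= 0)
    stopf("I0 must be a positive scalar")
  vals <- -log(pmax(px, 1) / I0)
  attenuation_image(matrix(vals, nrow(px), ncol(px)), background_I0 = as.integer(I0))
}

#' Construct an attenuation image
#'
#' @param values numeric matrix of unitless attenuation line integrals.
#' @param background_I0 the I0 used for normalization.
#' @return object of class `attenuation_image`.
#' @export
attenuation_image <- function(values, background_I0) {
  stopifnot(is.matrix(values))
  structure(list(values = values, background_I0 = as.integer(background_I0)),
            class = "attenuation_image")
}

#' @export
print.attenuation_image <- function(x, ...) {
  cat(sprintf("<attenuation_image> %d x %d px, I0 = %d, range [%.4f, %.4f]\n",
              nrow(x$values), ncol(x$values), x$background_I0,
              min(x$values), max(x$values)))
  invisible(x)
}
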