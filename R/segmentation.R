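#' Otsu's threshold
#'
#' Maximizes the between-class variance of a 256-bin histogram over the data
#' range. Returns `NA` when the input is (near-)constant.
#'
#' @param values numeric vector.
#' @param n_bins histogram resolution.
#' @return threshold on the scale of `values`, or `NA`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- values[is.finite(values)]
  rng <- range(v)
  if (diff(rng) < 1e-12) return(NA_real_)
  h <- tabulate(pmin(pmax(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                     n_bins), n_bins)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# stage 1 of the dual watershed: foreground/background basins grown from
# confident markers, flooding along the gradient magnitude so the boundary
# settles on the grain edge. Marker thresholds come from a robust model of
# the background noise (the holder leaves most pixels uncovered, so the
# median/MAD of the attenuation map characterize the background): pixels
# beyond 8 noise SDs are sure grain matter — including faint husk-only
# (chaffy) grains — and pixels within 4 SDs sure background. A global Otsu
# cut is unreliable here because the grain fill fraction may be far below
# the background mass.
foreground_mask <- function(att_values, k_fg = 8, k_bg = 4) {
  sigma <- stats::mad(att_values)
  t_fg <- max(k_fg * sigma, 1e-6)
  markers <- matrix(0L, nrow(att_values), ncol(att_values))
  markers[att_values <= k_bg * sigma] <- 1L  # sure background
  markers[att_values >= t_fg] <- 2L          # sure grain matter
  if (!any(markers == 2L))
    return(matrix(FALSE, nrow(att_values), ncol(att_values)))
  gy <- att_values * 0
  gx <- att_values * 0
  nr <- nrow(att_values); nc <- ncol(att_values)
  gy[2:(nr - 1), ] <- (att_values[3:nr, ] - att_values[1:(nr - 2), ]) / 2
  gx[, 2:(nc - 1)] <- (att_values[, 3:nc] - att_values[, 1:(nc - 2)]) / 2
  grad <- sqrt(gy^2 + gx^2)
  lab <- cpp_watershed(grad, markers, matrix(TRUE, nr, nc))
  lab == 2L
}

# stage 2: split merged foreground components on distance-transform peaks;
# a marker is the superlevel set {EDT >= h_frac * component max}, which is
# connected (hence one marker) for a convex blob and splits for touching pairs
instance_split <- function(mask, h_frac = 0.6) {
  comp <- cpp_label_components(mask)
  if (max(comp) == 0L) return(comp)
  ed <- cpp_edt(mask)
  cmax <- vapply(seq_len(max(comp)), function(k) max(ed[comp == k]), numeric(1))
  marker_mask <- mask & ed >= (h_frac * cmax)[pmax(comp, 1L)] & comp > 0L
  markers <- cpp_label_components(marker_mask)
  cpp_watershed(-ed, markers, mask)
}

segments_from_labels <- function(lab) {
  labels <- sort(unique(lab[lab > 0L]))
  if (!length(labels)) return(structure(list(), class = "grain_segments",
                                        label_image = lab * 0L))
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% nrow(lab))          # 0-based row
  cols <- ((idx - 1L) %/% nrow(lab))         # 0-based col
  segs <- vector("list", length(labels))
  for (j in seq_along(labels)) {
    k <- labels[j]
    sel <- lab[idx] == k
    p <- cbind(row = rows[sel], col = cols[sel])
    segs[[j]] <- list(label = k, pixels = p,
                      bbox = c(min(p[, 1]), min(p[, 2]),
                               max(p[, 1]) + 1L, max(p[, 2]) + 1L),
                      area_px = nrow(p))
  }
  # deterministic order: lexicographic on bbox origin, then relabel 1..n
  ord <- order(vapply(segs, function(s) s$bbox[1], numeric(1)),
               vapply(segs, function(s) s$bbox[2], numeric(1)))
  segs <- segs[ord]
  relab <- lab * 0L
  for (k in seq_along(segs)) {
    segs[[k]]$label <- k
    relab[segs[[k]]$pixels[, 1] + 1L + nrow(lab) * segs[[k]]$pixels[, 2]] <- k
  }
  structure(segs, class = "grain_segments", label_image = relab)
}

#' Detect and label individual grains
#'
#' Dual-watershed blob analysis on a normalized attenuation image:
#' (1) foreground/background separation by marker watershed on the gradient
#' magnitude, with markers from an Otsu threshold on log-attenuation;
#' (2) instance splitting of merged foreground blobs by watershed on the
#' negated Euclidean distance transform, seeded at distance peaks. The result
#' is then cleaned by [clean_segments()].
#'
#' @param att an [attenuation_image] (or numeric matrix of attenuation
#'   values).
#' @param min_area_px minimum segment area kept, pixels (default 50).
#' @param struct_radius radius of the disk structuring element used by the
#'   morphological opening (default 1.5, a full 3 x 3 neighbourhood).
#' @param h_frac distance-peak marker level as a fraction of each component's
#'   maximum distance value.
#' @param clean apply [clean_segments()] before returning (default TRUE).
#' @return an object of class `grain_segments`: a list of segments, each with
#'   `label`, `pixels` (m x 2, 0-based row/col), half-open `bbox`
#'   (row_min, col_min, row_max, col_max) and `area_px`; the integer label
#'   image is attached as attribute `label_image`. Segments are sorted by
#'   bbox origin.
#' @export
segment_grains <- function(att, min_area_px = 50L, struct_radius = 1.5,
                           h_frac = 0.6, clean = TRUE) {
  vals <- if (inherits(att, "attenuation_image")) att$values else att
  fg <- foreground_mask(vals)
  if (!any(fg)) return(segments_from_labels(matrix(0L, nrow(vals), ncol(vals))))
  lab <- instance_split(fg, h_frac = h_frac)
  segs <- segments_from_labels(lab)
  if (clean) segs <- clean_segments(segs, min_area_px = min_area_px,
                                    struct_radius = struct_radius)
  segs
}

#' Morphological cleanup of labelled segments
#'
#' Applies a binary opening (erosion then dilation with a disk structuring
#' element) to each segment's own mask — removing single-pixel noise without
#' letting neighbouring segments merge — then drops segments smaller than
#' `min_area_px` and relabels contiguously from 1 in bbox order.
#'
#' @param segments a `grain_segments` object.
#' @param min_area_px minimum area kept.
#' @param struct_radius disk radius of the structuring element.
#' @return a cleaned `grain_segments` object.
#' @export
clean_segments <- function(segments, min_area_px = 50L, struct_radius = 1.5) {
  lab <- attr(segments, "label_image")
  out <- lab * 0L
  for (s in segments) {
    # open within a padded crop of the segment for speed
    pad <- ceiling(struct_radius) + 1L
    r0 <- max(s$bbox[1] - pad, 0L); c0 <- max(s$bbox[2] - pad, 0L)
    r1 <- min(s$bbox[3] + pad, nrow(lab)); c1 <- min(s$bbox[4] + pad, ncol(lab))
    crop <- lab[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE] == s$label
    opened <- cpp_dilate(cpp_erode(crop, struct_radius), struct_radius)
    if (sum(opened) >= min_area_px)
      out[(r0 + 1L):r1, (c0 + 1L):c1][opened] <- s$label
  }
  segments_from_labels(out)
}

#' @export
print.grain_segments <- function(x, ...) {
  cat(sprintf("<grain_segments> %d segments, areas %s px\n", length(x),
              if (length(x)) paste(range(vapply(x, `[[`, integer(1), "area_px")),
                                   collapse = "..") else "-"))
  invisible(x)
}

#' Segment summary table
#'
#' @param segments a `grain_segments` object.
#' @return data.frame with label, bbox and area columns.
#' @export
segments_table <- function(segments) {
  if (!length(segments))
    return(data.frame(label = integer(), row_min = integer(),
                      col_min = integer(), row_max = integer(),
                      col_max = integer(), area_px = integer()))
  do.call(rbind, lapply(segments, function(s)
    data.frame(label = s$label, row_min = s$bbox[1], col_min = s$bbox[2],
               row_max = s$bbox[3], col_max = s$bbox[4], area_px = s$area_px)))
}

#' Segment centroids
#'
#' @param segments a `grain_segments` object.
#' @return n x 2 matrix of (row, col) centroids in 0-based pixel coordinates.
#' @export
segment_centroids <- function(segments) {
  t(vapply(segments, function(s) colMeans(s$pixels), numeric(2)))
}
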