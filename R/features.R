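# circle through three points; NULL if (near-)collinear
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((ctr - p1)^2)))
}

circle_two <- function(p1, p2) {
  ctr <- (p1 + p2) / 2
  list(center = ctr, radius = sqrt(sum((p1 - p2)^2)) / 2)
}

in_circle <- function(circ, p, eps = 1e-9) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
}

#' Minimum enclosing circle of a point set
#'
#' Welzl-type incremental construction on the convex hull of the pixel
#' centers, with a deterministic pseudo-random insertion order (expected
#' linear time on the hull). A single point yields radius 0; two points the
#' diameter circle.
#'
#' @param points n x 2 matrix of (row, col) coordinates (pixel centers).
#' @return list with `center` (length-2) and `radius`.
#' @export
min_enclosing_circle <- function(points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 2L)
  p <- unique(p)
  n <- nrow(p)
  if (n == 0L) stopf("min_enclosing_circle: empty point set")
  if (n == 1L) return(list(center = as.numeric(p[1, ]), radius = 0))
  if (n > 3L) {
    hull <- grDevices::chull(p[, 2], p[, 1])  # (x, y) = (col, row)
    if (length(hull) >= 2L) p <- p[hull, , drop = FALSE]
    n <- nrow(p)
  }
  p <- p[lcg_permutation(n), , drop = FALSE]
  circ <- list(center = as.numeric(p[1, ]), radius = 0)
  for (i in seq_len(n)[-1L]) {
    if (in_circle(circ, p[i, ])) next
    # p[i] must lie on the boundary
    circ <- circle_two(p[1, ], p[i, ])
    for (j in seq_len(i - 1L)[-1L]) {
      if (in_circle(circ, p[j, ])) next
      # p[i] and p[j] on the boundary
      circ <- circle_two(p[i, ], p[j, ])
      for (k in seq_len(j - 1L)) {
        if (in_circle(circ, p[k, ])) next
        cc <- circumcircle(p[i, ], p[j, ], p[k, ])
        if (is.null(cc)) {
          # collinear triple: fall back to the widest diameter circle
          d <- as.matrix(stats::dist(rbind(p[i, ], p[j, ], p[k, ])))
          w <- which(d == max(d), arr.ind = TRUE)[1, ]
          pts <- rbind(p[i, ], p[j, ], p[k, ])
          cc <- circle_two(pts[w[1], ], pts[w[2], ])
        }
        circ <- cc
      }
    }
  }
  circ
}

#' The eight blob descriptors of one grain segment
#'
#' Computed on the normalized attenuation image:
#' f1 segment size in pixels; f2 mean grey value; f3 virtual weight (sum of
#' normalized grey values); f4 population standard deviation of the grey
#' values; f5 sphere radius `sqrt(f1 / pi)` (radius of the equal-area
#' circle); f6 average weight `f2 * f5`; f7 minimum covering circle radius of
#' the pixel centers; f8 sphere ratio `f5 / f7` (1 for circle-like segments,
#' towards 0 for elongated ones).
#'
#' @param segment one element of a `grain_segments` object.
#' @param att an [attenuation_image] or numeric matrix.
#' @return named numeric vector `f1`..`f8`.
#' @export
compute_feature_vector <- function(segment, att) {
  vals <- if (inherits(att, "attenuation_image")) att$values else att
  p <- segment$pixels
  if (any(p < 0) || any(p[, 1] >= nrow(vals)) || any(p[, 2] >= ncol(vals)))
    stopf("segment %s has pixels outside the image", segment$label)
  g <- vals[p[, 1] + 1L + nrow(vals) * p[, 2]]
  f1 <- nrow(p)
  f2 <- mean(g)
  f3 <- sum(g)
  f4 <- sqrt(mean((g - f2)^2))       # population SD: a descriptor
  f5 <- sqrt(f1 / pi)
  f6 <- f2 * f5
  f7 <- min_enclosing_circle(p)$radius
  f8 <- if (f7 > 0) f5 / f7 else 1
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6, f7 = f7, f8 = f8)
}

#' Feature table for all segments
#'
#' @param segments a `grain_segments` object.
#' @param att an [attenuation_image] or numeric matrix.
#' @return data.frame with `label` and `f1`..`f8`, one row per segment in
#'   label order.
#' @export
features_table <- function(segments, att) {
  cols <- c("label", paste0("f", 1:8))
  if (!length(segments)) {
    out <- as.data.frame(matrix(numeric(), 0, 9))
    names(out) <- cols
    return(out)
  }
  rows <- lapply(segments, function(s)
    c(label = s$label, compute_feature_vector(s, att)))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- cols
  out
}

#' Convert pixel areas to physical units
#'
#' @param area_px area in pixels.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return area in mm^2.
#' @export
px_to_mm2 <- function(area_px, pixel_size_um = 49.5) {
  area_px * (pixel_size_um / 1000)^2
}
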