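# Shared fixtures and independent oracles, all built in code.

# small detector whose holder grid fits ~25 life-size grains
small_acq <- function(seed = 1L, noise_sd = 60) {
  acquisition_model(background_I0 = 12000L, detector_shape = c(340L, 1200L),
                    noise_sd = noise_sd, rng_seed = seed)
}

# rasterized filled disk as a grain_segment-like list on a unit image
disk_segment <- function(radius) {
  g <- expand.grid(row = -radius:radius, col = -radius:radius)
  g <- as.matrix(g[g$row^2 + g$col^2 <= radius^2, c("row", "col")])
  g <- g + radius
  list(label = 1L, pixels = g,
       bbox = c(0L, 0L, 2L * radius + 1L, 2L * radius + 1L),
       area_px = nrow(g))
}

unit_image <- function(n) matrix(1, n, n)

# O(n^4)-style brute-force minimum enclosing circle: smallest covering circle
# among all pair-diameter circles and all triple circumcircles
brute_mcc_radius <- function(p) {
  p <- unique(p)
  n <- nrow(p)
  if (n == 1L) return(0)
  tp <- t(p)
  covers <- function(ctr, rad) all(sqrt(colSums((tp - ctr)^2)) <= rad + 1e-9)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ctr <- (p[i, ] + p[j, ]) / 2
    rad <- sqrt(sum((p[i, ] - p[j, ])^2)) / 2
    if (rad < best && covers(ctr, rad)) best <- rad
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- grainray:::circumcircle(p[i, ], p[j, ], p[k, ])
    if (!is.null(cc) && cc$radius < best && covers(cc$center, cc$radius))
      best <- cc$radius
  }
  best
}

# brute-force binary opening with a disk structuring element, on a small
# logical mask (loops, no shared code with the package's C++ routines)
brute_opening <- function(mask, radius = 1.5) {
  off <- expand.grid(dr = -2:2, dc = -2:2)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, ]
  nr <- nrow(mask); nc <- ncol(mask)
  get <- function(m, r, c) if (r < 1 || r > nr || c < 1 || c > nc) FALSE else m[r, c]
  er <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc)
    er[r, c] <- all(mapply(function(dr, dc) get(mask, r + dr, c + dc),
                           off$dr, off$dc))
  di <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc)
    di[r, c] <- any(mapply(function(dr, dc) get(er, r + dr, c + dc),
                           off$dr, off$dc))
  di
}

# quadrature-free independent oracle for ellipsoid through-thickness: locate
# the beam entry/exit depth by root finding on the implicit surface equation
rootfind_thickness <- function(x, y, a, b, cc) {
  q <- 1 - x^2 / a^2 - y^2 / b^2
  if (q <= 0) return(0)
  g <- function(z) x^2 / a^2 + y^2 / b^2 + z^2 / cc^2 - 1
  z_star <- stats::uniroot(g, c(0, cc), tol = 1e-12)$root
  2 * z_star
}
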