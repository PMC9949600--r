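#' Star length distribution analysis
#'
#' Samples points uniformly among the bone voxels inside the spherical ROI
#' (seeded, reproducible) and measures, for each point and each test
#' direction, the length of the bone intercept through the point along that
#' direction (marching both ways until the ray exits bone or leaves the
#' sphere). Returns the directional mean star lengths and the anisotropy
#' ratio (largest/smallest eigenvalue axis) of the star-length orientation
#' tensor `T = sum_w Lbar(w) w w'`.
#'
#' @param volume a [binary_volume()].
#' @param roi a `sphere_roi` or `NULL`.
#' @param n_points number of seed points (the conventional default is 2000).
#' @param dirs a [direction_set()]; SLD cost scales with points x directions,
#'   so a coarser set than for MIL is typical.
#' @param seed RNG seed for point sampling.
#' @param step_voxels marching step.
#' @return list `mean_length_mm` (per direction), `dirs`,
#'   `anisotropy_ratio`, `n_points`.
#' @export
sld_analysis <- function(volume, roi = NULL, n_points = 2000L,
                         dirs = direction_set(65L), seed = 1L,
                         step_voxels = 0.5) {
  stopifnot(is_binary_volume(volume))
  roi <- roi %||% default_roi(volume)
  mask <- volume$mask
  d <- dim(mask)
  sel <- sphere_voxel_mask(d, roi$center, roi$radius) & mask
  idx <- which(sel)
  if (length(idx) == 0L) stop("no bone voxels inside the ROI")
  replace <- length(idx) < n_points
  if (replace) {
    warning("fewer bone voxels than requested points: sampling with replacement")
  }
  pts_idx <- with_local_seed(seed, sample(idx, n_points, replace = replace))
  ai <- arrayInd(pts_idx, d)
  vmm <- volume$voxel_size_um / 1000

  march <- function(w, sense) {
    # steps each point takes along sense*w before exiting bone or sphere
    steps <- numeric(n_points)
    alive <- rep(TRUE, n_points)
    t <- 0
    while (any(alive)) {
      t <- t + step_voxels
      px <- ai[alive, 1] + sense * t * w[1]
      py <- ai[alive, 2] + sense * t * w[2]
      pz <- ai[alive, 3] + sense * t * w[3]
      rx <- round(px); ry <- round(py); rz <- round(pz)
      ok <- rx >= 1 & rx <= d[1] & ry >= 1 & ry <= d[2] & rz >= 1 & rz <= d[3]
      ok <- ok & ((px - roi$center[1])^2 + (py - roi$center[2])^2 +
                    (pz - roi$center[3])^2 <= roi$radius^2)
      ok[ok] <- mask[cbind(rx[ok], ry[ok], rz[ok])]
      steps[alive][ok] <- t
      alive[alive] <- ok
    }
    steps
  }

  nd <- nrow(dirs)
  mean_len <- numeric(nd)
  for (i in seq_len(nd)) {
    w <- dirs[i, ]
    len <- (march(w, +1) + march(w, -1) + step_voxels) * vmm
    mean_len[i] <- mean(len)
  }
  Tm <- matrix(0, 3, 3)
  for (i in seq_len(nd)) {
    Tm <- Tm + mean_len[i] * tcrossprod(dirs[i, ])
  }
  Tm <- Tm / nd
  ev <- sort(eigen(Tm, symmetric = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, max(ev) * 1e-9)
  list(mean_length_mm = mean_len, dirs = dirs,
       anisotropy_ratio = ev[1] / ev[3], n_points = n_points)
}
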