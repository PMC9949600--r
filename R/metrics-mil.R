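#' Bone volume fraction within a spherical region of interest
#'
#' Bone voxels whose centers lie inside the sphere divided by all voxels
#' whose centers lie inside the sphere.
#'
#' @param volume a [binary_volume()].
#' @param roi a `sphere_roi`, or `NULL` to use the whole volume.
#' @return fraction in \[0, 1\].
#' @export
bv_tv <- function(volume, roi = NULL) {
  stopifnot(is_binary_volume(volume))
  if (is.null(roi)) return(mean(volume$mask))
  sel <- sphere_voxel_mask(dim(volume$mask), roi$center, roi$radius)
  if (!any(sel)) stop("empty ROI: sphere contains no voxel centers")
  mean(volume$mask[sel])
}

## Cast a parallel grid of test lines along direction w through the sphere and
## tally, per line sample sequence: bone run lengths, run boundary types, and
## total in-sphere line length. Returns aggregate counts for one direction.
##
## Sampling: lines at `spacing` voxel offsets on the plane normal to w; points
## every `step` voxels along the line; a sample is "in" when inside the sphere
## and inside the grid.
direction_line_stats <- function(mask, center, radius, w, spacing, step) {
  b <- orthonormal_basis(w)
  off <- seq(-radius + spacing / 2, radius, by = spacing)
  og <- expand.grid(a = off, b = off)
  og <- og[og$a^2 + og$b^2 < radius^2, ]
  nl <- nrow(og)
  if (nl == 0L) return(NULL)
  tmax <- sqrt(radius^2 - og$a^2 - og$b^2)
  ts <- seq(-radius, radius, by = step)
  nt <- length(ts)
  d <- dim(mask)
  # coordinates: nl x nt for each axis
  base <- cbind(center[1] + og$a * b$u[1] + og$b * b$v[1],
                center[2] + og$a * b$u[2] + og$b * b$v[2],
                center[3] + og$a * b$u[3] + og$b * b$v[3])
  inside <- outer(tmax, abs(ts), `>=`)           # in-sphere flag per (line, t)
  px <- round(outer(base[, 1], ts * w[1], `+`))
  py <- round(outer(base[, 2], ts * w[2], `+`))
  pz <- round(outer(base[, 3], ts * w[3], `+`))
  ingrid <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
  inside <- inside & ingrid
  bone <- matrix(FALSE, nl, nt)
  idx <- which(inside)
  bone[idx] <- mask[cbind(px[idx], py[idx], pz[idx])]

  # run-length analysis per line on the in-sphere stretch
  total_len <- 0; bone_len <- 0; crossings <- 0L
  interior_runs <- 0L; interior_run_len <- 0
  for (l in seq_len(nl)) {
    sel <- inside[l, ]
    if (!any(sel)) next
    bl <- bone[l, sel]
    n <- length(bl)
    total_len <- total_len + n * step
    if (!any(bl)) next
    r <- rle(bl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    is_bone <- r$values
    bone_len <- bone_len + sum(r$lengths[is_bone]) * step
    # interfaces between consecutive runs
    crossings <- crossings + (length(r$lengths) - 1L)
    # bone runs not touching the sphere boundary (side-intersecting omitted)
    interior <- is_bone & starts > 1L & ends < n
    interior_runs <- interior_runs + sum(interior)
    interior_run_len <- interior_run_len + sum(r$lengths[interior]) * step
  }
  list(total_len = total_len, bone_len = bone_len, crossings = crossings,
       interior_runs = interior_runs, interior_run_len = interior_run_len)
}

#' Mean intercept length analysis and fabric tensor
#'
#' For each test direction a parallel grid of lines is cast through the
#' spherical ROI; the mean intercept length is the total test-line length in
#' the sphere divided by half the number of bone/background interface
#' crossings (so for plates normal to the line it equals the structural
#' period). Bone chords that touch the sphere boundary are excluded from the
#' intercept bookkeeping (side-intersecting paths omitted). The fabric tensor
#' is the least-squares fit of the ellipsoid form `1/MIL(w)^2 = w' A w`; the
#' degree of anisotropy is the ratio of the longest to the shortest MIL
#' ellipsoid semi-axis (>= 1; 1 = isotropic).
#'
#' @param volume a [binary_volume()].
#' @param roi a `sphere_roi` (radius >= 5 voxels), or `NULL` for the largest
#'   sphere centered in the volume.
#' @param dirs a [direction_set()].
#' @param line_spacing_voxels spacing of the test-line grid.
#' @param step_voxels sampling step along each line.
#' @return list with `mil` (per-direction mean intercept length, mm; `NA`
#'   for dropped directions), `dirs`, `fabric_tensor` (3x3), `eigenvalues`
#'   (MIL ellipsoid semi-axes, mm, descending), `da`.
#' @export
mil_analysis <- function(volume, roi = NULL, dirs = direction_set(257L),
                         line_spacing_voxels = 2, step_voxels = 0.5) {
  stopifnot(is_binary_volume(volume))
  roi <- roi %||% default_roi(volume)
  if (roi$radius < 5) stop("ROI radius must be >= 5 voxels for MIL analysis")
  vmm <- volume$voxel_size_um / 1000
  nd <- nrow(dirs)
  mil <- rep(NA_real_, nd)
  for (i in seq_len(nd)) {
    st <- direction_line_stats(volume$mask, roi$center, roi$radius, dirs[i, ],
                               line_spacing_voxels, step_voxels)
    if (is.null(st) || st$crossings == 0L) next
    mil[i] <- (st$total_len * vmm) / (st$crossings / 2)
  }
  dropped <- sum(is.na(mil))
  if (dropped == nd) stop("all directions dropped: no bone/background crossings")
  if (dropped > 0L) {
    warning(sprintf("%d of %d directions had no crossings and were dropped",
                    dropped, nd))
  }
  keep <- which(!is.na(mil))
  X <- cbind(dirs[keep, 1]^2, dirs[keep, 2]^2, dirs[keep, 3]^2,
             2 * dirs[keep, 1] * dirs[keep, 2],
             2 * dirs[keep, 1] * dirs[keep, 3],
             2 * dirs[keep, 2] * dirs[keep, 3])
  y <- 1 / mil[keep]^2
  coef <- stats::lm.fit(X, y)$coefficients
  A <- matrix(c(coef[1], coef[4], coef[5],
                coef[4], coef[2], coef[6],
                coef[5], coef[6], coef[3]), 3, 3)
  ev <- eigen(A, symmetric = TRUE)$values
  floor_ev <- max(ev) * 1e-6
  ev <- pmax(ev, floor_ev)
  axes <- sort(1 / sqrt(ev), decreasing = TRUE)   # semi-axes, mm
  list(mil = mil, dirs = dirs, fabric_tensor = A,
       eigenvalues = axes, da = axes[1] / axes[3])
}

#' Trabecular number
#'
#' Mean number of bone struts crossed per mm of test line: interface
#' crossings / 2 per unit line length, averaged over the direction set. Also
#' reports the per-direction values and the plate-model estimate
#' `(BV/TV) / Tb.Th`.
#'
#' @param volume a [binary_volume()].
#' @param roi a `sphere_roi` or `NULL`.
#' @param dirs a [direction_set()].
#' @param tb_th_mm optional trabecular thickness (mm) for the plate model;
#'   computed via [tb_th()] when omitted.
#' @param line_spacing_voxels,step_voxels sampling controls.
#' @return list with `tb_n_per_mm` (direction-averaged), `per_direction`,
#'   `plate_model_per_mm`.
#' @export
tb_n <- function(volume, roi = NULL, dirs = direction_set(257L),
                 tb_th_mm = NULL, line_spacing_voxels = 2, step_voxels = 0.5) {
  stopifnot(is_binary_volume(volume))
  roi <- roi %||% default_roi(volume)
  vmm <- volume$voxel_size_um / 1000
  nd <- nrow(dirs)
  dens <- rep(NA_real_, nd)
  for (i in seq_len(nd)) {
    st <- direction_line_stats(volume$mask, roi$center, roi$radius, dirs[i, ],
                               line_spacing_voxels, step_voxels)
    if (is.null(st)) next
    dens[i] <- (st$crossings / 2) / (st$total_len * vmm)
  }
  mean_dens <- mean(dens, na.rm = TRUE)
  if (!is.finite(mean_dens)) mean_dens <- 0
  bv <- bv_tv(volume, roi)
  plate <- if (bv == 0) {
    0
  } else if (is.null(tb_th_mm)) {
    th <- tb_th(volume, roi)$local_spheres_um / 1000
    if (th > 0) bv / th else 0
  } else {
    bv / tb_th_mm
  }
  list(tb_n_per_mm = mean_dens, per_direction = dens,
       plate_model_per_mm = plate)
}

#' Largest sphere ROI centered in a volume.
#' @noRd
default_roi <- function(volume) {
  d <- dim(volume$mask)
  sphere_roi((d + 1) / 2, min(d) / 2)
}
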