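#' Specification of a rod-lattice phantom
#'
#' Describes a cubic lattice of cylindrical struts used as a synthetic
#' stand-in for trabecular bone. Struts of radius `strut_radius_mm` run along
#' all three axes through the lattice node lines; spacing may differ per axis
#' to create anisotropic fixtures.
#'
#' @param spacing_mm lattice period per axis (length 1 or 3, mm).
#' @param strut_radius_mm cylinder radius (mm); must be < min(spacing)/2 so
#'   that struts from neighbouring cells do not merge.
#' @param extent_mm physical size of the volume per axis (length 1 or 3, mm);
#'   must cover at least two lattice periods per axis.
#' @param voxel_size_um voxel size; must not exceed the strut radius so every
#'   strut spans at least one voxel.
#' @return A `lattice_spec` list.
#' @export
lattice_spec <- function(spacing_mm, strut_radius_mm, extent_mm, voxel_size_um) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 3L)
  stopifnot(length(spacing_mm) == 3L, length(extent_mm) == 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be positive")
  }
  if (!is.finite(strut_radius_mm) || strut_radius_mm <= 0) {
    stop("degenerate spec: `strut_radius_mm` must be positive")
  }
  if (any(!is.finite(extent_mm)) || any(extent_mm <= 0)) {
    stop("degenerate spec: `extent_mm` must be positive")
  }
  if (strut_radius_mm >= min(spacing_mm) / 2) {
    stop("struts overlap: `strut_radius_mm` must be < min(spacing_mm)/2")
  }
  if (any(extent_mm < 2 * spacing_mm)) {
    stop("`extent_mm` must cover at least 2 lattice periods per axis")
  }
  if (voxel_size_um > strut_radius_mm * 1000) {
    stop("`voxel_size_um` must be <= strut_radius_mm * 1000 (struts must span >= 1 voxel)")
  }
  structure(list(spacing_mm = spacing_mm, strut_radius_mm = strut_radius_mm,
                 extent_mm = extent_mm, voxel_size_um = voxel_size_um),
            class = "lattice_spec")
}

## Node line positions along one axis: spacing/2, 3*spacing/2, ... within extent.
lattice_node_positions <- function(spacing, extent) {
  p <- seq(spacing / 2, extent - spacing / 2 + 1e-12, by = spacing)
  p[p <= extent]
}

## Squared distance from each coordinate to its nearest node position.
dist2_to_nodes <- function(coords, nodes) {
  d <- outer(coords, nodes, function(a, b) (a - b)^2)
  apply(d, 1L, min)
}

#' Rod-lattice phantom with analytic ground truth
#'
#' Builds a [binary_volume()] containing cylindrical struts along all three
#' axes through the lattice nodes (hard cylinders unioned at the nodes), and
#' returns ground-truth values for the downstream metrics: trabecular
#' thickness `2 * strut_radius`, per-axis trabecular number `1 / spacing`,
#' connectivity as the cycle rank (E - V + 1) of the node-strut graph, and
#' bone volume fraction by voxel counting.
#'
#' @param spec a [lattice_spec()].
#' @return list with `volume` ([binary_volume()]) and `truth` (list with
#'   fields `bv_tv`, `tb_th_um`, `tb_n_per_mm` (per axis), `connectivity`,
#'   `da_expected_order`, `provenance`).
#' @export
make_rod_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  v <- spec$voxel_size_um / 1000
  dims <- pmax(1L, as.integer(round(spec$extent_mm / v)))
  cx <- axis_centers_mm(dims[1], spec$voxel_size_um)
  cy <- axis_centers_mm(dims[2], spec$voxel_size_um)
  cz <- axis_centers_mm(dims[3], spec$voxel_size_um)
  nx <- lattice_node_positions(spec$spacing_mm[1], spec$extent_mm[1])
  ny <- lattice_node_positions(spec$spacing_mm[2], spec$extent_mm[2])
  nz <- lattice_node_positions(spec$spacing_mm[3], spec$extent_mm[3])
  r2 <- spec$strut_radius_mm^2
  dx2 <- dist2_to_nodes(cx, nx)
  dy2 <- dist2_to_nodes(cy, ny)
  dz2 <- dist2_to_nodes(cz, nz)
  # struts along z: near a (x,y) node line; along y: near (x,z); along x: near (y,z)
  xy <- outer(dx2, dy2, `+`) <= r2
  xz <- outer(dx2, dz2, `+`) <= r2
  yz <- outer(dy2, dz2, `+`) <= r2
  mask <- array(FALSE, dim = dims)
  mask <- mask | array(rep(xy, dims[3]), dim = dims)
  mask <- mask | aperm(array(rep(xz, dims[2]), dim = c(dims[1], dims[3], dims[2])),
                       c(1, 3, 2))
  mask <- mask | aperm(array(rep(yz, dims[1]), dim = c(dims[2], dims[3], dims[1])),
                       c(3, 1, 2))
  vol <- binary_volume(mask, spec$voxel_size_um)
  truth <- list(
    bv_tv = mean(mask),
    tb_th_um = 2 * spec$strut_radius_mm * 1000,
    tb_n_per_mm = 1 / spec$spacing_mm,
    connectivity = lattice_cycle_rank(length(nx), length(ny), length(nz)),
    da_expected_order = if (length(unique(spec$spacing_mm)) == 1L)
      "isotropic" else "anisotropic",
    provenance = "voxel-oracle"
  )
  list(volume = vol, truth = truth)
}

#' Cycle rank (first Betti number) of a full kx x ky x kz node-strut graph
#'
#' Independent topology oracle for lattice phantoms: vertices are lattice
#' nodes, edges connect axis-adjacent nodes, and the cycle rank of the
#' connected graph is E - V + 1.
#'
#' @param kx,ky,kz node counts per axis.
#' @return integer cycle rank.
#' @export
lattice_cycle_rank <- function(kx, ky = kx, kz = kx) {
  v <- kx * ky * kz
  e <- (kx - 1) * ky * kz + kx * (ky - 1) * kz + kx * ky * (kz - 1)
  as.integer(e - v + 1L)
}

#' Parallel-plate phantom with analytic ground truth
#'
#' Solid plates of thickness `plate_thickness_mm` separated by gaps of
#' `gap_mm`, normal to one axis: the canonical strongly anisotropic fixture.
#' Ground truth: BV.TV = t/(t+g), trabecular thickness = plate thickness,
#' plate-model trabecular number = 1/(t+g).
#'
#' @param plate_thickness_mm,gap_mm plate thickness and inter-plate gap (mm).
#' @param normal_axis axis index (1-3) the plates are normal to.
#' @param extent_mm physical size per axis (length 1 or 3, mm); must cover at
#'   least one full period along the normal axis.
#' @param voxel_size_um voxel size (µm); thickness + gap must span >= 2 voxels.
#' @return list with `volume` and `truth` (as in [make_rod_lattice()]).
#' @export
make_plate_stack <- function(plate_thickness_mm, gap_mm, normal_axis = 3L,
                             extent_mm, voxel_size_um) {
  stopifnot(normal_axis %in% 1:3)
  if (plate_thickness_mm <= 0 || gap_mm < 0) stop("degenerate plate spec")
  period <- plate_thickness_mm + gap_mm
  v <- voxel_size_um / 1000
  if (period < 2 * v) stop("thickness + gap must span at least 2 voxels")
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 3L)
  if (extent_mm[normal_axis] < period) {
    stop("`extent_mm` along the normal axis is smaller than one period")
  }
  dims <- pmax(1L, as.integer(round(extent_mm / v)))
  cn <- axis_centers_mm(dims[normal_axis], voxel_size_um)
  # plates centred at period*(k + 1/2): bone where distance to a centre <= t/2
  centers <- seq(period / 2, extent_mm[normal_axis], by = period)
  dmin <- dist2_to_nodes(cn, centers)
  in_plate <- dmin <= (plate_thickness_mm / 2)^2
  mask <- array(FALSE, dim = dims)
  idx <- slice.index(mask, normal_axis)
  mask[] <- in_plate[idx]
  vol <- binary_volume(mask, voxel_size_um)
  truth <- list(
    bv_tv = plate_thickness_mm / period,
    tb_th_um = plate_thickness_mm * 1000,
    tb_n_per_mm = 1 / period,
    connectivity = 0L,
    da_expected_order = "anisotropic",
    provenance = "analytic"
  )
  list(volume = vol, truth = truth)
}
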