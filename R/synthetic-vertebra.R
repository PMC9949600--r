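#' Synthetic whole "vertebra" phantom
#'
#' Builds a whole-vertebra stand-in: a cortical tube (the centrum) whose outer
#' radius narrows to `waist_fraction * centrum_radius_mm` at mid-length,
#' filled with rod-lattice trabeculae, plus a concentric dorsal arch ring
#' whose inner radius lies outside the centrum so that every transverse slice
#' encloses an annular vertebral foramen between centrum and arch. With
#' `arch_gap = TRUE` a dorsal sector of the arch is cut away, opening the
#' foramen (slices then fail the closed-foramen inclusion rule).
#'
#' The axial radius profile is parabolic:
#' `r(z) = R * (w + (1 - w) * (2 z / L - 1)^2)`, so the narrowest transverse
#' plane is exactly the axial midpoint; its slice index is returned as ground
#' truth for the waist-finding step.
#'
#' @param centrum_radius_mm outer radius of the centrum at its ends.
#' @param waist_fraction waist radius as a fraction of `centrum_radius_mm`,
#'   in (0, 1).
#' @param shell_thickness_mm cortical shell thickness; must span >= 1 voxel.
#' @param arch_inner_radius_mm,arch_outer_radius_mm arch annulus radii; the
#'   inner radius must exceed `centrum_radius_mm` (nested outside).
#' @param interior a [lattice_spec()] for the trabecular filling; its spacing
#'   and strut radius are used, its extent is ignored.
#' @param length_mm cranio-caudal length of the phantom.
#' @param voxel_size_um voxel size.
#' @param arch_gap cut a dorsal sector out of the arch ring?
#' @return list with `volume` ([binary_volume()]) and `truth` (fields
#'   `waist_slice`, `center` (transverse voxel coords), `waist_radius_mm`,
#'   `radius_profile_mm`).
#' @export
make_synthetic_vertebra <- function(centrum_radius_mm = 3,
                                    waist_fraction = 0.7,
                                    shell_thickness_mm = 0.3,
                                    arch_inner_radius_mm = 4,
                                    arch_outer_radius_mm = 5,
                                    interior = lattice_spec(0.5, 0.1, 2, voxel_size_um),
                                    length_mm = 6,
                                    voxel_size_um = 50,
                                    arch_gap = FALSE) {
  if (waist_fraction <= 0 || waist_fraction >= 1) stop("`waist_fraction` must be in (0, 1)")
  if (arch_inner_radius_mm <= centrum_radius_mm) {
    stop("arch radii must be nested outside the centrum")
  }
  if (arch_outer_radius_mm <= arch_inner_radius_mm) stop("arch radii out of order")
  v <- voxel_size_um / 1000
  if (shell_thickness_mm < v) stop("cortical shell thinner than one voxel")

  half_w <- arch_outer_radius_mm + 2 * v       # transverse half-extent with margin
  n1 <- as.integer(round(2 * half_w / v))      # dorso-ventral
  n2 <- n1                                     # medio-lateral
  n3 <- as.integer(round(length_mm / v))       # cranio-caudal
  c1 <- half_w; c2 <- half_w                   # centre of the ring system (mm)

  x <- axis_centers_mm(n1, voxel_size_um) - c1
  y <- axis_centers_mm(n2, voxel_size_um) - c2
  z <- axis_centers_mm(n3, voxel_size_um)
  rr <- sqrt(outer(x^2, y^2, `+`))             # transverse radius per pixel
  # polar angle: dorsal direction = -x (low first index)
  ang <- atan2(outer(rep(1, length(x)), y, function(a, b) b),
               outer(-x, rep(1, length(y)), function(a, b) a))

  # trabecular lattice field (evaluated on the full grid, masked to the interior)
  nx <- lattice_node_positions(interior$spacing_mm[1], 2 * half_w)
  ny <- lattice_node_positions(interior$spacing_mm[2], 2 * half_w)
  nz <- lattice_node_positions(interior$spacing_mm[3], length_mm)
  r2s <- interior$strut_radius_mm^2
  dx2 <- dist2_to_nodes(x + c1, nx)
  dy2 <- dist2_to_nodes(y + c2, ny)
  dz2 <- dist2_to_nodes(z, nz)
  lat_xy <- outer(dx2, dy2, `+`) <= r2s
  lat_xz <- outer(dx2, dz2, `+`) <= r2s
  lat_yz <- outer(dy2, dz2, `+`) <= r2s

  arch_ring <- rr >= arch_inner_radius_mm & rr <= arch_outer_radius_mm
  if (arch_gap) {
    # remove a 40 degree dorsal wedge
    arch_ring <- arch_ring & !(abs(ang) < (20 * pi / 180))
  }

  mask <- array(FALSE, dim = c(n1, n2, n3))
  L <- length_mm
  R <- centrum_radius_mm
  w <- waist_fraction
  for (k in seq_len(n3)) {
    rk <- R * (w + (1 - w) * (2 * z[k] / L - 1)^2)
    shell <- rr <= rk & rr >= rk - shell_thickness_mm
    inside <- rr < rk - shell_thickness_mm
    trab <- (lat_xy | outer(lat_xz[, k], rep(TRUE, n2)) |
               outer(rep(TRUE, n1), lat_yz[, k])) & inside
    mask[, , k] <- shell | trab | arch_ring
  }

  profile <- R * (w + (1 - w) * (2 * z / L - 1)^2)
  truth <- list(
    waist_slice = which.min(profile),
    center = c(c1 / v + 0.5, c2 / v + 0.5),
    waist_radius_mm = min(profile),
    radius_profile_mm = profile
  )
  list(volume = binary_volume(mask, voxel_size_um), truth = truth)
}
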