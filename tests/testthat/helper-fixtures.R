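# Shared fixtures, built in code at test time.

# Small plate stack: 3 full periods of t = 0.1 mm plates, g = 0.4 mm gaps.
plate_fixture <- function(voxel_size_um = 20) {
  make_plate_stack(0.1, 0.4, normal_axis = 3L, extent_mm = 1.5,
                   voxel_size_um = voxel_size_um)
}

# Isotropic rod lattice, 3 periods of 0.5 mm, struts r = 0.05 mm.
lattice_fixture <- function(voxel_size_um = 20, spacing = 0.5,
                            extent = 1.5, radius = 0.05) {
  make_rod_lattice(lattice_spec(spacing, radius, extent, voxel_size_um))
}

# One transverse slice: solid centrum disc r = 3 mm plus arch annulus
# 4-5 mm, the analytic GC/CSA oracle geometry (18*pi bone over 25*pi total).
disc_annulus_slice <- function(voxel_size_um = 25) {
  v <- voxel_size_um / 1000
  n <- round(11 / v)
  cc <- (n + 1) / 2
  m0 <- matrix(0, n, n)
  xx <- (row(m0) - cc) * v
  yy <- (col(m0) - cc) * v
  r <- sqrt(xx^2 + yy^2)
  (r <= 3) | (r >= 4 & r <= 5)
}

# Voxelized solid torus (one handle).
torus_mask <- function() {
  a <- array(FALSE, c(31, 31, 9))
  x <- slice.index(a, 1) - 16
  y <- slice.index(a, 2) - 16
  z <- slice.index(a, 3) - 5
  (sqrt(x^2 + y^2) - 8)^2 + z^2 <= 9
}

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", object, tol, expected))
}
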