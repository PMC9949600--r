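#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. None of these are exported.

#' Shift a 3D array by an integer offset, padding with `fill`.
#' @noRd
shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  kx <- fx >= 1L & fx <= d[1]; ky <- fy >= 1L & fy <= d[2]; kz <- fz >= 1L & fz <= d[3]
  out[sx[kx], sy[ky], sz[kz]] <- a[fx[kx], fy[ky], fz[kz]]
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxel-center coordinates (mm) along one axis: centers at (i - 0.5) * v.
#' @noRd
axis_centers_mm <- function(n, voxel_size_um) {
  (seq_len(n) - 0.5) * voxel_size_um / 1000
}

#' Logical mask of voxels whose centers lie inside a sphere (voxel units).
#' @noRd
sphere_voxel_mask <- function(dims, center, radius) {
  dx2 <- (seq_len(dims[1]) - center[1])^2
  dy2 <- (seq_len(dims[2]) - center[2])^2
  dz2 <- (seq_len(dims[3]) - center[3])^2
  r2 <- radius^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(d2 <= r2, dim = dims)
}

#' Two orthonormal vectors perpendicular to a unit vector w.
#' @noRd
orthonormal_basis <- function(w) {
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(
    w[2] * u[3] - w[3] * u[2],
    w[3] * u[1] - w[1] * u[3],
    w[1] * u[2] - w[2] * u[1]
  )
  list(u = u, v = v)
}
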