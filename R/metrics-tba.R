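#' Full trabecular architecture profile of one ROI
#'
#' Convenience wrapper running all seven microstructure metrics on a
#' spherical ROI and applying the quality-control rules. Returns one row per
#' call, suitable for `rbind`-ing across vertebrae.
#'
#' @param volume a [binary_volume()].
#' @param roi a `sphere_roi`, or `NULL` for the largest centered sphere.
#' @param dirs direction set for MIL/Tb.N.
#' @param sld_dirs coarser direction set for the star length distribution.
#' @param n_points SLD seed points.
#' @param seed RNG seed for the SLD point sample.
#' @param min_connectivity,min_relative_resolution QC thresholds (see
#'   [apply_qc()]).
#' @return data.frame (1 row) with fields `bv_tv`, `tb_th_um`,
#'   `tb_th_plate_um`, `tb_n_per_mm`, `tb_n_plate_per_mm`, `da`, `mil_e1`,
#'   `mil_e2`, `mil_e3`, `sld_ratio`, `connectivity`, `conn_d_per_mm3`,
#'   `relative_resolution`, `qc_pass`, `qc_flagged`.
#' @export
tba_profile <- function(volume, roi = NULL, dirs = direction_set(129L),
                        sld_dirs = direction_set(33L), n_points = 500L,
                        seed = 1L, min_connectivity = 40,
                        min_relative_resolution = 2.5) {
  stopifnot(is_binary_volume(volume))
  roi <- roi %||% default_roi(volume)
  bv <- bv_tv(volume, roi)
  th <- tb_th(volume, roi)
  mil <- mil_analysis(volume, roi, dirs = dirs)
  tn <- tb_n(volume, roi, dirs = dirs, tb_th_mm = th$local_spheres_um / 1000)
  sld <- sld_analysis(volume, roi, n_points = n_points, dirs = sld_dirs,
                      seed = seed)
  cd <- connectivity_density(volume, roi)
  res <- data.frame(
    bv_tv = bv,
    tb_th_um = th$local_spheres_um,
    tb_th_plate_um = th$plate_model_um,
    tb_n_per_mm = tn$tb_n_per_mm,
    tb_n_plate_per_mm = tn$plate_model_per_mm,
    da = mil$da,
    mil_e1 = mil$eigenvalues[1],
    mil_e2 = mil$eigenvalues[2],
    mil_e3 = mil$eigenvalues[3],
    sld_ratio = sld$anisotropy_ratio,
    connectivity = cd$connectivity,
    conn_d_per_mm3 = cd$conn_d_per_mm3
  )
  apply_qc(res, volume$voxel_size_um,
           min_connectivity = min_connectivity,
           min_relative_resolution = min_relative_resolution)
}

#' Quality-control rules for a trabecular architecture result
#'
#' Relative resolution is trabecular thickness divided by voxel size (mean
#' strut width in pixels). A result passes when connectivity is at least
#' `min_connectivity` (low-connectivity ROIs are too small to characterize a
#' network) and relative resolution is at least `min_relative_resolution`.
#' Both comparisons are boundary-inclusive; results sitting exactly on a
#' threshold are flagged in `qc_flagged`.
#'
#' @param result data.frame with columns `tb_th_um` and `connectivity` (for
#'   example one row from [tba_profile()]).
#' @param voxel_size_um voxel size of the analysed stack.
#' @param min_connectivity,min_relative_resolution inclusive thresholds.
#' @return `result` with columns `relative_resolution`, `qc_pass`,
#'   `qc_flagged` appended/updated.
#' @export
apply_qc <- function(result, voxel_size_um, min_connectivity = 40,
                     min_relative_resolution = 2.5) {
  rr <- result$tb_th_um / voxel_size_um
  result$relative_resolution <- rr
  result$qc_pass <- result$connectivity >= min_connectivity &
    rr >= min_relative_resolution
  result$qc_flagged <- result$qc_pass &
    (result$connectivity == min_connectivity | rr == min_relative_resolution)
  result
}
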