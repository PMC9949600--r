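#' Squared Euclidean distance transform of a 3D mask
#'
#' Distance from each foreground voxel center to the nearest background voxel
#' center, computed separably: an exact sequential 1D pass along the first
#' axis, then brute-force lower envelopes along the remaining axes with the
#' offset range bounded by the current maximum distance (trabecular
#' structures are thin, so the bound keeps the cost linear).
#'
#' @param mask 3D logical array (`TRUE` = foreground).
#' @return 3D numeric array of squared distances (voxel units); `Inf` where
#'   no background exists along any path.
#' @export
edt_squared <- function(mask) {
  d <- dim(mask)
  big <- sum(d)^2
  d2 <- array(0, dim = d)
  # 1D pass along axis 1 (sequential, vectorized over the other axes)
  dist1 <- array(big, dim = d)
  dist1[!mask] <- 0
  for (i in seq_len(d[1])[-1]) {
    dist1[i, , ] <- pmin(dist1[i, , ], dist1[i - 1L, , ] + 1)
  }
  for (i in rev(seq_len(d[1])[-d[1]])) {
    dist1[i, , ] <- pmin(dist1[i, , ], dist1[i + 1L, , ] + 1)
  }
  d2 <- dist1^2
  # envelope passes along axes 2 and 3; offsets stop once no voxel's current
  # value exceeds o^2 (no further improvement is possible)
  for (ax in 2:3) {
    src <- d2
    omax <- d[ax] - 1L
    for (o in seq_len(omax)) {
      o2 <- o * o
      if (o2 >= max(d2)) break
      if (ax == 2L) {
        n <- d[2]
        d2[, seq_len(n - o), ] <- pmin(d2[, seq_len(n - o), , drop = FALSE],
                                       src[, (o + 1L):n, , drop = FALSE] + o2)
        d2[, (o + 1L):n, ] <- pmin(d2[, (o + 1L):n, , drop = FALSE],
                                   src[, seq_len(n - o), , drop = FALSE] + o2)
      } else {
        n <- d[3]
        d2[, , seq_len(n - o)] <- pmin(d2[, , seq_len(n - o), drop = FALSE],
                                       src[, , (o + 1L):n, drop = FALSE] + o2)
        d2[, , (o + 1L):n] <- pmin(d2[, , (o + 1L):n, drop = FALSE],
                                   src[, , seq_len(n - o), drop = FALSE] + o2)
      }
    }
  }
  d2[d2 >= big^2] <- Inf
  d2
}

## Local thickness by sphere fitting: every bone voxel's thickness is the
## diameter of the largest inscribed sphere containing it. Sphere centers are
## the distance-transform values, painted in decreasing radius order;
## candidate centers already covered by an equal-or-larger sphere are skipped
## (the standard dominance shortcut, sub-voxel error only). Radii are binned
## to half-voxels for the vectorized ball dilation.
local_thickness <- function(mask) {
  d <- dim(mask)
  dist <- sqrt(edt_squared(mask))
  dist[!mask] <- 0
  lt <- array(0, dim = d)
  rbin <- round(dist * 2) / 2
  radii <- sort(unique(rbin[rbin > 0]), decreasing = TRUE)
  for (r in radii) {
    centers <- rbin == r & lt < 2 * r
    if (!any(centers)) next
    omax <- floor(r)
    covered <- centers
    for (dx in -omax:omax) for (dy in -omax:omax) for (dz in -omax:omax) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (dx * dx + dy * dy + dz * dz > r * r) next
      covered <- covered | shift3(centers, dx, dy, dz)
    }
    upd <- covered & mask & lt < 2 * r
    lt[upd] <- 2 * r
  }
  lt
}

#' Trabecular thickness
#'
#' Headline estimator (`local_spheres`): the mean over bone voxels in the ROI
#' of the diameter of the largest inscribed sphere containing the voxel
#' (distance-transform based). Secondary estimator (`plate_model`):
#' `2 * BV / BS` with the bone surface estimated by counting exposed voxel
#' faces. Both are reported because different software lineages use different
#' estimators and their offset is of interest when comparing published
#' values.
#'
#' @param volume a [binary_volume()].
#' @param roi a `sphere_roi` or `NULL` for the whole volume.
#' @return list with `local_spheres_um`, `plate_model_um`, `n_bone_voxels`.
#' @export
tb_th <- function(volume, roi = NULL) {
  stopifnot(is_binary_volume(volume))
  mask <- volume$mask
  d <- dim(mask)
  sel <- if (is.null(roi)) array(TRUE, d) else
    sphere_voxel_mask(d, roi$center, roi$radius)
  bone_in <- mask & sel
  if (!any(bone_in)) stop("no bone voxels in the ROI")
  v <- volume$voxel_size_um
  lt <- local_thickness(mask)
  local_um <- mean(lt[bone_in]) * v

  # plate model: exposed faces of bone voxels inside the ROI
  faces <- 0
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- shift3(mask, sh[1], sh[2], sh[3], fill = FALSE)
    faces <- faces + sum(bone_in & !nb)
  }
  bv <- sum(bone_in)
  plate_um <- if (faces > 0) 2 * bv / faces * v else Inf
  list(local_spheres_um = local_um, plate_model_um = plate_um,
       n_bone_voxels = bv)
}
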