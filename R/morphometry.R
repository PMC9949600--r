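#' Closed-foramen slice inclusion rule
#'
#' A transverse slice of a whole-vertebra stack qualifies for global
#' compactness / cross-sectional area measurement only when the vertebral
#' foramen is completely surrounded by bone: the slice background must have a
#' 4-connected component that does not touch the slice border. A binarized
#' vertebra also encloses trabecular cavities inside the centrum in every
#' slice, so by default enclosed components lying wholly inside the centrum
#' region ([centrum_mask()]) are discounted -- only a cavity outside the
#' centrum (the foramen between centrum and neural arch) qualifies a slice.
#' Set `discount_centrum = FALSE` for the literal flood-fill rule, which is
#' appropriate for sections without internal trabecular cavities.
#'
#' @param volume a [binary_volume()] of a whole vertebra.
#' @param discount_centrum ignore enclosed cavities inside the centrum region?
#' @param centrum optional precomputed centrum mask.
#' @return logical vector, one flag per slice.
#' @export
slice_inclusion <- function(volume, discount_centrum = TRUE, centrum = NULL) {
  stopifnot(is_binary_volume(volume))
  d <- dim(volume$mask)
  if (discount_centrum && is.null(centrum)) centrum <- centrum_mask(volume)
  vapply(seq_len(d[3]), function(k) {
    slice_has_enclosed_cavity(volume$mask[, , k],
                              if (discount_centrum) centrum[, , k] else NULL)
  }, logical(1))
}

slice_has_enclosed_cavity <- function(sl, centrum_sl = NULL) {
  bg <- !sl
  if (!any(bg)) return(FALSE)
  lab <- EBImage::bwlabel(bg * 1L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  enclosed <- setdiff(unique(as.vector(lab)), c(0L, border))
  if (length(enclosed) == 0L) return(FALSE)
  if (!is.null(centrum_sl)) {
    enclosed <- Filter(function(e) any(lab == e & !centrum_sl), enclosed)
  }
  length(enclosed) > 0L
}

#' Global compactness and cross-sectional area
#'
#' Over the slices passing the closed-foramen rule ([slice_inclusion()]):
#' per-slice bone area is the bone pixel count times pixel area; per-slice
#' total area fills all enclosed holes (bone plus enclosed cavities, not the
#' convex hull). Cross-sectional area is the unweighted mean bone area
#' (mm^2); global compactness is the unweighted mean of the per-slice
#' bone/total ratios.
#'
#' @param volume a [binary_volume()] of a whole vertebra.
#' @param voxel_size_um voxel size; defaults to the volume's.
#' @return list with `csa_mm2`, `gc`, `n_slices_included`, `per_slice`
#'   (data.frame: slice, bone_area_mm2, total_area_mm2, foramen_closed).
#' @export
gc_csa <- function(volume, voxel_size_um = volume$voxel_size_um) {
  stopifnot(is_binary_volume(volume))
  inc <- slice_inclusion(volume)
  if (!any(inc)) stop("no enclosed foramen: no slice qualifies")
  d <- dim(volume$mask)
  pa <- (voxel_size_um / 1000)^2
  bone_a <- total_a <- numeric(d[3])
  for (k in seq_len(d[3])) {
    sl <- volume$mask[, , k]
    bone_a[k] <- sum(sl) * pa
    total_a[k] <- sum(EBImage::fillHull(sl * 1L) > 0) * pa
  }
  ratio <- ifelse(total_a > 0, bone_a / total_a, NA_real_)
  list(csa_mm2 = mean(bone_a[inc]),
       gc = mean(ratio[inc]),
       n_slices_included = sum(inc),
       per_slice = data.frame(slice = seq_len(d[3]),
                              bone_area_mm2 = bone_a,
                              total_area_mm2 = total_a,
                              foramen_closed = inc))
}
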