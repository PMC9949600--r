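## 3D connected-component labelling via igraph on the voxel adjacency graph.
## `offsets` selects the connectivity (13 half-neighbourhood offsets for
## 26-connectivity, 3 for 6-connectivity).
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- if (connectivity == 26L) {
    og <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    og <- og[og$dx != 0 | og$dy != 0 | og$dz != 0, ]
    # half of the symmetric set is enough for an undirected graph
    og[og$dz > 0 | (og$dz == 0 & og$dy > 0) |
         (og$dz == 0 & og$dy == 0 & og$dx > 0), ]
  } else {
    data.frame(dx = c(1, 0, 0), dy = c(0, 1, 0), dz = c(0, 0, 1))
  }
  vox <- which(mask)
  if (length(vox) == 0L) return(list(labels = array(0L, d), n = 0L, sizes = integer(0)))
  id <- array(0L, d)
  id[vox] <- seq_along(vox)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(mask, offs$dx[r], offs$dy[r], offs$dz[r], fill = FALSE)
    both <- mask & nb
    if (!any(both)) next
    a <- id[both]
    nbid <- shift3(id, offs$dx[r], offs$dy[r], offs$dz[r], fill = 0L)
    b <- nbid[both]
    from <- c(from, a); to <- c(to, b)
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = length(vox),
                          directed = FALSE)
  comp <- igraph::components(g)
  labels <- array(0L, d)
  labels[vox] <- comp$membership
  list(labels = labels, n = comp$no, sizes = as.integer(comp$csize))
}

#' Purify a binary volume (largest bone and background components)
#'
#' Keeps only the largest 26-connected bone component (stray particles become
#' background) and the largest 6-connected background component (enclosed
#' cavities become bone), the standard pre-processing before an
#' Euler-characteristic connectivity count.
#'
#' @param mask 3D logical array.
#' @return purified 3D logical array.
#' @export
purify_mask <- function(mask) {
  lb <- label_components(mask, 26L)
  if (lb$n > 1L) {
    keep <- which.max(lb$sizes)
    mask <- lb$labels == keep
  }
  lbg <- label_components(!mask, 6L)
  if (lbg$n > 1L) {
    keep <- which.max(lbg$sizes)
    mask <- mask | (lbg$labels != keep & lbg$labels > 0L)
  }
  mask
}

#' Euler characteristic of a voxel complex
#'
#' Computes chi = V - E + F - C of the cubical complex occupied by the
#' foreground voxels (vertices, edges, faces shared between voxels counted
#' once). For a connected, cavity-free structure the connectivity (first
#' Betti number, number of independent loops) is 1 - chi.
#'
#' @param mask 3D logical array.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  occ <- function(offsets) {
    # count grid elements touched by >= 1 voxel among the offset stencil
    acc <- array(FALSE, dim = d + 1L)
    for (off in offsets) {
      acc <- acc | pad[(2L - off[1]):(d[1] + 2L - off[1]),
                       (2L - off[2]):(d[2] + 2L - off[2]),
                       (2L - off[3]):(d[3] + 2L - off[3])]
    }
    sum(acc)
  }
  verts <- occ(lapply(seq_len(8) - 1L,
                      function(b) c(b %% 2L, (b %/% 2L) %% 2L, b %/% 4L)))
  ex <- occ(list(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 1)))
  ey <- occ(list(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1)))
  ez <- occ(list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  fx <- occ(list(c(0, 0, 0), c(1, 0, 0)))
  fy <- occ(list(c(0, 0, 0), c(0, 1, 0)))
  fz <- occ(list(c(0, 0, 0), c(0, 0, 1)))
  cells <- sum(mask)
  as.integer(verts - (ex + ey + ez) + (fx + fy + fz) - cells)
}

#' Connectivity and connectivity density
#'
#' With purification on (default), retains the largest 26-connected bone
#' component and fills enclosed cavities, then computes the Euler
#' characteristic by the vertex - edge + face - cell decomposition of the
#' voxel complex. Connectivity is `1 - chi` (the number of independent
#' loops); connectivity density divides by the ROI volume in mm^3. A negative
#' connectivity after purification indicates topological noise; it is
#' reported clamped to zero with a flag and a warning.
#'
#' @param volume a [binary_volume()].
#' @param roi a `sphere_roi`, or `NULL` to analyse the whole volume.
#' @param purify apply the purification step?
#' @return list with `connectivity`, `conn_d_per_mm3`, `euler`,
#'   `clamped` (logical), `roi_volume_mm3`.
#' @export
connectivity_density <- function(volume, roi = NULL, purify = TRUE) {
  stopifnot(is_binary_volume(volume))
  d <- dim(volume$mask)
  if (is.null(roi)) {
    sub <- volume$mask
    nvox <- prod(d)
  } else {
    sel <- sphere_voxel_mask(d, roi$center, roi$radius)
    if (!any(sel)) stop("empty ROI")
    sub <- volume$mask & sel
    nvox <- sum(sel)
  }
  if (purify) sub <- purify_mask(sub)
  chi <- euler_characteristic(sub)
  conn <- 1L - chi
  clamped <- FALSE
  if (conn < 0L) {
    warning("negative connectivity after purification (topological noise); ",
            "reporting 0")
    conn <- 0L
    clamped <- TRUE
  }
  vmm3 <- (volume$voxel_size_um / 1000)^3
  roi_vol <- nvox * vmm3
  list(connectivity = conn, conn_d_per_mm3 = conn / roi_vol, euler = chi,
       clamped = clamped, roi_volume_mm3 = roi_vol)
}
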