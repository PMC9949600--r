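#' Default per-slice centrum mask
#'
#' Heuristic stand-in for the operator's by-eye delineation of the centrum:
#' in each transverse slice, bone is labelled into 4-connected components;
#' the centrum is taken to be the largest component that lies inside the
#' filled hull of another component (the arch ring encloses the centrum in
#' our whole-vertebra phantoms), falling back to the largest bone component
#' when no component is enclosed. The returned mask is the filled hull of
#' that component, i.e. the bone-bounded centrum region. Callers with real
#' anatomy should supply their own mask.
#'
#' @param volume a [binary_volume()] of a whole vertebra.
#' @return 3D logical array, `TRUE` inside the centrum region per slice.
#' @export
centrum_mask <- function(volume) {
  stopifnot(is_binary_volume(volume))
  d <- dim(volume$mask)
  out <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) {
    sl <- volume$mask[, , k]
    if (!any(sl)) next
    lab <- EBImage::bwlabel(sl * 1L)
    nlab <- max(lab)
    if (nlab == 0L) next
    hulls <- lapply(seq_len(nlab), function(l) EBImage::fillHull(lab == l) > 0)
    hull_area <- vapply(hulls, sum, numeric(1))
    # the centrum is the smallest bone-bounded region containing the bone
    # centroid (the arch ring, when closed, bounds a larger region around it)
    cen <- round(c(mean(which(sl, arr.ind = TRUE)[, 1]),
                   mean(which(sl, arr.ind = TRUE)[, 2])))
    cand <- which(vapply(hulls, function(h) h[cen[1], cen[2]], logical(1)))
    pick <- if (length(cand) > 0L) {
      cand[which.min(hull_area[cand])]
    } else {
      which.max(hull_area)
    }
    out[, , k] <- hulls[[pick]]
  }
  out
}

#' Side length of the largest axis-aligned square of TRUEs (dynamic program)
#'
#' Classic all-ones-square DP; also returns the bottom-right corner of one
#' maximal square so the square can be placed.
#'
#' @param m logical matrix.
#' @return list `side`, `row`, `col` (top-left corner of a maximal square).
#' @export
largest_square <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0L, nr, nc)
  s[1, ] <- m[1, ] * 1L
  s[, 1] <- m[, 1] * 1L
  if (nr > 1L && nc > 1L) {
    for (i in 2:nr) {
      si1 <- s[i - 1L, ]
      si <- s[i, ]
      for (j in 2:nc) {
        if (m[i, j]) si[j] <- min(si1[j], si[j - 1L], si1[j - 1L]) + 1L
      }
      s[i, ] <- si
    }
  }
  side <- max(s)
  if (side == 0L) return(list(side = 0L, row = NA_integer_, col = NA_integer_))
  w <- which(s == side, arr.ind = TRUE)[1, ]
  list(side = as.integer(side),
       row = as.integer(w[1] - side + 1L),
       col = as.integer(w[2] - side + 1L))
}

## Interior (trabecular) region of one slice given the filled centrum mask:
## the part of the centrum deeper (by 2D distance to the centrum's outside)
## than the cortical shell. Shell depth is estimated from the trabecular
## space itself: the shallowest pixel of the largest intra-centrum background
## component marks where the cortex ends. The interior therefore contains
## both trabecular struts and inter-trabecular space, which is what the
## inscribed square must cover.
slice_interior <- function(bone_slice, centrum_slice) {
  empty <- matrix(FALSE, nrow(bone_slice), ncol(bone_slice))
  if (!any(centrum_slice)) return(empty)
  bg <- centrum_slice & !bone_slice
  if (!any(bg)) return(empty)
  d2 <- edt_squared(array(centrum_slice, dim = c(dim(centrum_slice), 1)))[, , 1]
  shell_depth <- sqrt(min(d2[bg]))
  centrum_slice & sqrt(d2) > max(0, shell_depth - 1)
}

#' Prism volume of interest at the centrum waist
#'
#' Implements the VOI protocol: find the transverse slice where the centrum
#' is narrowest (lexicographically by dorso-ventral then medio-lateral
#' extent; ties broken to the slice nearest the axial midpoint), inscribe the
#' largest axis-aligned square in the trabecular interior of that slice, and
#' extend the square symmetrically in both cranio-caudal directions while
#' every included slice's interior still contains it.
#'
#' @param volume a [binary_volume()] of a whole vertebra.
#' @param centrum 3D logical centrum mask; computed by [centrum_mask()] when
#'   omitted.
#' @return list of class `prism_voi`: `side`, `center` (2 transverse voxel
#'   indices), `zlim` (first and last included slice, inclusive), `square`
#'   (top-left corner), `waist_slice`.
#' @export
extract_prism_voi <- function(volume, centrum = NULL) {
  stopifnot(is_binary_volume(volume))
  if (is.null(centrum)) centrum <- centrum_mask(volume)
  d <- dim(volume$mask)
  dv <- ml <- rep(NA_integer_, d[3])
  for (k in seq_len(d[3])) {
    sl <- centrum[, , k]
    if (!any(sl)) next
    rws <- range(which(rowSums(sl) > 0))
    cls <- range(which(colSums(sl) > 0))
    dv[k] <- rws[2] - rws[1] + 1L
    ml[k] <- cls[2] - cls[1] + 1L
  }
  ok <- which(!is.na(dv))
  if (length(ok) == 0L) stop("VOI too small: no centrum region found")
  o <- ok[order(dv[ok], ml[ok], abs(ok - (d[3] + 1) / 2), ok)]
  waist <- o[1]

  interior <- slice_interior(volume$mask[, , waist], centrum[, , waist])
  if (sum(interior) < 9L) stop("VOI too small: interior region < 3 voxels across")
  sq <- largest_square(interior)
  if (sq$side < 3L) stop("VOI too small: interior region < 3 voxels across")
  ri <- sq$row:(sq$row + sq$side - 1L)
  ci <- sq$col:(sq$col + sq$side - 1L)

  fits <- function(k) {
    intr <- slice_interior(volume$mask[, , k], centrum[, , k])
    all(intr[ri, ci])
  }
  lo <- hi <- waist
  repeat {
    grew <- FALSE
    if (lo > 1L && fits(lo - 1L)) { lo <- lo - 1L; grew <- TRUE }
    if (hi < d[3] && fits(hi + 1L)) { hi <- hi + 1L; grew <- TRUE }
    if (!grew) break
  }
  structure(list(side = sq$side,
                 center = c(sq$row + (sq$side - 1) / 2,
                            sq$col + (sq$side - 1) / 2),
                 zlim = c(lo, hi),
                 square = c(sq$row, sq$col),
                 waist_slice = waist),
            class = "prism_voi")
}

#' Largest centered sphere inscribed in a prism VOI
#'
#' The sphere shares the prism's centroid; its radius is half the smaller of
#' the square side and the cranio-caudal extent. Using the inscribed sphere
#' as the analysis region removes the prism's edge and corner artifacts.
#'
#' @param voi a `prism_voi`.
#' @return list of class `sphere_roi`: `center` (3 voxel coordinates),
#'   `radius` (voxels).
#' @export
inscribed_sphere <- function(voi) {
  stopifnot(inherits(voi, "prism_voi"))
  zext <- voi$zlim[2] - voi$zlim[1] + 1L
  structure(list(center = c(voi$center, (voi$zlim[1] + voi$zlim[2]) / 2),
                 radius = min(voi$side, zext) / 2),
            class = "sphere_roi")
}

#' @export
print.prism_voi <- function(x, ...) {
  cat(sprintf("<prism_voi> side %d, waist slice %d, z %d..%d\n",
              x$side, x$waist_slice, x$zlim[1], x$zlim[2]))
  invisible(x)
}

#' @export
print.sphere_roi <- function(x, ...) {
  cat(sprintf("<sphere_roi> center (%.1f, %.1f, %.1f), radius %.1f voxels\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Serialize a VOI or ROI to JSON
#' @param x a `prism_voi` or `sphere_roi`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Construct a sphere ROI directly
#' @param center length-3 numeric voxel coordinates.
#' @param radius radius in voxels.
#' @return a `sphere_roi`.
#' @export
sphere_roi <- function(center, radius) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "sphere_roi")
}
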