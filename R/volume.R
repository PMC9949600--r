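#' Binary µCT volume
#'
#' Container for a binarized image stack: a 3D logical array (`TRUE` = bone)
#' with an isotropic physical voxel size. Axis convention: the third array
#' index runs cranio-caudally (one transverse slice per index); within a
#' transverse slice the first index is dorso-ventral (dorsal = low index) and
#' the second medio-lateral.
#'
#' @param mask 3D logical (or 0/1) array, `TRUE` where bone.
#' @param voxel_size_um isotropic voxel edge length in micrometres.
#' @return An object of class `binary_volume` with fields `mask` and
#'   `voxel_size_um`.
#' @export
binary_volume <- function(mask, voxel_size_um) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("`mask` must be logical or 0/1")
    mask <- array(mask > 0, dim = dim(mask))
  }
  if (any(dim(mask) == 0L)) stop("`mask` must be nonempty")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number")
  }
  structure(list(mask = mask, voxel_size_um = as.numeric(voxel_size_um)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %.3f um, BV fraction %.4f\n",
              d[1], d[2], d[3], x$voxel_size_um, mean(x$mask)))
  invisible(x)
}

is_binary_volume <- function(x) inherits(x, "binary_volume")

sidecar_path <- function(path) paste0(path, ".json")

#' Write a binary volume as a multi-page 8-bit TIFF plus JSON sidecar
#'
#' Bone voxels are written as 255, background as 0, one transverse slice per
#' page. The voxel size is stored in a sidecar JSON file (`<path>.json`)
#' because baseline TIFF has no reliable slot for a 3D isotropic voxel size.
#'
#' @param volume a [binary_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(volume, path) {
  stopifnot(is_binary_volume(volume))
  pages <- lapply(seq_len(dim(volume$mask)[3]),
                  function(k) volume$mask[, , k] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size_um,
         dims = dim(volume$mask),
         encoding = list(background = 0L, bone = 255L)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack with its JSON voxel-size sidecar
#'
#' By default the stack must already be binary (only the values 0 and 255, or
#' 0 and 1); pass `grayscale = TRUE` to obtain the raw 8-bit intensities for
#' subsequent [binarize()].
#'
#' @param path TIFF path written by [save_stack()] or equivalent.
#' @param grayscale if `TRUE`, return the 8-bit grayscale array instead of
#'   requiring a binary stack.
#' @return A [binary_volume()], or (with `grayscale = TRUE`) a list with
#'   fields `intensities` (3D integer array, 0-255) and `voxel_size_um`.
#' @export
load_stack <- function(path, grayscale = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing sidecar '", sc, "': field `voxel_size_um` is required")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  v <- meta$voxel_size_um
  if (is.null(v)) stop("sidecar is missing field `voxel_size_um`")
  if (length(v) > 1L) {
    if (length(unique(v)) > 1L) stop("anisotropic `voxel_size_um` is not supported")
    v <- v[1]
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  if (length(d1) > 2L) stop("expected single-channel (grayscale) TIFF pages")
  arr <- array(0L, dim = c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (!identical(dim(pg), d1)) stop("TIFF pages differ in size")
    arr[, , k] <- as.integer(round(pg * 255))
  }
  if (grayscale) {
    return(list(intensities = arr, voxel_size_um = as.numeric(v)))
  }
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0L, 1L, 255L))) {
    stop("stack is 8-bit grayscale, not binary: use load_stack(grayscale = TRUE) ",
         "and binarize() with a threshold")
  }
  binary_volume(arr > 0L, v)
}

#' Binarize an 8-bit grayscale stack
#'
#' Voxels with intensity greater than or equal to the threshold are bone
#' (inclusive at the threshold, mirroring the usual 127-255 binary
#' convention). With `method = "otsu"` the threshold maximizes between-class
#' variance over all candidate cutpoints.
#'
#' @param intensities 3D array of integers in 0-255, or the list returned by
#'   `load_stack(path, grayscale = TRUE)`.
#' @param voxel_size_um voxel size; taken from `intensities` when it is a
#'   `load_stack()` result.
#' @param method `"fixed"` or `"otsu"`.
#' @param threshold intensity cutoff for `method = "fixed"`.
#' @return A [binary_volume()] with attributes `threshold` and
#'   `bone_fraction`.
#' @export
binarize <- function(intensities, voxel_size_um = NULL,
                     method = c("fixed", "otsu"), threshold = 128L) {
  method <- match.arg(method)
  if (is.list(intensities) && !is.null(intensities$intensities)) {
    voxel_size_um <- voxel_size_um %||% intensities$voxel_size_um
    intensities <- intensities$intensities
  }
  if (is.null(voxel_size_um)) stop("`voxel_size_um` is required")
  if (length(dim(intensities)) != 3L) stop("`intensities` must be a 3D array")
  x <- as.integer(intensities)
  if (any(x < 0L | x > 255L)) stop("intensities must lie in 0-255")
  if (method == "otsu") {
    threshold <- otsu_threshold(x)
  } else {
    if (threshold <= 0 || threshold > 255) stop("`threshold` must be in (0, 255]")
  }
  mask <- array(intensities >= threshold, dim = dim(intensities))
  out <- binary_volume(mask, voxel_size_um)
  attr(out, "threshold") <- as.numeric(threshold)
  attr(out, "bone_fraction") <- mean(mask)
  out
}

#' Otsu threshold: cutpoint t (bone = intensity >= t) maximizing
#' between-class variance. Errors on constant images.
#' @noRd
otsu_threshold <- function(x) {
  if (length(unique(x)) < 2L) stop("constant image: Otsu threshold is undefined")
  h <- tabulate(x + 1L, nbins = 256L)
  n <- sum(h)
  levels <- 0:255
  cum_n <- cumsum(h)
  cum_s <- cumsum(h * levels)
  total <- cum_s[256]
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 1:255) {
    n0 <- cum_n[t]          # class "background": intensity < t  (levels 0..t-1)
    n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    m0 <- cum_s[t] / n0
    m1 <- (total - cum_s[t]) / n1
    v <- n0 * n1 * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}
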