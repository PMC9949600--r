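#' Quasi-uniform direction set on the hemisphere
#'
#' Unit vectors distributed by a Fibonacci spiral over the upper hemisphere
#' (z > 0), so no two directions are antipodal. The default of 2049
#' directions matches the density used by standard fabric-tensor software;
#' tests and desk-scale analyses use far fewer. An optional seed applies a
#' random rigid rotation to the whole set so repeated analyses can decorrelate
#' the sampling pattern from the lattice axes while staying reproducible.
#'
#' @param n number of directions.
#' @param seed optional integer; if given, the spiral is rotated by a random
#'   rotation drawn reproducibly from this seed.
#' @return `n` x 3 matrix of unit row vectors, class `direction_set`.
#' @export
direction_set <- function(n = 2049L, seed = NULL) {
  stopifnot(n >= 1L)
  i <- seq_len(n) - 0.5
  z <- i / n                       # hemisphere: z in (0, 1)
  phi <- i * pi * (3 - sqrt(5))    # golden angle
  s <- sqrt(pmax(0, 1 - z^2))
  m <- cbind(s * cos(phi), s * sin(phi), z)
  if (!is.null(seed)) {
    rot <- random_rotation(seed)
    m <- m %*% t(rot)
    # keep the antipodal-free convention: flip into z >= 0
    flip <- m[, 3] < 0
    m[flip, ] <- -m[flip, ]
  }
  colnames(m) <- c("x", "y", "z")
  class(m) <- c("direction_set", class(m))
  m
}

#' Random rotation matrix from a seed (QR of a Gaussian matrix).
#' @noRd
random_rotation <- function(seed) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run code with a local RNG state seeded from `seed` (no global side effects).
#' @noRd
with_local_seed <- function(seed, code) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  code
}
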