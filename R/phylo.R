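#' Brownian-motion species covariance from a phylogeny
#'
#' Under Brownian motion the expected trait covariance of two species is
#' proportional to the shared branch length from the root to their most
#' recent common ancestor. Tip labels must be unique and branch lengths
#' non-negative.
#'
#' @param tree an `ape` `phylo` object with branch lengths.
#' @param species optional character vector giving the row/column order.
#' @return symmetric positive semi-definite matrix with species dimnames.
#' @export
brownian_cov <- function(tree, species = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  C <- ape::vcv.phylo(tree)
  if (max(diag(C)) <= 0) stop("zero-depth tree")
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(C))
    if (length(missing) > 0L) {
      stop("species not in tree: ", paste(missing, collapse = ", "))
    }
    C <- C[species, species]
  }
  C
}

#' Phylogenetic generalized least squares regression
#'
#' GLS estimate `(X' C^-1 X)^-1 X' C^-1 y` of a log10-log10 regression with
#' Brownian error covariance `C`. Expects one row (a species mean) per
#' species; confidence intervals and the two-sided p-value for the slope use
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y positive numeric vectors named by species (or aligned with `C`).
#' @param C species covariance matrix from [brownian_cov()].
#' @param ci_level confidence level.
#' @return a `loglog_fit` with `model = "Brownian"`.
#' @export
pgls <- function(x, y, C, ci_level = 0.95) {
  if (length(x) != length(y) || length(x) != nrow(C)) {
    stop("x, y and C dimensions disagree")
  }
  if (any(x <= 0) || any(y <= 0)) stop("nonpositive values in x or y")
  if (!is.null(names(x)) && !is.null(rownames(C))) {
    if (!setequal(names(x), rownames(C))) stop("species names do not match C")
    C <- C[names(x), names(x)]
  }
  n <- length(x)
  lx <- log10(x); ly <- log10(y)
  Ci <- tryCatch(solve(C), error = function(e) {
    stop("singular covariance matrix; consider jittering branch lengths or a ",
         "lambda transform")
  })
  X <- cbind(1, lx)
  XtCi <- t(X) %*% Ci
  beta <- solve(XtCi %*% X, XtCi %*% ly)
  r <- ly - X %*% beta
  df <- n - 2L
  s2 <- as.numeric(t(r) %*% Ci %*% r) / df
  vb <- s2 * solve(XtCi %*% X)
  se <- sqrt(diag(vb))
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df)
  tval <- beta[2] / se[2]
  # GLS pseudo-R^2: variance explained in the whitened coordinates
  L <- t(chol(Ci))
  yw <- t(L) %*% ly
  rw <- t(L) %*% r
  ones <- t(L) %*% rep(1, n)
  fit0 <- ones * as.numeric(crossprod(ones, yw) / crossprod(ones))
  r2 <- 1 - sum(rw^2) / sum((yw - fit0)^2)
  structure(list(slope = beta[2], intercept = beta[1],
                 ci_low = beta[2] - tcrit * se[2],
                 ci_high = beta[2] + tcrit * se[2],
                 p_value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                 r_squared = r2,
                 n = n, ci_level = ci_level, model = "Brownian"),
            class = "loglog_fit")
}

#' Blomberg's K with a permutation test
#'
#' K compares the observed ratio of the trait's mean squared error around the
#' phylogenetically corrected mean (MSE0) to the phylogenetically corrected
#' mean squared error (MSE), against the ratio expected under Brownian motion
#' on the candidate tree; K near 1 indicates Brownian-like signal, K << 1
#' less signal than expected. Significance is assessed by permuting trait
#' values across tips and recomputing MSE0/MSE, with the (r+1)/(n+1)
#' correction.
#'
#' @param trait numeric vector named by species.
#' @param tree `phylo` object containing those species as tips.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list of class `phylo_signal`: `K`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
blomberg_k <- function(trait, tree, n_perm = 1000L, seed = 1L) {
  if (is.null(names(trait))) stop("trait must be named by species")
  if (length(trait) < 4L) stop("need at least 4 tips")
  if (stats::var(trait) == 0) stop("constant trait: K is undefined")
  C <- brownian_cov(tree, names(trait))
  n <- length(trait)
  Ci <- solve(C)
  one <- rep(1, n)
  denom_a <- as.numeric(t(one) %*% Ci %*% one)
  expected <- (sum(diag(C)) - n / denom_a) / (n - 1)
  ratio <- function(y) {
    a <- as.numeric(t(one) %*% Ci %*% y) / denom_a
    mse0 <- sum((y - a)^2) / (n - 1)
    mse <- as.numeric(t(y - a) %*% Ci %*% (y - a)) / (n - 1)
    mse0 / mse
  }
  obs <- ratio(trait)
  K <- obs / expected
  perm_ratios <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) ratio(sample(trait)), numeric(1))
  })
  r <- sum(perm_ratios >= obs)
  structure(list(K = K, p_value = (r + 1) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("<phylo_signal> Blomberg's K = %.3f, permutation p = %.3g (%d perms)\n",
              x$K, x$p_value, x$n_permutations))
  invisible(x)
}

#' Average regression results across vertebral positions
#'
#' Arithmetic means of slope, confidence bounds and p-values over per-position
#' fits, with the per-position slope range, and an "average (range)" label
#' matching the conventional table layout.
#'
#' @param results list of `loglog_fit` objects (one per position).
#' @return list: `slope`, `ci_low`, `ci_high`, `p_value`, `slope_range`,
#'   `label`, `n_positions`.
#' @export
average_over_positions <- function(results) {
  if (length(results) < 1L) stop("no position fits supplied")
  slopes <- vapply(results, `[[`, numeric(1), "slope")
  lo <- vapply(results, `[[`, numeric(1), "ci_low")
  hi <- vapply(results, `[[`, numeric(1), "ci_high")
  p <- vapply(results, `[[`, numeric(1), "p_value")
  rng <- range(slopes)
  list(slope = mean(slopes), ci_low = mean(lo), ci_high = mean(hi),
       p_value = mean(p), slope_range = rng,
       label = sprintf("%.2f (%.2f-%.2f)", mean(slopes), rng[1], rng[2]),
       n_positions = length(results))
}
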