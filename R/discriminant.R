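## Optimal-scoring linear discriminant core. X: n x p numeric (already
## transformed/whitened), Y: n x K class weight matrix (indicator for plain
## FDA, whitened indicator for the phylogenetic variant). Returns discriminant
## directions, class centroids in discriminant space, per-dimension weights
## and priors, so that classification is nearest centroid under the weighted
## metric minus log prior.
optimal_scoring_fit <- function(X, Y, ridge = 0) {
  n <- nrow(X)
  K <- ncol(Y)
  cw <- colSums(Y)
  if (any(cw <= 0)) stop("every class needs positive weight")
  Xm <- colMeans(X)
  Xc <- sweep(X, 2, Xm)
  XtX <- crossprod(Xc)
  if (ridge > 0) XtX <- XtX + diag(ridge, ncol(Xc))
  qrX <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(qrX)) {
    warning("singular within-class covariance; applying ridge jitter")
    XtX <- XtX + diag(1e-8 * mean(diag(XtX)), ncol(Xc))
    qrX <- solve(XtX)
  }
  B <- qrX %*% crossprod(Xc, Y)            # p x K regression coefficients
  M <- crossprod(Y, Xc %*% B)              # K x K = Y' X B
  Dh <- diag(1 / sqrt(cw), K)
  Ms <- Dh %*% M %*% Dh
  Ms <- (Ms + t(Ms)) / 2
  eg <- eigen(Ms, symmetric = TRUE)
  keep <- which(eg$values > 1e-9 & eg$values < 1 - 1e-9)
  keep <- utils::head(keep, min(ncol(X), K - 1L))
  if (length(keep) == 0L) keep <- 1L
  alpha2 <- pmin(pmax(eg$values[keep], 1e-9), 1 - 1e-9)
  theta <- Dh %*% eg$vectors[, keep, drop = FALSE]   # class scores
  V <- B %*% theta                         # discriminant directions (p x L)
  H <- Xc %*% V                            # variates for training rows
  # class centroids in variate space, weighted by Y
  cent <- sweep(crossprod(Y, H), 1, cw, `/`)
  # scale each variate to unit pooled within-class variance so that nearest
  # centroid (minus log prior) in this space is the canonical LDA rule
  R <- H - Y %*% cent
  wv <- colSums(R^2) / max(1, n - K)
  wts <- 1 / pmax(wv, 1e-12)
  list(Xmean = Xm, V = V, centroids = cent, weights = wts,
       priors = cw / sum(cw), alpha2 = alpha2)
}

os_predict <- function(fit, X) {
  H <- sweep(X, 2, fit$Xmean) %*% fit$V
  K <- nrow(fit$centroids)
  d2 <- sapply(seq_len(K), function(k) {
    dd <- sweep(H, 2, fit$centroids[k, ])
    colSums(t(dd^2) * fit$weights) - 2 * log(fit$priors[k])
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  apply(d2, 1, which.min)
}

#' Flexible discriminant analysis (linear, via optimal scoring)
#'
#' Linear discriminant classification computed through the optimal-scoring
#' route (a linear regression of scored class indicators, equivalent to
#' canonical LDA). The headline accuracy is the resubstitution correct
#' classification rate; leave-one-out cross-validation is available as an
#' option.
#'
#' @param data data.frame holding predictors and the class column.
#' @param predictors character vector of predictor column names (at most 3,
#'   mirroring the discriminant protocol's limit).
#' @param class name of the class column (>= 2 levels, each with >= 2 rows
#'   for resubstitution).
#' @param loo also compute leave-one-out accuracy?
#' @return list of class `fda_result`: `predicted`, `accuracy`, `confusion`,
#'   `loo_accuracy` (if requested), `levels`, `fit`.
#' @export
fda_classify <- function(data, predictors, class, loo = FALSE) {
  if (length(predictors) > 3L) stop("at most 3 predictor metrics are allowed")
  stopifnot(all(predictors %in% names(data)), class %in% names(data))
  y <- factor(data[[class]])
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  X <- as.matrix(data[, predictors, drop = FALSE])
  Y <- stats::model.matrix(~ y - 1)
  fit <- optimal_scoring_fit(X, Y)
  pred <- os_predict(fit, X)
  predicted <- factor(levels(y)[pred], levels = levels(y))
  confusion <- table(truth = y, predicted = predicted)
  out <- list(predicted = predicted,
              accuracy = mean(predicted == y),
              confusion = confusion,
              levels = levels(y),
              fit = fit)
  if (loo) {
    hits <- vapply(seq_len(nrow(X)), function(i) {
      f <- optimal_scoring_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE])
      levels(y)[os_predict(f, X[i, , drop = FALSE])] == as.character(y[i])
    }, logical(1))
    out$loo_accuracy <- mean(hits)
  }
  class(out) <- "fda_result"
  out
}

#' @export
print.fda_result <- function(x, ...) {
  cat(sprintf("<fda_result> accuracy %.3f over %d observations\n",
              x$accuracy, length(x$predicted)))
  print(x$confusion)
  invisible(x)
}

#' Lambda-scaled Brownian covariance
#'
#' Pagel's lambda transform: off-diagonal entries of the Brownian covariance
#' are multiplied by lambda, diagonals kept.
#'
#' @param C Brownian covariance matrix.
#' @param lambda scalar in \[0, 1\].
#' @return transformed matrix.
#' @export
lambda_cov <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Estimate Pagel's lambda for a predictor block
#'
#' Maximizes the summed per-trait profile log-likelihood of a Brownian model
#' with lambda-scaled covariance over a coarse grid followed by golden-section
#' refinement in the bracketing interval. Traits are treated as independent
#' given the tree (each with its own rate and root state).
#'
#' @param X numeric matrix, one row per species (rownames = species).
#' @param tree `phylo` containing those species.
#' @param grid lambda grid for the coarse pass.
#' @return list: `lambda`, `loglik`, `grid_loglik`.
#' @export
estimate_lambda <- function(X, tree, grid = seq(0, 1, by = 0.1)) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("X must have species rownames")
  C <- brownian_cov(tree, rownames(X))
  n <- nrow(X)
  ll_one <- function(V, x) {
    eg <- eigen(V, symmetric = TRUE)
    if (min(eg$values) <= 0) return(-Inf)
    Vi <- eg$vectors %*% diag(1 / eg$values) %*% t(eg$vectors)
    ldet <- sum(log(eg$values))
    one <- rep(1, n)
    a <- as.numeric(t(one) %*% Vi %*% x) / as.numeric(t(one) %*% Vi %*% one)
    r <- x - a
    s2 <- as.numeric(t(r) %*% Vi %*% r) / n
    s2 <- max(s2, 1e-12)
    -0.5 * (n * log(2 * pi * s2) + ldet + n)
  }
  ll <- function(lambda) {
    V <- lambda_cov(C, lambda)
    sum(apply(X, 2, function(x) ll_one(V, x)))
  }
  gl <- vapply(grid, ll, numeric(1))
  i <- which.max(gl)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE)
  best <- if (opt$objective >= max(gl)) {
    list(lambda = opt$maximum, loglik = opt$objective)
  } else {
    list(lambda = grid[i], loglik = gl[i])
  }
  c(best, list(grid_loglik = stats::setNames(gl, grid)))
}

#' Inverse matrix square root with an eigenvalue floor.
#' @noRd
inv_sqrt_psd <- function(C, floor = 1e-10) {
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, floor)
  eg$vectors %*% diag(1 / sqrt(ev)) %*% t(eg$vectors)
}

#' Phylogenetic flexible discriminant analysis
#'
#' Whitens the predictors and the class indicator matrix by the inverse
#' square root of the lambda-scaled Brownian covariance, then fits the
#' optimal-scoring discriminant on the transformed data and classifies the
#' (transformed) training rows. With lambda = 0 on an ultrametric tree this
#' reduces exactly to [fda_classify()]. Expects one row per species
#' (species means).
#'
#' @param data data.frame with a `species` column, predictors and the class
#'   column; one row per species.
#' @param predictors,class as in [fda_classify()].
#' @param tree `phylo` containing the species.
#' @param lambda fixed lambda; `NULL` estimates it via [estimate_lambda()].
#' @return list of class `fda_result` with `lambda` recorded.
#' @export
pfda_classify <- function(data, predictors, class, tree, lambda = NULL) {
  if (length(predictors) > 3L) stop("at most 3 predictor metrics are allowed")
  stopifnot("species" %in% names(data))
  if (anyDuplicated(data$species)) {
    stop("one row per species required (use species means)")
  }
  y <- factor(data[[class]])
  X <- as.matrix(data[, predictors, drop = FALSE])
  rownames(X) <- data$species
  C <- brownian_cov(tree, data$species)
  if (is.null(lambda)) lambda <- estimate_lambda(X, tree)$lambda
  W <- inv_sqrt_psd(lambda_cov(C, lambda))
  Xw <- W %*% X
  Y <- stats::model.matrix(~ y - 1)
  Yw <- W %*% Y
  fit <- optimal_scoring_fit(Xw, Yw)
  pred <- os_predict(fit, Xw)
  predicted <- factor(levels(y)[pred], levels = levels(y))
  confusion <- table(truth = y, predicted = predicted)
  structure(list(predicted = predicted,
                 accuracy = mean(predicted == y),
                 confusion = confusion,
                 levels = levels(y),
                 lambda = lambda,
                 fit = fit),
            class = "fda_result")
}
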