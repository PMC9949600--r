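#' Standardized major axis slope
#'
#' `sign(r) * sd(y) / sd(x)` on (already transformed) data.
#'
#' @param x,y numeric vectors.
#' @return the SMA slope.
#' @export
sma_slope <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance in a group")
  s <- stats::sd(y) / stats::sd(x)
  r <- stats::cor(x, y)
  if (r < 0) -s else s
}

## Profile (over the free correlation and scale) of -2/n * log-likelihood of a
## centred bivariate normal constrained so its SMA slope equals b:
## Sigma = s^2 * [[1, rho*b], [rho*b, b^2]]. After profiling the scale the
## objective in rho has a closed-form stationary point (quadratic).
sma_profile_dev <- function(Sxx, Syy, Sxy, b) {
  A0 <- Sxx + Syy / b^2
  cc <- 2 * Sxy / b
  rho <- cc / A0   # stationary point of the profiled deviance; |rho| < 1 by AM-GM
  -log1p(-rho^2) + 2 * log(A0 - rho * cc) + log(b^2) - 2 * log(2)
}

## Unconstrained deviance contribution: log|S_ml| for the centred sample
## second-moment matrix (its SMA slope is the per-group estimate).
sma_free_dev <- function(Sxx, Syy, Sxy) {
  log(max(Sxx * Syy - Sxy^2, 1e-300))
}

#' Likelihood-ratio test for a common standardized major axis slope
#'
#' Tests whether several groups share one SMA slope. Each group is modelled
#' as a centred bivariate normal; constraining the SMA slope (sd(y)/sd(x)
#' with the correlation's sign) to a common value b leaves the correlation
#' and scale free, and profiling them gives a closed-form per-group deviance.
#' The common slope is the 1D minimizer of the summed profile deviance, and
#' the likelihood-ratio statistic is compared to a chi-squared distribution
#' with (groups - 1) degrees of freedom.
#'
#' @param groups named list; each element a list/data.frame with components
#'   `x` and `y` (already log-transformed as appropriate).
#' @param alpha significance level for the verdict.
#' @return list of class `sma_common_slope`: `slopes` (per group),
#'   `common_slope`, `lr`, `df`, `p_value`, `verdict`.
#' @export
sma_common_slope_test <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  stats_g <- lapply(groups, function(g) {
    x <- g$x; y <- g$y
    if (length(x) < 3L) stop("each group needs n >= 3")
    if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance in a group")
    n <- length(x)
    xc <- x - mean(x); yc <- y - mean(y)
    list(n = n, Sxx = mean(xc^2), Syy = mean(yc^2), Sxy = mean(xc * yc),
         slope = sma_slope(x, y))
  })
  slopes <- vapply(stats_g, `[[`, numeric(1), "slope")
  if (!(all(slopes > 0) || all(slopes < 0))) {
    warning("group SMA slopes differ in sign; common-slope model is strained")
  }
  sgn <- sign(stats_g[[1]]$slope)
  dev_at <- function(babs) {
    b <- sgn * babs
    sum(vapply(stats_g, function(s) {
      s$n * sma_profile_dev(s$Sxx, s$Syy, s$Sxy, b)
    }, numeric(1)))
  }
  babs <- abs(slopes)
  lo <- min(babs) / 2; hi <- max(babs) * 2
  opt <- stats::optimize(dev_at, c(lo, hi))
  free <- sum(vapply(stats_g, function(s) {
    s$n * (sma_free_dev(s$Sxx, s$Syy, s$Sxy))
  }, numeric(1)))
  lr <- max(0, opt$objective - free)
  df <- length(groups) - 1L
  p <- stats::pchisq(lr, df, lower.tail = FALSE)
  structure(list(slopes = slopes, common_slope = sgn * opt$minimum,
                 lr = lr, df = df, p_value = p,
                 verdict = if (p < alpha) "not equal" else "equal"),
            class = "sma_common_slope")
}

#' @export
print.sma_common_slope <- function(x, ...) {
  cat(sprintf("<sma_common_slope> LR = %.3f (df %d), p = %.3g: slopes are %s\n",
              x$lr, x$df, x$p_value, x$verdict))
  cat("  group slopes:", paste(sprintf("%.3f", x$slopes), collapse = ", "), "\n")
  invisible(x)
}
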