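#' Built-in metric specifications with isometric expectations
#'
#' Isometric slopes against a linear body-size proxy follow dimensional
#' analysis: ratios (BV.TV, GC, DA) are dimensionless (slope 0), trabecular
#' number is per-length (-1), trabecular thickness is a length (1),
#' cross-sectional area scales as length squared (2), connectivity density is
#' per-volume (-3), and body mass as length cubed (3).
#'
#' @return data.frame: `metric`, `units`, `isometric_slope`.
#' @export
metric_specs <- function() {
  data.frame(
    metric = c("bv_tv", "gc", "da", "tb_n", "tb_th", "csa", "conn_d", "mass"),
    units = c("", "", "", "1/mm", "mm", "mm^2", "1/mm^3", "g"),
    isometric_slope = c(0, 0, 0, -1, 1, 2, -3, 3),
    stringsAsFactors = FALSE
  )
}

#' Log-log least-squares regression
#'
#' Ordinary least squares on log10-transformed positive data (the iid special
#' case of generalized least squares; see [pgls()] for the phylogenetic
#' error structure). The 95% confidence interval uses the t distribution
#' with n - 2 degrees of freedom; the p-value tests slope = 0 (two-sided).
#'
#' @param x,y positive numeric vectors.
#' @param ci_level confidence level.
#' @return object of class `loglog_fit`: `slope`, `intercept`, `ci_low`,
#'   `ci_high`, `p_value`, `r_squared`, `n`, plus the underlying `lm` fit.
#' @export
fit_loglog <- function(x, y, ci_level = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad) > 0L) {
    stop("nonpositive or missing values at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("x has no variance")
  lx <- log10(x); ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  sm <- summary(fit)
  ci <- stats::confint(fit, "lx", level = ci_level)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci_low = ci[1], ci_high = ci[2],
                 p_value = sm$coefficients["lx", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 n = length(x),
                 ci_level = ci_level,
                 model = "iid",
                 fit = fit),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "<loglog_fit:%s> slope %.3f [%.3f, %.3f], p = %.3g, R^2 = %.3f, n = %d\n",
    x$model, x$slope, x$ci_low, x$ci_high, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Confidence-interval based allometry call
#'
#' A slope is isometric ("0") when the isometric expectation lies inside the
#' confidence interval; otherwise it is positively ("+") or negatively ("-")
#' allometric according to whether the fitted slope lies above or below the
#' expectation.
#'
#' @param result a `loglog_fit` (or any list with `slope`, `ci_low`,
#'   `ci_high`).
#' @param isometric_slope the isometric expectation, or a metric name from
#'   [metric_specs()].
#' @return one of `"+"`, `"-"`, `"0"`.
#' @export
classify_allometry <- function(result, isometric_slope) {
  if (is.character(isometric_slope)) {
    ms <- metric_specs()
    i <- match(isometric_slope, ms$metric)
    if (is.na(i)) stop("unknown metric: ", isometric_slope)
    isometric_slope <- ms$isometric_slope[i]
  }
  if (isometric_slope >= result$ci_low && isometric_slope <= result$ci_high) {
    "0"
  } else if (result$slope > isometric_slope) {
    "+"
  } else {
    "-"
  }
}

#' Select the linear measurement (and vertebral position) that best tracks mass
#'
#' Stage 1 regresses log mass on the log of each candidate measurement,
#' pooling positions, and keeps the measurement with the highest R-squared.
#' Stage 2 repeats per vertebral position for the winning measurement and
#' picks the best position. Ties go to the first candidate in column order
#' (recorded in the result). Rows with missing mass are dropped with a
#' warning.
#'
#' @param data data.frame with columns `mass_g`, `position`, and the
#'   candidate measurement columns.
#' @param candidates character vector of measurement column names.
#' @return list `measurement`, `position`, `r2_by_measurement`,
#'   `r2_by_position`, `tie` (logical).
#' @export
select_body_size_proxy <- function(data, candidates) {
  stopifnot(all(candidates %in% names(data)), "mass_g" %in% names(data))
  drop <- !is.finite(data$mass_g)
  if (any(drop)) {
    warning(sum(drop), " rows dropped: missing mass")
    data <- data[!drop, ]
  }
  r2 <- vapply(candidates, function(m) {
    ok <- is.finite(data[[m]]) & data[[m]] > 0
    fit_loglog(data[[m]][ok], data$mass_g[ok])$r_squared
  }, numeric(1))
  best <- which(r2 == max(r2))
  tie <- length(best) > 1L
  if (tie) message("tie in R^2 between candidates; keeping first in column order")
  winner <- candidates[best[1]]
  positions <- sort(unique(data$position))
  r2p <- vapply(positions, function(p) {
    sub <- data[data$position == p, ]
    fit_loglog(sub[[winner]], sub$mass_g)$r_squared
  }, numeric(1))
  bestp <- which(r2p == max(r2p))
  list(measurement = winner, position = positions[bestp[1]],
       r2_by_measurement = r2, r2_by_position = r2p, tie = tie)
}

#' Species means by vertebral position
#'
#' Arithmetic means of each (raw-scale) numeric metric per species x
#' position; downstream log transforms are applied to the means. Mean-then-
#' log and log-then-mean differ on skewed data, so the choice is explicit
#' and switchable.
#'
#' @param data data.frame with `species` and `position` columns.
#' @param metrics columns to average; default all numeric columns.
#' @param log_first average on the log scale instead (geometric means).
#' @return data.frame of species x position means, carrying over `clade`,
#'   `ecology` and `size_class` when present.
#' @export
species_means <- function(data, metrics = NULL, log_first = FALSE) {
  stopifnot(all(c("species", "position") %in% names(data)))
  if (is.null(metrics)) {
    metrics <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  keys <- unique(data[, c("species", "position")])
  rownames(keys) <- NULL
  for (m in metrics) {
    keys[[m]] <- mapply(function(s, p) {
      v <- data[[m]][data$species == s & data$position == p]
      if (log_first) 10^mean(log10(v)) else mean(v)
    }, keys$species, keys$position)
  }
  for (extra in c("clade", "ecology", "size_class")) {
    if (extra %in% names(data)) {
      keys[[extra]] <- data[[extra]][match(keys$species, data$species)]
    }
  }
  keys
}
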