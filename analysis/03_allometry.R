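#!/usr/bin/env Rscript

# Stage 3: body-size proxy selection and allometric regressions.
#
# Reads the simulated comparative table (stage 1; regenerated if absent),
# picks the linear measurement that best tracks body mass, fits the
# whole-dataset log10-log10 regressions for all seven microstructure metrics
# plus mass, classifies each slope against its isometric expectation, and
# runs the per-clade / per-ecology fits with common-slope tests.

suppressPackageStartupMessages(library(trabcomp))
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/simulated_clade.csv")) {
  source("analysis/01_simulate_clade.R")
}
dat <- read.csv("results/simulated_clade.csv", check.names = FALSE)

proxy <- select_body_size_proxy(
  dat, c("izl_mm", "ch_mm", "cl_mm", "cw_mm", "th_mm", "tw_mm", "zw_mm"))
cat(sprintf("body-size proxy: %s (best position %s, R^2 = %.3f)\n",
            proxy$measurement, proxy$position, max(proxy$r2_by_position)))

ms <- metric_specs()
iso <- setNames(ms$isometric_slope, ms$metric)
metrics <- c("bv_tv", "tb_n", "tb_th", "gc", "csa", "da", "conn_d", "mass")
whole <- do.call(rbind, lapply(metrics, function(m) {
  y <- if (m == "mass") dat$mass_g else dat[[m]]
  f <- fit_loglog(dat$izl_mm, y)
  data.frame(metric = m, isometric = iso[[m]], slope = f$slope,
             ci_low = f$ci_low, ci_high = f$ci_high,
             allometry = classify_allometry(f, iso[[m]]),
             p_value = f$p_value, r_squared = f$r_squared)
}))
write.csv(whole, "results/allometry_whole.csv", row.names = FALSE)
print(whole, digits = 3)

for (grp in c("clade", "ecology")) {
  tab <- do.call(rbind, lapply(setdiff(metrics, "mass"), function(m) {
    groups <- split(dat, dat[[grp]])
    sma <- suppressWarnings(sma_common_slope_test(
      lapply(groups, function(g) list(x = log10(g$izl_mm), y = log10(g[[m]])))))
    do.call(rbind, lapply(names(groups), function(g) {
      f <- fit_loglog(groups[[g]]$izl_mm, groups[[g]][[m]])
      data.frame(metric = m, group = g, slope = f$slope,
                 r_squared = f$r_squared, p_value = f$p_value,
                 allometry = classify_allometry(f, iso[[m]]),
                 equality = paste("Slopes are", sma$verdict),
                 equality_p = sma$p_value)
    }))
  }))
  out <- sprintf("results/allometry_by_%s.csv", grp)
  write.csv(tab, out, row.names = FALSE)
  cat("wrote", out, "\n")
}
cat(sprintf("%d of %d whole-dataset slopes depart from isometry\n",
            sum(whole$allometry != "0"), nrow(whole)))
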