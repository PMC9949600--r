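#!/usr/bin/env Rscript

# Stage 5: classify size class and ecology from the microstructure metrics.
#
# Per vertebral position, species means feed flexible discriminant analysis
# (FDA) and its phylogenetic variant (pFDA, lambda estimated per task) for
# the two classification tasks, each with its conventional 3-metric subset:
# size class from the most size-correlated metrics, ecology from the least
# size-correlated ones. Because ecology and clade are almost perfectly
# confounded in the design, pFDA is expected to be no more accurate than FDA.

suppressPackageStartupMessages(library(trabcomp))
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/simulated_clade.csv")) {
  source("analysis/01_simulate_clade.R")
}
dat <- read.csv("results/simulated_clade.csv", check.names = FALSE)
tree <- ape::read.tree("results/simulated_clade_tree.nwk")

sm <- species_means(dat)
sm$size_class <- study_design()$size_class[
  match(sm$species, study_design()$species)]
subsets <- list(size_class = c("tb_th", "csa", "conn_d"),
                ecology = c("bv_tv", "gc", "da"))
positions <- sort(unique(sm$position))

tab <- do.call(rbind, lapply(names(subsets), function(task) {
  per <- do.call(rbind, lapply(positions, function(p) {
    sub <- sm[sm$position == p, ]
    f <- fda_classify(sub, subsets[[task]], task)
    pf <- pfda_classify(sub, subsets[[task]], task, tree)
    data.frame(group = task, position = p, fda = f$accuracy,
               pfda = pf$accuracy, lambda = pf$lambda)
  }))
  rbind(per, data.frame(group = task, position = "All positions",
                        fda = mean(per$fda), pfda = mean(per$pfda),
                        lambda = NA))
}))
write.csv(tab, "results/discriminant_accuracy.csv", row.names = FALSE)
print(tab, digits = 3)
all_rows <- tab[tab$position == "All positions", ]
cat(sprintf("mean accuracy -- size class: FDA %.2f vs pFDA %.2f; ecology: FDA %.2f vs pFDA %.2f\n",
            all_rows$fda[1], all_rows$pfda[1], all_rows$fda[2], all_rows$pfda[2]))
cat("wrote results/discriminant_accuracy.csv\n")
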