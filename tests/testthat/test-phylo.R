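# Brownian covariance, PGLS, Blomberg's K, position averaging.

test_that("Brownian covariance reproduces hand-computed path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- brownian_cov(tr)
  expect_identical(C["A", "B"], 1)
  expect_identical(C["A", "A"], 2)
  expect_identical(C["A", "C"], 0)
  ev <- eigen(C, symmetric = TRUE)$values
  expect_true(all(ev >= -1e-12))
  # star tree: b * identity
  st <- ape::stree(5, "star"); st$edge.length <- rep(2.5, 5)
  Cs <- brownian_cov(st)
  expect_equal(unname(Cs), diag(2.5, 5))
  expect_error(brownian_cov(ape::read.tree(text = "((A:0,B:0):0,C:0);")),
               "zero-depth")
})

test_that("PGLS reduces to OLS under identity covariance", {
  set.seed(6)
  n <- 12
  x <- setNames(exp(rnorm(n, 2, 0.6)), paste0("s", 1:n))
  y <- setNames(x^0.8 * exp(rnorm(n, 0, 0.2)), names(x))
  p <- pgls(x, y, diag(n))
  o <- fit_loglog(x, y)
  expect_within(p$slope, o$slope, 1e-10)
  expect_within(p$intercept, o$intercept, 1e-10)
  expect_within(p$ci_low, o$ci_low, 1e-10)
  expect_within(p$p_value, o$p_value, 1e-10)
  expect_within(p$r_squared, o$r_squared, 1e-10)
})

test_that("PGLS matches hand matrix algebra on a 3-taxon tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- brownian_cov(tr)
  x <- setNames(c(10, 14, 20), c("A", "B", "C"))
  y <- setNames(c(3, 4, 6), c("A", "B", "C"))
  p <- pgls(x, y, C)
  X <- cbind(1, log10(x)); Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% log10(y))
  expect_within(p$slope, beta[2], 1e-12)
  expect_within(p$intercept, beta[1], 1e-12)
})

test_that("PGLS agrees with the reference GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(8)
  tr <- synthetic_tree()
  C <- brownian_cov(tr)
  sp <- rownames(C)
  x <- setNames(exp(rnorm(length(sp), 2, 0.5)), sp)
  y <- setNames(x^0.7 * exp(rnorm(length(sp), 0, 0.2)), sp)
  p <- pgls(x, y, C)
  d <- data.frame(lx = log10(x), ly = log10(y), sp = sp)
  g <- nlme::gls(ly ~ lx, data = d,
                 correlation = ape::corBrownian(1, phy = tr, form = ~sp))
  expect_within(p$slope, unname(coef(g)[2]), 1e-8)
  expect_within(p$p_value, summary(g)$tTable[2, 4], 1e-8)
})

test_that("PGLS recovers a Brownian generating slope on average", {
  tr <- synthetic_tree()
  C <- brownian_cov(tr)
  sp <- rownames(C)
  est <- vapply(1:200, function(s) {
    trabcomp:::with_local_seed(1000 + s, {
      lx <- rnorm(length(sp), 1, 0.4)
      dev <- t(chol(C / mean(diag(C)))) %*% rnorm(length(sp)) * 0.1
      ly <- 0.74 * lx + as.vector(dev)
      pgls(setNames(10^lx, sp), setNames(10^ly, sp), C)$slope
    })
  }, numeric(1))
  expect_within(mean(est), 0.74, 0.05)
})

test_that("PGLS on simulated clades with Brownian deviations keeps coverage", {
  mod <- default_generating_model()
  picks <- c("tb_th", "conn_d")
  hits <- matrix(FALSE, 100, length(picks))
  for (s in 1:100) {
    sim <- simulate_clade(clade_sim_spec(bm_share = 0.1, seed = 300 + s))
    smn <- species_means(sim$data)
    C <- brownian_cov(sim$tree)
    for (j in seq_along(picks)) {
      agg <- aggregate(smn[, c("izl_mm", picks[j])],
                       by = list(species = smn$species), mean)
      x <- setNames(agg$izl_mm, agg$species)
      y <- setNames(agg[[picks[j]]], agg$species)
      f <- pgls(x, y, C[names(x), names(x)])
      e <- mod$exponent[match(picks[j], mod$metric)]
      hits[s, j] <- e >= f$ci_low && e <= f$ci_high
    }
  }
  expect_true(all(colSums(hits) >= 90))
})

test_that("Blomberg's K matches the reference implementation and is invariant", {
  skip_if_not_installed("phytools")
  tr <- synthetic_tree()
  tv <- trabcomp:::with_local_seed(21, {
    C <- brownian_cov(tr)
    setNames(as.vector(t(chol(C)) %*% rnorm(nrow(C))), rownames(C))
  })
  ours <- blomberg_k(tv, tr, n_perm = 199, seed = 5)
  ref <- phytools::phylosig(tr, tv, method = "K")
  expect_within(ours$K, as.numeric(ref), 1e-8)
  # scaling/shifting the trait leaves K and the permutation p unchanged
  scaled <- blomberg_k(3 * tv + 7, tr, n_perm = 199, seed = 5)
  expect_within(scaled$K, ours$K, 1e-10)
  expect_identical(scaled$p_value, ours$p_value)
  # fixed seed: identical p
  again <- blomberg_k(tv, tr, n_perm = 199, seed = 5)
  expect_identical(again$p_value, ours$p_value)
  expect_error(blomberg_k(setNames(rep(1, 10), tr$tip.label), tr), "constant")
})

test_that("K centres on 1 under Brownian motion and drops for iid noise", {
  tr <- synthetic_tree()
  C <- brownian_cov(tr)
  ks <- vapply(1:500, function(s) {
    trabcomp:::with_local_seed(2000 + s, {
      tv <- setNames(as.vector(t(chol(C)) %*% rnorm(nrow(C))), rownames(C))
      blomberg_k(tv, tr, n_perm = 2, seed = 1)$K
    })
  }, numeric(1))
  expect_gte(mean(ks), 0.85)
  expect_lte(mean(ks), 1.15)
  iid <- vapply(1:100, function(s) {
    trabcomp:::with_local_seed(5000 + s, {
      tv <- setNames(rnorm(nrow(C)), rownames(C))
      res <- blomberg_k(tv, tr, n_perm = 99, seed = 1)
      c(res$K, res$p_value)
    })
  }, numeric(2))
  expect_lt(mean(iid[1, ]), 0.6)
  expect_gt(mean(iid[2, ] > 0.05), 0.5)
})

test_that("position averaging reports means and ranges", {
  mk <- function(s) list(slope = s, ci_low = s - 0.1, ci_high = s + 0.1,
                         p_value = 0.01)
  avg <- average_over_positions(list(mk(0.69), mk(0.77)))
  expect_within(avg$slope, 0.73, 1e-12)
  expect_identical(avg$slope_range, c(0.69, 0.77))
  expect_identical(avg$label, "0.73 (0.69-0.77)")
  one <- average_over_positions(list(mk(0.5)))
  expect_identical(one$slope, 0.5)
  expect_error(average_over_positions(list()), "no position")
})
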