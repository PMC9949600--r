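# FDA via optimal scoring and the phylogenetic variant.

test_that("well-separated classes are classified perfectly", {
  set.seed(10)
  d <- data.frame(
    p1 = c(rnorm(12, 0), rnorm(12, 10)),   # 10 within-class sd apart
    p2 = rnorm(24),
    cls = rep(c("a", "b"), each = 12))
  f <- fda_classify(d, c("p1", "p2"), "cls")
  expect_identical(f$accuracy, 1)
  expect_identical(sum(f$confusion), 24L)
  expect_identical(unname(rowSums(f$confusion)), c(12, 12))
})

test_that("optimal scoring agrees with the canonical LDA reference", {
  skip_if_not_installed("MASS")
  set.seed(11)
  n <- c(15, 25, 10)
  X <- rbind(matrix(rnorm(n[1] * 3), ncol = 3),
             sweep(matrix(rnorm(n[2] * 3), ncol = 3), 2, c(2, 0, 1), `+`),
             sweep(matrix(rnorm(n[3] * 3), ncol = 3), 2, c(0, 3, -1), `+`))
  d <- data.frame(X, cls = rep(c("a", "b", "c"), n))
  f <- fda_classify(d, c("X1", "X2", "X3"), "cls")
  ref <- predict(MASS::lda(X, d$cls))$class
  expect_identical(as.character(f$predicted), as.character(ref))
  # affine rescaling of a predictor does not change predictions
  d2 <- d; d2$X2 <- d2$X2 * 50 - 3
  f2 <- fda_classify(d2, c("X1", "X2", "X3"), "cls")
  expect_identical(f$predicted, f2$predicted)
  # duplicating every row leaves the discriminant unchanged
  f3 <- fda_classify(rbind(d, d), c("X1", "X2", "X3"), "cls")
  expect_identical(f3$predicted[seq_len(nrow(d))], f$predicted)
})

test_that("permuted labels classify at chance", {
  # n large enough that the resubstitution optimism (order p*K/n) is small
  set.seed(12)
  rates <- vapply(1:100, function(i) {
    d <- data.frame(p1 = rnorm(300), p2 = rnorm(300), p3 = rnorm(300),
                    cls = sample(rep(c("a", "b", "c"), 100)))
    fda_classify(d, c("p1", "p2", "p3"), "cls")$accuracy
  }, numeric(1))
  expect_within(mean(rates), 1 / 3, 0.1)
})

test_that("the predictor budget is enforced", {
  d <- data.frame(a = 1:6, b = 1:6, c = 1:6, d = 1:6,
                  cls = rep(c("x", "y"), 3))
  expect_error(fda_classify(d, c("a", "b", "c", "d"), "cls"), "3 predictor")
})

test_that("lambda estimation separates Brownian from iid predictors", {
  tr <- synthetic_tree()
  C <- brownian_cov(tr)
  lam_bm <- vapply(1:40, function(s) {
    trabcomp:::with_local_seed(s, {
      M <- sapply(1:3, function(j)
        as.vector(t(chol(C)) %*% rnorm(nrow(C))))
      rownames(M) <- rownames(C)
      estimate_lambda(M, tr)$lambda
    })
  }, numeric(1))
  lam_iid <- vapply(1:40, function(s) {
    trabcomp:::with_local_seed(100 + s, {
      M <- matrix(rnorm(3 * nrow(C)), nrow(C))
      rownames(M) <- rownames(C)
      estimate_lambda(M, tr)$lambda
    })
  }, numeric(1))
  expect_gt(mean(lam_bm > 0.8), 0.5)
  expect_lt(mean(lam_iid), 0.2)
  # refinement never loses to the endpoint-only grid
  M <- matrix(rnorm(30), 10); rownames(M) <- rownames(C)
  fine <- estimate_lambda(M, tr)
  coarse <- estimate_lambda(M, tr, grid = c(0, 1))
  expect_gte(fine$loglik, max(coarse$grid_loglik) - 1e-9)
})

test_that("pFDA reduces to FDA for lambda 0 and star trees", {
  set.seed(13)
  tr <- synthetic_tree()
  d <- data.frame(species = tr$tip.label,
                  p1 = rnorm(10), p2 = rnorm(10),
                  cls = rep(c("u", "v"), 5))
  f <- fda_classify(d, c("p1", "p2"), "cls")
  pf0 <- pfda_classify(d, c("p1", "p2"), "cls", tr, lambda = 0)
  expect_identical(pf0$predicted, f$predicted)
  st <- ape::stree(10, "star"); st$edge.length <- rep(3, 10)
  st$tip.label <- d$species
  pfs <- pfda_classify(d, c("p1", "p2"), "cls", st, lambda = 1)
  expect_identical(pfs$predicted, f$predicted)
  expect_identical(pfs$accuracy, f$accuracy)
  # separable classes stay perfect under any lambda
  d$p1 <- ifelse(d$cls == "u", 0, 25) + rnorm(10, 0, 0.5)
  for (lam in c(0, 0.5, 1)) {
    expect_identical(
      pfda_classify(d, c("p1", "p2"), "cls", tr, lambda = lam)$accuracy, 1)
  }
})

test_that("pFDA is no more accurate than FDA on the confounded clade", {
  # ecology aligns with clade by construction; averaging over simulated
  # datasets, whitening by the phylogeny removes ecological covariance
  des <- study_design()
  mod <- default_generating_model()
  var_x <- stats::var(log10(rep(des$mass_g, des$n_specimens)^(1 / 3)))
  offs <- trabcomp:::default_ecology_offsets(mod, 0.5, var_x)
  acc <- vapply(1:30, function(s) {
    sim <- simulate_clade(clade_sim_spec(bm_share = 0.1,
                                         ecology_offsets = offs, seed = s))
    smn <- species_means(sim$data)
    sub <- smn[smn$position == "ps1", ]
    f <- fda_classify(sub, c("bv_tv", "gc", "da"), "ecology")
    pf <- pfda_classify(sub, c("bv_tv", "gc", "da"), "ecology", sim$tree)
    c(f$accuracy, pf$accuracy)
  }, numeric(2))
  expect_lte(mean(acc[2, ]), mean(acc[1, ]) + 1e-9)
})
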