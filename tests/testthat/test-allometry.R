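# Log-log regression, allometry calls, proxy selection, species means.

test_that("isometric expectations follow dimensional analysis", {
  ms <- metric_specs()
  iso <- setNames(ms$isometric_slope, ms$metric)
  expect_identical(iso[["bv_tv"]], 0)
  expect_identical(iso[["gc"]], 0)
  expect_identical(iso[["da"]], 0)
  expect_identical(iso[["tb_n"]], -1)
  expect_identical(iso[["tb_th"]], 1)
  expect_identical(iso[["csa"]], 2)
  expect_identical(iso[["conn_d"]], -3)
  expect_identical(iso[["mass"]], 3)
})

test_that("exact power laws are fit exactly and errors are informative", {
  x <- c(1, 2, 4, 8, 16, 32)
  f <- suppressWarnings(fit_loglog(x, 2 * x^0.66))
  expect_within(f$slope, 0.66, 1e-10)
  expect_within(f$r_squared, 1, 1e-10)
  expect_within(f$intercept, log10(2), 1e-10)
  expect_error(fit_loglog(rep(2, 5), 1:5), "variance")
  expect_error(fit_loglog(c(1, 2, -3), c(1, 2, 3)), "rows")
  expect_error(fit_loglog(1:2, 1:2), "at least 3")
})

test_that("slope is invariant to positive rescaling of either axis", {
  set.seed(2)
  x <- runif(30, 1, 100)
  y <- 3 * x^1.4 * exp(rnorm(30, 0, 0.1))
  f1 <- fit_loglog(x, y)
  f2 <- fit_loglog(17 * x, 0.01 * y)
  expect_within(f2$slope, f1$slope, 1e-12)
  expect_within(f2$r_squared, f1$r_squared, 1e-12)
})

test_that("allometry calls reproduce the reference regression table", {
  # printed slope / CI / isometric-expectation triples with known calls
  rows <- list(
    list(s = 0.33, lo = 0.23, hi = 0.42, iso = 0, call = "+"),    # BV.TV
    list(s = -0.28, lo = -0.44, hi = -0.31, iso = -1, call = "+"), # Tb.N
    list(s = 0.66, lo = 0.60, hi = 0.72, iso = 1, call = "-"),    # Tb.Th
    list(s = 0.14, lo = 0.11, hi = 0.17, iso = 0, call = "+"),    # GC
    list(s = 1.84, lo = 1.74, hi = 1.95, iso = 2, call = "-"),    # CSA
    list(s = 0.04, lo = -0.01, hi = 0.10, iso = 0, call = "0"),   # DA
    list(s = -1.35, lo = -1.51, hi = -1.20, iso = -3, call = "+"),# Conn.D
    list(s = 3.20, lo = 3.12, hi = 3.29, iso = 3, call = "+")     # mass
  )
  for (r in rows) {
    res <- list(slope = r$s, ci_low = r$lo, ci_high = r$hi)
    expect_identical(classify_allometry(res, r$iso), r$call)
  }
  expect_identical(
    classify_allometry(list(slope = 0.66, ci_low = 0.6, ci_high = 0.72),
                       "tb_th"), "-")
})

test_that("simulated thickness data covers its generating exponent", {
  mod <- default_generating_model()
  j <- match("tb_th", mod$metric)
  hits <- vapply(1:100, function(s) {
    d <- simulate_clade(clade_sim_spec(seed = s))$data
    f <- fit_loglog(d$izl_mm, d$tb_th)
    mod$exponent[j] >= f$ci_low && mod$exponent[j] <= f$ci_high
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("body-size proxy selection picks the cleanest measurement", {
  set.seed(5)
  n <- 60
  d <- data.frame(mass_g = runif(n, 100, 40000),
                  position = rep(paste0("ps", 1:6), each = 10))
  d$izl_mm <- d$mass_g^(1 / 3) * exp(rnorm(n, 0, 0.001))  # near-exact
  d$cw_mm <- d$mass_g^(1 / 3) * exp(rnorm(n, 0, 0.2))
  d$th_mm <- d$mass_g^(1 / 3) * exp(rnorm(n, 0, 0.3))
  pr <- suppressWarnings(select_body_size_proxy(d, c("izl_mm", "cw_mm", "th_mm")))
  expect_identical(pr$measurement, "izl_mm")
  expect_true(all(pr$r2_by_measurement[-1] < pr$r2_by_measurement[1]))
  # missing masses are dropped with a warning
  d2 <- d; d2$mass_g[1:3] <- NA
  expect_warning(select_body_size_proxy(d2, c("izl_mm", "cw_mm")), "missing mass")
  # simulator default: izl wins and tracks the design R^2
  sim <- simulate_clade(clade_sim_spec(seed = 3))$data
  pr2 <- select_body_size_proxy(
    sim, c("izl_mm", "ch_mm", "cl_mm", "cw_mm", "th_mm", "tw_mm", "zw_mm"))
  expect_identical(pr2$measurement, "izl_mm")
  expect_gt(max(pr2$r2_by_measurement), 0.95)
})

test_that("species means average raw values and keep grouping columns", {
  d <- data.frame(species = rep(c("a", "b"), each = 4),
                  position = rep(c("ps1", "ps2"), 4),
                  clade = rep(c("X", "Y"), each = 4),
                  val = c(1, 2, 3, 4, 10, 20, 30, 40))
  sm <- species_means(d, metrics = "val")
  expect_identical(nrow(sm), 4L)
  expect_identical(sm$val[sm$species == "a" & sm$position == "ps1"], 2)
  expect_identical(sm$clade[sm$species == "b"][1], "Y")
  # single specimen per species x position: identity
  d1 <- d[c(1, 2, 5, 6), ]
  sm1 <- species_means(d1, metrics = "val")
  expect_identical(sort(sm1$val), sort(d1$val))
  # mean-then-log vs log-then-mean differ on skewed pairs (Jensen)
  skew <- data.frame(species = "a", position = "ps1", val = c(1, 100))
  m_raw <- species_means(skew, metrics = "val")$val
  m_log <- species_means(skew, metrics = "val", log_first = TRUE)$val
  expect_gt(m_raw, m_log)
})
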