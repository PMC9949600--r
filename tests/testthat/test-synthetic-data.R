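# Phantom generators: ground truth, invariants, determinism.

test_that("degenerate lattice specs are rejected", {
  expect_error(lattice_spec(0.5, 0, 2, 10), "positive")
  expect_error(lattice_spec(0.5, 0.05, 0, 10), "positive")
  expect_error(lattice_spec(0.5, 0.3, 2, 10), "overlap")
  expect_error(lattice_spec(0.5, 0.05, 0.6, 10), "2 lattice periods")
  expect_error(lattice_spec(0.5, 0.05, 2, 80), "voxel")
})

test_that("rod lattice connectivity ground truth is the graph cycle rank", {
  # brute-force oracle: beta1 = E - V + 1 on the k^3 node-strut graph
  cycle_rank_oracle <- function(k) {
    v <- k^3
    e <- 3 * k^2 * (k - 1)
    e - v + 1
  }
  for (k in 2:4) {
    expect_identical(lattice_cycle_rank(k, k, k), as.integer(cycle_rank_oracle(k)))
    rl <- lattice_fixture(voxel_size_um = 25, extent = 0.5 * k)
    expect_identical(rl$truth$connectivity, as.integer(cycle_rank_oracle(k)))
  }
})

test_that("rod lattice BV.TV tracks a fine-grid voxel-count oracle", {
  rl <- lattice_fixture(voxel_size_um = 10)   # voxel = radius / 5
  # independent oracle: voxel counting on one lattice cell at 2x resolution
  fine <- lattice_fixture(voxel_size_um = 5)
  expect_within(rl$truth$bv_tv, fine$truth$bv_tv,
                0.02 * max(fine$truth$bv_tv, rl$truth$bv_tv))
  expect_identical(rl$truth$tb_th_um, 100)
  expect_identical(rl$truth$da_expected_order, "isotropic")
})

test_that("plate stack ground truth is analytic", {
  ps <- plate_fixture(20)
  expect_equal(ps$truth$bv_tv, 0.2)
  expect_equal(mean(ps$volume$mask), 0.2, tolerance = 1e-8)
  expect_equal(ps$truth$tb_n_per_mm, 2)
  # slice-counting oracle for the plate period along the normal
  prof <- apply(ps$volume$mask, 3, any)
  runs <- rle(prof)
  expect_identical(sum(runs$values), 3L)       # 3 plates in 1.5 mm
  expect_error(make_plate_stack(0.1, 0.4, 3, 0.4, 20), "period")
})

test_that("plate stacks along different axes are axis permutations", {
  a <- make_plate_stack(0.1, 0.4, 3, 1.5, 25)$volume$mask
  b <- make_plate_stack(0.1, 0.4, 1, 1.5, 25)$volume$mask
  expect_identical(a, aperm(b, c(2, 3, 1)))
})

test_that("synthetic vertebra construction records its waist", {
  sv <- make_synthetic_vertebra(voxel_size_um = 50, waist_fraction = 0.7)
  d <- dim(sv$volume$mask)
  expect_equal(sv$truth$waist_slice, which.min(sv$truth$radius_profile_mm))
  expect_equal(sv$truth$waist_slice, round(d[3] / 2), tolerance = 1)
  expect_error(make_synthetic_vertebra(voxel_size_um = 50,
                                       shell_thickness_mm = 0.01),
               "shell")
  expect_error(make_synthetic_vertebra(voxel_size_um = 50,
                                       arch_inner_radius_mm = 2),
               "nested")
})

test_that("clade simulation is deterministic and honours the design", {
  s1 <- simulate_clade(clade_sim_spec(seed = 7))
  s2 <- simulate_clade(clade_sim_spec(seed = 7))
  expect_identical(s1$data, s2$data)
  des <- study_design()
  expect_identical(nrow(s1$data), sum(des$n_specimens) * 6L)
  # ecology is the fixed species-to-ecology map in every row
  eco <- setNames(des$ecology, des$species)
  expect_identical(s1$data$ecology, unname(eco[s1$data$species]))
  # masses span the design range
  expect_identical(sort(unique(s1$data$mass_g)), sort(des$mass_g))
  expect_error(clade_sim_spec(noise_scale = -1), "sigma")
})

test_that("zero-noise simulation refits the generating exponents exactly", {
  s0 <- simulate_clade(clade_sim_spec(noise_scale = 0, seed = 1))
  mod <- default_generating_model()
  for (j in seq_len(nrow(mod))) {
    f <- suppressWarnings(fit_loglog(s0$data$izl_mm, s0$data[[mod$metric[j]]]))
    expect_within(f$slope, mod$exponent[j], 1e-3)
  }
})

test_that("volume and table generators are byte-stable under a fixed seed", {
  a <- lattice_fixture(25)$volume$mask
  b <- lattice_fixture(25)$volume$mask
  expect_identical(a, b)
})
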