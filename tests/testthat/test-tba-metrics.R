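# Microstructure metrics on phantoms with analytic ground truth.

test_that("bone volume fraction is exact on trivial and plate inputs", {
  d <- c(24L, 24L, 24L)
  all_bone <- binary_volume(array(TRUE, d), 20)
  none <- binary_volume(array(FALSE, d), 20)
  roi <- sphere_roi(c(12.5, 12.5, 12.5), 10)
  expect_identical(bv_tv(all_bone, roi), 1)
  expect_identical(bv_tv(none, roi), 0)
  expect_error(bv_tv(all_bone, sphere_roi(c(200, 200, 200), 2)), "empty")
  ps <- plate_fixture(20)
  expect_within(bv_tv(ps$volume, NULL), 0.2, 1e-6)
  expect_within(bv_tv(ps$volume), 0.2, 0.02)
})

test_that("bv_tv is monotone under bone dilation", {
  rl <- lattice_fixture(25)
  m <- rl$volume$mask
  dil <- m | trabcomp:::shift3(m, 1, 0, 0) | trabcomp:::shift3(m, -1, 0, 0) |
    trabcomp:::shift3(m, 0, 1, 0) | trabcomp:::shift3(m, 0, -1, 0)
  vd <- binary_volume(dil, 25)
  expect_gte(bv_tv(vd), bv_tv(rl$volume))
})

test_that("MIL separates plates from an isotropic lattice", {
  ps <- plate_fixture(20)
  mil_p <- suppressWarnings(mil_analysis(ps$volume, dirs = direction_set(49L)))
  expect_gt(mil_p$da, 3)
  # along the plate normal the intercept length is shortest
  dirs <- mil_p$dirs
  iz <- which.max(abs(dirs[, 3]))
  fin <- which(is.finite(mil_p$mil))
  ix <- fin[which.min(abs(dirs[fin, 3]))]     # most in-plane measurable direction
  expect_lt(mil_p$mil[iz], mil_p$mil[ix])
  rl <- lattice_fixture(20)
  mil_l <- mil_analysis(rl$volume, dirs = direction_set(49L))
  expect_gte(mil_l$da, 1)
  expect_lte(mil_l$da, 1.15)
  expect_true(all(diff(mil_l$eigenvalues) <= 0))
})

test_that("MIL is insensitive to the line-grid spacing on a dense lattice", {
  rl <- make_rod_lattice(lattice_spec(0.4, 0.08, 1.2, 20))
  roi <- trabcomp:::default_roi(rl$volume)
  m1 <- mil_analysis(rl$volume, roi, dirs = direction_set(25L),
                     line_spacing_voxels = 1)
  m2 <- mil_analysis(rl$volume, roi, dirs = direction_set(25L),
                     line_spacing_voxels = 2)
  rel <- abs(m1$mil - m2$mil) / m1$mil
  expect_lt(stats::median(rel, na.rm = TRUE), 0.03)
  expect_within(m2$da, m1$da, 0.1)
})

test_that("DA grows monotonically as one lattice spacing is stretched", {
  das <- vapply(c(0.5, 0.75, 1.0), function(sy) {
    sp <- lattice_spec(c(0.5, sy, 0.5), 0.05, c(1.5, max(1.5, 2 * sy), 1.5), 25)
    rl <- make_rod_lattice(sp)
    roi <- sphere_roi((dim(rl$volume$mask) + 1) / 2, 28)
    mil_analysis(rl$volume, roi, dirs = direction_set(25L))$da
  }, numeric(1))
  expect_true(all(diff(das) > 0))
})

test_that("trabecular number matches the plate period and chord oracle", {
  ps <- plate_fixture(10)
  roi <- trabcomp:::default_roi(ps$volume)
  dirs <- direction_set(49L)
  tn <- tb_n(ps$volume, roi, dirs = dirs, tb_th_mm = 0.1)
  iz <- which.max(dirs[, 3])
  expect_within(tn$per_direction[iz], 2, 0.1)     # 2 per mm +- 5%
  expect_within(tn$plate_model_per_mm, 2, 0.15)
  empty <- binary_volume(array(FALSE, c(16, 16, 16)), 100)
  expect_identical(tb_n(empty, dirs = direction_set(9L))$tb_n_per_mm, 0)
})

test_that("direction-averaged Tb.N agrees with a brute-force ray tracer", {
  rl <- lattice_fixture(25)
  roi <- trabcomp:::default_roi(rl$volume)
  dirs <- direction_set(9L)
  tn <- tb_n(rl$volume, roi, dirs = dirs, tb_th_mm = 0.1)
  # independent oracle: whole-volume rays on a plane grid, floor sampling
  mask <- rl$volume$mask
  d <- dim(mask)
  vmm <- 25 / 1000
  oracle_dir <- function(w) {
    b <- trabcomp:::orthonormal_basis(w)
    og <- expand.grid(a = seq(-max(d), max(d), by = 3),
                      b = seq(-max(d), max(d), by = 3))
    ctr <- (d + 1) / 2
    ts <- seq(-max(d), max(d), by = 0.25)
    cr <- 0; len <- 0
    for (l in seq_len(nrow(og))) {
      px <- floor(ctr[1] + og$a[l] * b$u[1] + og$b[l] * b$v[1] + ts * w[1])
      py <- floor(ctr[2] + og$a[l] * b$u[2] + og$b[l] * b$v[2] + ts * w[2])
      pz <- floor(ctr[3] + og$a[l] * b$u[3] + og$b[l] * b$v[3] + ts * w[3])
      ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
      if (sum(ok) < 2) next
      bl <- mask[cbind(px[ok], py[ok], pz[ok])]
      cr <- cr + sum(diff(bl) != 0)
      len <- len + sum(ok) * 0.25 * vmm
    }
    (cr / 2) / len
  }
  oracle <- mean(vapply(seq_len(nrow(dirs)),
                        function(i) oracle_dir(dirs[i, ]), numeric(1)),
                 na.rm = TRUE)
  expect_within(tn$tb_n_per_mm, oracle, 0.1 * oracle)
})

test_that("star lengths reproduce plate thickness and cap at the ROI", {
  ps <- plate_fixture(20)
  roi <- trabcomp:::default_roi(ps$volume)
  dirs <- direction_set(33L)
  sld <- sld_analysis(ps$volume, roi, n_points = 400, dirs = dirs, seed = 2)
  iz <- which.max(dirs[, 3])
  expect_within(sld$mean_length_mm[iz], 0.1, 0.02)  # plate thickness +- 1 voxel
  ix <- which.min(abs(dirs[, 3]))
  expect_lte(sld$mean_length_mm[ix], 2 * roi$radius * 20 / 1000 + 0.02)
  expect_gt(sld$anisotropy_ratio, 1)
  # determinism under a fixed seed
  sld2 <- sld_analysis(ps$volume, roi, n_points = 400, dirs = dirs, seed = 2)
  expect_identical(sld$mean_length_mm, sld2$mean_length_mm)
  # more points than bone voxels: sample with replacement, warn
  tiny <- binary_volume(array(rep(c(TRUE, FALSE), 500), dim = c(10, 10, 10)), 50)
  expect_warning(sld_analysis(tiny, sphere_roi(c(5, 5, 5), 4.5),
                              n_points = 5000, dirs = direction_set(5L)),
                 "replacement")
})

test_that("local-sphere thickness recovers plate and rod dimensions", {
  ps <- plate_fixture(20)
  th <- tb_th(ps$volume, trabcomp:::default_roi(ps$volume))
  expect_within(th$local_spheres_um, 100, 20)   # +- 1 voxel
  expect_within(th$plate_model_um, 100, 20)
  rl <- lattice_fixture(10, extent = 1.2)       # voxel = radius/5
  th_r <- tb_th(rl$volume, trabcomp:::default_roi(rl$volume))
  expect_within(th_r$local_spheres_um, 100, 15)
})

test_that("thickness is scale consistent across resolutions", {
  # 2x upsampling of the same geometry; widths stay an even voxel count so
  # the center-to-center distance convention is exact at both scales
  p1 <- make_plate_stack(0.1, 0.4, 3, 0.5, 10)$volume
  p2 <- make_plate_stack(0.1, 0.4, 3, 0.5, 5)$volume
  t1 <- tb_th(p1)$local_spheres_um
  t2 <- tb_th(p2)$local_spheres_um
  expect_lt(abs(t1 - t2) / t2, 0.02)
})

test_that("the batch profile assembles all metrics with QC applied", {
  rl <- lattice_fixture(25)
  prof <- tba_profile(rl$volume, dirs = direction_set(25L),
                      sld_dirs = direction_set(9L), n_points = 200, seed = 3)
  expect_identical(nrow(prof), 1L)
  expect_within(prof$bv_tv, bv_tv(rl$volume, trabcomp:::default_roi(rl$volume)),
                1e-12)
  expect_true(prof$da >= 1)
  expect_true(all(c(prof$mil_e1, prof$mil_e2, prof$mil_e3) > 0))
  expect_gte(prof$mil_e1, prof$mil_e3)
  expect_identical(prof$relative_resolution,
                   prof$tb_th_um / rl$volume$voxel_size_um)
  expect_identical(prof$qc_pass,
                   prof$connectivity >= 40 & prof$relative_resolution >= 2.5)
  # profile is reproducible under the same seed
  prof2 <- tba_profile(rl$volume, dirs = direction_set(25L),
                       sld_dirs = direction_set(9L), n_points = 200, seed = 3)
  expect_identical(prof, prof2)
})

test_that("metrics are invariant under axis permutation", {
  rl <- lattice_fixture(25)
  perm <- binary_volume(aperm(rl$volume$mask, c(3, 1, 2)), 25)
  dirs <- direction_set(25L)
  m1 <- mil_analysis(rl$volume, dirs = dirs)
  m2 <- mil_analysis(perm, dirs = dirs)
  expect_within(m2$da, m1$da, 0.03)
  expect_equal(sort(diag(m2$fabric_tensor)), sort(diag(m1$fabric_tensor)),
               tolerance = 0.05)
  expect_identical(bv_tv(perm), bv_tv(rl$volume))
  c1 <- connectivity_density(rl$volume)$connectivity
  c2 <- connectivity_density(perm)$connectivity
  expect_identical(c1, c2)
})
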