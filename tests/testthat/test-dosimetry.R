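# Slab phantom: 50 x-layers of 2 cc each (100 cc), dose linear in x.
slab_phantom <- function() {
  g <- voxel_grid(c(50, 25, 10), 2)
  mask <- structure_mask(g, array(TRUE, g$shape), "slab", "OAR")
  layer_dose <- 0.8 * seq_len(50) # 0.8 .. 40 Gy
  dose <- dose_distribution(g, array(rep(layer_dose, times = 25 * 10), g$shape))
  list(grid = g, mask = mask, dose = dose)
}

test_that("dvh is a step for uniform dose and matches the slab closed form", {
  g <- voxel_grid(c(16, 16, 16), 2)
  m <- centered_sphere(g, 10, "S", "PTV")
  uni <- dose_distribution(g, array(20, g$shape))
  curve <- dvh(m, uni, bin_gy = 0.5)
  expect_equal(curve$volume_cc[curve$dose_gy == 0], volume_cc(m))
  expect_true(all(curve$volume_cc[curve$dose_gy <= 20] == volume_cc(m)))
  expect_true(all(curve$volume_cc[curve$dose_gy > 20] == 0))

  # monotone non-increasing for random dose fields
  set.seed(5)
  rnd <- dose_distribution(g, array(runif(prod(g$shape), 0, 30), g$shape))
  expect_true(all(diff(dvh(m, rnd)$volume_cc) <= 0))

  # linear slab: V(>= d) = (40 - d)/40 * 100 cc within one bin/layer
  sl <- slab_phantom()
  curve <- dvh(sl$mask, sl$dose, bin_gy = 0.1)
  sel <- curve$dose_gy > 0.8 & curve$dose_gy < 39
  expect_equal(curve$volume_cc[sel], (40 - curve$dose_gy[sel]) / 40 * 100,
    tolerance = 2 / 100 * 2 # one 2cc layer on 100cc
  )
  expect_error(dvh(structure_mask(g, array(FALSE, g$shape)), uni), "empty")
})

test_that("d_max, d_cc and v_gy behave on uniform and slab fields", {
  g <- voxel_grid(c(16, 16, 16), 2)
  m <- centered_sphere(g, 10, "S", "OAR")
  uni <- dose_distribution(g, array(20, g$shape))
  expect_equal(d_max(m, uni), 20)
  expect_equal(d_cc(m, uni, 1), 20)
  expect_equal(v_gy(m, uni, 20), volume_cc(m))
  expect_equal(v_gy(m, uni, 20.1), 0)
  # d_cc at v -> 0+ approaches d_max
  expect_equal(d_cc(m, uni, 1e-6), d_max(m, uni))
  expect_error(d_cc(m, uni, 1e6), "exceeds")

  sl <- slab_phantom()
  # hottest 10 cc of the 0..40 linear slab: continuum 36 Gy, one layer tol
  expect_lte(abs(d_cc(sl$mask, sl$dose, 10) - 36), 0.8 + 1e-9)
  expect_equal(d_cc(sl$mask, sl$dose, 10), oracle_d_cc(sl$mask, sl$dose, 10))
  set.seed(7)
  rnd <- dose_distribution(sl$grid, array(runif(12500, 0, 30), sl$grid$shape))
  for (v in c(0.5, 10, 50)) {
    expect_equal(d_cc(sl$mask, rnd, v), oracle_d_cc(sl$mask, rnd, v))
  }
  # v_gy non-increasing in d
  vg <- vapply(seq(0, 40, 5), function(d) v_gy(sl$mask, sl$dose, d), numeric(1))
  expect_true(all(diff(vg) <= 0))
})

test_that("coverage_pct counts the fraction of target at prescription", {
  g <- voxel_grid(c(20, 20, 20), 2)
  rx <- prescription("PTV1", 30, 5)
  ptv <- box_mask(g, c(4, 4, 4), c(18, 18, 18), "PTV1", "PTV") # 8^3 voxels
  full <- dose_distribution(g, array(31, g$shape))
  expect_equal(coverage_pct(ptv, full, rx), 100)

  # dose >= TD in exactly half the PTV voxels -> 50
  dd <- array(0, g$shape)
  idx <- which(ptv$voxels)
  dd[idx[seq_len(length(idx) / 2)]] <- 30
  expect_equal(coverage_pct(ptv, dose_distribution(g, dd), rx), 50)

  sphere <- centered_sphere(g, 10, "PTV1", "PTV")
  sd <- synth_dose(sphere, rx, falloff_mm = 12)
  expect_equal(coverage_pct(sphere, sd, rx), 100) # plateau by construction
  expect_equal(coverage_pct(sphere, sd, rx), oracle_coverage_pct(sphere, sd, rx))
})

test_that("r50 matches the analytic sphere and the voxel-count oracle", {
  g <- voxel_grid(c(64, 64, 64), 2)
  sph <- centered_sphere(g, 16, "PTV1", "PTV")
  rx <- prescription("PTV1", 40, 10)
  dd <- synth_dose(sph, rx, falloff_mm = 16, hotspot_pct = 100)
  # 50% isodose at 24 mm: continuum R50 = (24/16)^3 = 3.375
  expect_equal(r50(sph, dd, rx), 3.375, tolerance = 0.05)
  expect_equal(r50(sph, dd, rx), oracle_r50(sph, dd, rx))

  # dose = TD inside the PTV and 0 outside -> R50 exactly 1
  dd_in <- array(0, g$shape)
  dd_in[sph$voxels] <- 40
  expect_equal(r50(sph, dose_distribution(g, dd_in), rx), 1.0)

  # a second distant target with its own dose cloud inflates single-PTV R50
  sph2 <- centered_sphere(g, 12, "PTV2", "PTV", offset_mm = c(44, 0, 0))
  dd2 <- synth_dose(list(sph, sph2), rx, falloff_mm = 16)
  expect_gt(r50(sph, dd2, rx), r50(sph, dd, rx))
  # with the union as denominator the ratio comes back down
  expect_lt(r50(list(sph, sph2), dd2, rx), r50(sph, dd2, rx))
})

test_that("d2cm_pct measures falloff at the 2 cm shell", {
  g <- voxel_grid(c(64, 64, 64), 2)
  sph <- centered_sphere(g, 16, "PTV1", "PTV")
  rx <- prescription("PTV1", 40, 10)
  # falloff 16 mm: dose is zero at >= 16 mm, so 0% at 20 mm
  expect_equal(d2cm_pct(sph, synth_dose(sph, rx, falloff_mm = 16), rx), 0)
  # falloff 40 mm: dose at 20 mm is 50% of prescription
  expect_equal(
    d2cm_pct(sph, synth_dose(sph, rx, falloff_mm = 40), rx), 50,
    tolerance = 100 * 2 / 40 / 50 # one voxel of falloff
  )
  expect_equal(
    d2cm_pct(sph, dose_distribution(g, array(40, g$shape)), rx), 100
  )
  # agrees with an explicit distance-loop oracle on a small grid
  gs <- voxel_grid(c(26, 26, 26), 2)
  ss <- centered_sphere(gs, 8, "PTV1", "PTV")
  dd <- synth_dose(ss, rx, falloff_mm = 40)
  dist <- oracle_distance_mm(ss)
  sel <- pmax(0, dist - mean(gs$spacing) / 4) >= 20
  expect_equal(
    d2cm_pct(ss, dd, rx), 100 * max(dd$dose_gy[sel]) / 40,
    tolerance = 1e-12
  )
  # non-increasing in shell distance for monotone falloff fields
  vals <- vapply(c(16, 20, 24), function(s) {
    d2cm_pct(sph, synth_dose(sph, rx, falloff_mm = 40), rx, shell_mm = s)
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(d2cm_pct(sph, synth_dose(sph, rx), rx, shell_mm = 5), "spacing")
})

test_that("high_dose_spillage_pct counts hot volume outside the target", {
  g <- voxel_grid(c(32, 32, 32), 2)
  rx <- prescription("PTV1", 40, 10)
  vox <- array(FALSE, g$shape)
  vox[9:18, 9:18, 9:18] <- TRUE # 1000 voxels
  ptv <- structure_mask(g, vox, "PTV1", "PTV")

  dd_in <- array(0, g$shape)
  dd_in[ptv$voxels] <- 44 # hotspot confined to the PTV
  expect_equal(high_dose_spillage_pct(ptv, dose_distribution(g, dd_in), rx), 0)

  # 10-voxel 106% blob outside a 1000-voxel PTV -> 1.0%
  dd_blob <- dd_in
  dd_blob[1:10, 1, 1] <- 42.4 # 106% of 40 Gy
  expect_equal(
    high_dose_spillage_pct(ptv, dose_distribution(g, dd_blob), rx), 1.0
  )
  sd <- synth_dose(ptv, rx, falloff_mm = 16, hotspot_pct = 110)
  expect_equal(high_dose_spillage_pct(ptv, sd, rx), 0) # inside-only
  expect_equal(
    high_dose_spillage_pct(ptv, dose_distribution(g, dd_blob), rx),
    oracle_spillage_pct(ptv, dose_distribution(g, dd_blob), rx)
  )
})

test_that("ptv_eval subtracts (expanded) OARs from the target", {
  g <- voxel_grid(c(24, 24, 24), 2)
  ptv <- box_mask(g, c(0, 0, 0), c(14, 14, 14), "PTV1", "PTV")
  far <- box_mask(g, c(30, 30, 30), c(40, 40, 40), "bowel", "OAR")
  pe <- ptv_eval(ptv, list(far))
  expect_equal(pe$voxels, ptv$voxels)
  expect_identical(pe$role, "PTV_EVAL")

  # half-overlapping boxes -> half the PTV remains
  half <- box_mask(g, c(8, 0, 0), c(14, 14, 14), "bowel", "OAR")
  pe2 <- ptv_eval(ptv, list(half))
  expect_equal(sum(pe2$voxels), sum(ptv$voxels & !half$voxels))
  expect_equal(volume_cc(pe2), volume_cc(ptv) / 2)

  # OAR covering the PTV -> empty with warning
  all_oar <- box_mask(g, c(-2, -2, -2), c(20, 20, 20), "bowel", "OAR")
  expect_warning(pe3 <- ptv_eval(ptv, list(all_oar)), "empty")
  expect_equal(sum(pe3$voxels), 0)

  # margin shrinks the eval volume further
  pe4 <- ptv_eval(ptv, list(half), margin_mm = 4)
  expect_lt(sum(pe4$voxels), sum(pe2$voxels))
})
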