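test_that("dice handles identity, disjoint, partial overlap and empties", {
  g <- voxel_grid(c(20, 20, 20), 2)
  a <- box_mask(g, c(0, 0, 0), c(18, 18, 6), "A", "GTV")
  expect_equal(as.numeric(dice(a, a)), 1.0)

  b <- box_mask(g, c(0, 0, 20), c(18, 18, 26), "B", "GTV")
  expect_equal(as.numeric(dice(a, b)), 0.0)

  # two 1000-voxel cubes overlapping in 500 voxels -> 0.5
  v1 <- array(FALSE, g$shape)
  v1[1:10, 1:10, 1:10] <- TRUE
  v2 <- array(FALSE, g$shape)
  v2[1:10, 1:10, 6:15] <- TRUE
  expect_equal(as.numeric(dice(
    structure_mask(g, v1, "c1", "GTV"),
    structure_mask(g, v2, "c2", "GTV")
  )), 0.5)

  e1 <- structure_mask(g, array(FALSE, g$shape), "e1", "GTV")
  e2 <- structure_mask(g, array(FALSE, g$shape), "e2", "GTV")
  d <- dice(e1, e2)
  expect_equal(as.numeric(d), 1.0)
  expect_true(attr(d, "vacuous"))
  expect_equal(as.numeric(dice(e1, a)), 0.0)

  g2 <- voxel_grid(c(20, 20, 20), 1)
  expect_error(dice(a, box_mask(g2, c(0, 0, 0), c(5, 5, 5), "x", "GTV")),
    "grid mismatch")

  # symmetry and range on random masks
  for (s in 1:5) {
    m1 <- random_mask(g, 0.3, seed = s)
    m2 <- random_mask(g, 0.3, seed = s + 100)
    d12 <- as.numeric(dice(m1, m2))
    expect_identical(d12, as.numeric(dice(m2, m1)))
    expect_gte(d12, 0)
    expect_lte(d12, 1)
    expect_equal(d12, oracle_dice(m1, m2))
  }
})

test_that("reference_dsc pools lesions before comparing", {
  g <- voxel_grid(c(40, 40, 40), 2)
  ref <- list(
    reference_gtvs = list(
      centered_sphere(g, 8, "GTV1", "GTV", c(-18, 0, 0)),
      centered_sphere(g, 8, "GTV2", "GTV", c(18, 0, 0))
    ),
    reference_ptvs = list(
      centered_sphere(g, 12, "PTV1", "PTV", c(-18, 0, 0)),
      centered_sphere(g, 12, "PTV2", "PTV", c(18, 0, 0))
    )
  )
  sub_same <- contour_submission("A", "case",
    gtvs = ref$reference_gtvs, ptvs = ref$reference_ptvs
  )
  expect_equal(unname(reference_dsc(sub_same, ref)), c(1, 1))

  # no GTV drawn -> 0 against a non-empty reference
  sub_none <- contour_submission("B", "case", ptvs = ref$reference_ptvs)
  expect_equal(unname(reference_dsc(sub_none, ref)[["dsc_gtv"]]), 0)

  # one lesion missed: union DSC equals dice of explicitly OR-ed masks
  sub_miss <- contour_submission("C", "case",
    gtvs = ref$reference_gtvs[1], ptvs = ref$reference_ptvs[1]
  )
  got <- reference_dsc(sub_miss, ref)[["dsc_gtv"]]
  expect_equal(
    got,
    oracle_dice(ref$reference_gtvs[[1]], union_mask(ref$reference_gtvs))
  )
  expect_lt(got, 1)
})

test_that("pairwise_dsc is symmetric with unit diagonal", {
  g <- voxel_grid(c(32, 32, 32), 2)
  subs <- lapply(1:4, function(i) {
    contour_submission(LETTERS[i], "case",
      gtvs = list(centered_sphere(g, 10, "GTV1", "GTV", c(2 * i, 0, 0)))
    )
  })
  m <- pairwise_dsc(subs, "GTV")
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(rownames(m), LETTERS[1:4])
  expect_true(all(m >= 0 & m <= 1))

  same <- pairwise_dsc(list(subs[[1]], subs[[1]]), "GTV")
  expect_equal(unname(same), matrix(1, 2, 2))
  expect_error(pairwise_dsc(subs[1], "GTV"), "two submissions")
})

test_that("icc_2_1 matches the ANOVA oracle and known cases", {
  # raters identical, subjects differ: perfect absolute agreement
  expect_equal(as.numeric(icc_2_1(matrix(c(1, 0, 1, 0), 2, 2))), 1.0)

  # zero total variance: defined as 1 with a warning
  expect_warning(v <- icc_2_1(matrix(0.3, 3, 4)), "zero total variance")
  expect_equal(as.numeric(v), 1.0)

  # brute-force ANOVA agreement on random 5x6 matrices
  for (s in 1:8) {
    set.seed(s)
    m <- matrix(runif(30), 5, 6)
    expect_equal(as.numeric(icc_2_1(m)), oracle_icc21_aov(m),
      tolerance = 1e-10
    )
  }

  # absolute-agreement sensitivity: a systematic offset on one rater's
  # column lowers ICC(2,1) when real subject structure is present
  for (s in c(17, 42, 99)) {
    set.seed(s)
    subj <- runif(5, 0, 1)
    m <- outer(subj, rep(1, 6)) + matrix(rnorm(30, 0, 0.05), 5, 6)
    expect_gt(as.numeric(icc_2_1(m)), 0)
    m_shift <- m
    m_shift[, 2] <- m_shift[, 2] + 0.3
    expect_lt(as.numeric(icc_2_1(m_shift)), as.numeric(icc_2_1(m)))
  }

  expect_error(icc_2_1(matrix(c(1, NA, 0, 1), 2, 2)), "complete")
})

test_that("reliability of the packaged DSC table matches the ANOVA oracle", {
  tab <- fixture_agreement_table()
  m_gtv <- ratings_from_reference(tab, "GTV")
  expect_equal(dim(m_gtv), c(4, 10))
  v <- as.numeric(icc_2_1(m_gtv))
  expect_equal(v, oracle_icc21_aov(m_gtv), tolerance = 1e-10)
  expect_equal(round_half_up(v, 3), 0.661)
})

test_that("bootstrap CI is seed-deterministic, ordered and calibrated", {
  g <- voxel_grid(c(40, 40, 40), 2)
  a <- centered_sphere(g, 16, "A", "PTV")
  b <- centered_sphere(g, 16, "B", "PTV", offset_mm = c(5, 3, 0))

  expect_equal(unname(bootstrap_ci(a, a, 200, seed = 9)), c(1, 1))
  ci1 <- bootstrap_ci(a, b, 500, seed = 4)
  ci2 <- bootstrap_ci(a, b, 500, seed = 4)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lo"]], ci1[["hi"]])
  expect_true(all(ci1 >= 0 & ci1 <= 1))

  # interval widths shrink as the phantom grows (nested spheres)
  widths <- vapply(c(8, 12, 18), function(r) {
    aa <- centered_sphere(g, r, "A", "PTV")
    bb <- centered_sphere(g, r, "B", "PTV", offset_mm = c(3, 2, 0))
    ci <- bootstrap_ci(aa, bb, 400, seed = 2)
    ci[["hi"]] - ci[["lo"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  e <- structure_mask(g, array(FALSE, g$shape), "e", "PTV")
  expect_warning(ci0 <- bootstrap_ci(e, e, 50, seed = 1), "empty")
  expect_equal(unname(ci0), c(0, 0))

  # voxel-block resampling unit is also available and deterministic
  cb <- bootstrap_ci(a, b, 200, seed = 5, unit = "voxel_block")
  expect_identical(cb, bootstrap_ci(a, b, 200, seed = 5, unit = "voxel_block"))
})

test_that("agreement_table reports rounded DSC with CI per case and kind", {
  g <- voxel_grid(c(40, 40, 40), 2)
  ref <- make_case("NODAL", grid_spec = g, seed = 3, case_id = "Case1")
  subs <- list(
    contour_submission("A", "Case1",
      gtvs = ref$reference_gtvs, ptvs = ref$reference_ptvs
    ),
    contour_submission("B", "Case1",
      gtvs = list(), ptvs = ref$reference_ptvs
    )
  )
  tab <- agreement_table(subs, list(Case1 = ref), n_boot = 100, seed = 1)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$dsc[tab$center_id == "A" & tab$volume_kind == "GTV"], 1)
  expect_equal(tab$dsc[tab$center_id == "B" & tab$volume_kind == "GTV"], 0)
  expect_true(all(tab$ci_low <= tab$ci_high))
})
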