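# Shared phantoms and independent brute-force oracles. The oracles never
# call the implementation paths they check: they loop over voxels (or use
# base R's aov) directly.

small_grid <- function(n = 32, spacing = 2) voxel_grid(rep(n, 3), spacing)

centered_sphere <- function(grid, radius_mm, label = "PTV1", role = "PTV",
                            offset_mm = c(0, 0, 0)) {
  ctr <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  ellipsoid_mask(grid, ctr + offset_mm, radius_mm, label, role)
}

random_mask <- function(grid, p = 0.2, seed = 1, label = "rand",
                        role = "GTV") {
  set.seed(seed)
  structure_mask(grid, runif(prod(grid$shape)) < p, label, role)
}

# --- voxel-loop oracles -----------------------------------------------------

oracle_volume_cc <- function(mask) {
  n <- 0L
  v <- mask$voxels
  for (i in seq_along(v)) if (v[i]) n <- n + 1L
  n * prod(mask$grid$spacing) / 1000
}

oracle_dice <- function(a, b) {
  va <- as.vector(a$voxels)
  vb <- as.vector(b$voxels)
  ni <- 0L
  na <- 0L
  nb <- 0L
  for (i in seq_along(va)) {
    if (va[i]) na <- na + 1L
    if (vb[i]) nb <- nb + 1L
    if (va[i] && vb[i]) ni <- ni + 1L
  }
  if (na + nb == 0L) 1.0 else 2 * ni / (na + nb)
}

# explicit O(n^2) distance-to-mask, in mm
oracle_distance_mm <- function(mask) {
  grid <- mask$grid
  idx <- which(mask$voxels, arr.ind = TRUE)
  pos <- cbind(
    (idx[, 1] - 1) * grid$spacing[1],
    (idx[, 2] - 1) * grid$spacing[2],
    (idx[, 3] - 1) * grid$spacing[3]
  )
  out <- array(NA_real_, grid$shape)
  for (i in seq_len(grid$shape[1])) {
    for (j in seq_len(grid$shape[2])) {
      for (k in seq_len(grid$shape[3])) {
        p <- c(
          (i - 1) * grid$spacing[1], (j - 1) * grid$spacing[2],
          (k - 1) * grid$spacing[3]
        )
        out[i, j, k] <- sqrt(min(
          (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 + (pos[, 3] - p[3])^2
        ))
      }
    }
  }
  out
}

oracle_coverage_pct <- function(ptv, dose, rx) {
  sel <- as.vector(ptv$voxels)
  dd <- as.vector(dose$dose_gy)
  hit <- 0L
  tot <- 0L
  for (i in seq_along(sel)) {
    if (sel[i]) {
      tot <- tot + 1L
      if (dd[i] >= rx$total_dose_gy) hit <- hit + 1L
    }
  }
  100 * hit / tot
}

oracle_r50 <- function(ptv, dose, rx) {
  sel <- as.vector(ptv$voxels)
  dd <- as.vector(dose$dose_gy)
  iso <- 0L
  tot <- 0L
  for (i in seq_along(sel)) {
    if (sel[i]) tot <- tot + 1L
    if (dd[i] >= 0.5 * rx$total_dose_gy) iso <- iso + 1L
  }
  iso / tot
}

oracle_spillage_pct <- function(ptv, dose, rx, thr = 105) {
  sel <- as.vector(ptv$voxels)
  dd <- as.vector(dose$dose_gy)
  hot <- 0L
  tot <- 0L
  for (i in seq_along(sel)) {
    if (sel[i]) tot <- tot + 1L
    if (!sel[i] && dd[i] >= thr / 100 * rx$total_dose_gy) hot <- hot + 1L
  }
  100 * hot / tot
}

oracle_d_cc <- function(mask, dose, v_cc) {
  dd <- sort(dose$dose_gy[mask$voxels], decreasing = TRUE)
  vox_cc <- prod(mask$grid$spacing) / 1000
  dd[max(1L, ceiling(v_cc / vox_cc - 1e-9))]
}

# two-way ANOVA route through base R's aov(), independent of the
# sum-of-squares formulas in icc_2_1()
oracle_icc21_aov <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subj = factor(as.vector(row(m))),
    rater = factor(as.vector(col(m)))
  )
  ms <- stats::anova(stats::aov(y ~ subj + rater, data = df))$`Mean Sq`
  n <- nrow(m)
  k <- ncol(m)
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
}

# high-precision two-pass mean/SD oracle
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  c(mean = m, sd = s)
}
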