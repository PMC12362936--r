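# Phase-1 statistics: Dice similarity of summed target volumes against the
# reference label, pairwise inter-center DSC, ICC(2,1), and non-parametric
# bootstrap 95% confidence intervals.

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to agree perfectly
#' (DSC 1 with attribute `vacuous = TRUE`); an empty mask against a
#' non-empty one scores 0.
#'
#' @param a,b [structure_mask()]s on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!same_grid(a$grid, b$grid)) {
    stop(sprintf("grid mismatch: '%s' on %s vs '%s' on %s",
      a$label, format(a$grid), b$label, format(b$grid)))
  }
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na == 0 && nb == 0) {
    return(structure(1.0, vacuous = TRUE))
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' DSC of a submission's summed volumes against the reference
#'
#' Pools the submission's GTVs (and PTVs) by voxelwise union and compares
#' each pooled volume with the union of the reference case's volumes. A
#' submission that drew nothing for a non-empty reference scores 0.
#'
#' @param sub a [contour_submission()].
#' @param ref a `case_archetype` (see [make_case()]) holding
#'   `reference_gtvs` and `reference_ptvs`.
#' @return Named numeric `c(dsc_gtv = , dsc_ptv = )`.
#' @export
reference_dsc <- function(sub, ref) {
  one <- function(sub_masks, ref_masks, role) {
    ref_u <- union_mask(ref_masks, label = paste0("ref_", role))
    if (length(sub_masks) == 0) {
      return(if (any(ref_u$voxels)) 0.0 else structure(1.0, vacuous = TRUE))
    }
    sub_u <- union_mask(sub_masks, label = paste0("sub_", role))
    as.numeric(dice(sub_u, ref_u))
  }
  c(
    dsc_gtv = one(sub$gtvs, ref$reference_gtvs, "GTV"),
    dsc_ptv = one(sub$ptvs, ref$reference_ptvs, "PTV")
  )
}

#' Pairwise inter-center DSC matrix
#'
#' @param subs list of [contour_submission()]s for one case (>= 2).
#' @param volume_kind `"GTV"` or `"PTV"`.
#' @return Symmetric `length(subs)` x `length(subs)` matrix (diagonal 1),
#'   dimnames = center ids; entry (i, j) is the DSC of the two centers'
#'   pooled volumes.
#' @export
pairwise_dsc <- function(subs, volume_kind = c("GTV", "PTV")) {
  volume_kind <- match.arg(volume_kind)
  if (length(subs) < 2) stop("need at least two submissions")
  case_ids <- unique(vapply(subs, function(s) s$case_id, character(1)))
  if (length(case_ids) != 1) {
    stop("pairwise DSC expects submissions from a single case")
  }
  grid <- NULL
  unions <- lapply(subs, function(s) {
    masks <- if (volume_kind == "GTV") s$gtvs else s$ptvs
    if (length(masks) == 0) {
      return(NULL)
    }
    union_mask(masks, label = s$center_id)
  })
  grid <- NULL
  for (u in unions) if (!is.null(u)) grid <- u$grid
  if (is.null(grid)) stop("no submission contains any ", volume_kind)
  empty <- structure_mask(grid, array(FALSE, grid$shape), "empty", volume_kind)
  unions <- lapply(unions, function(u) if (is.null(u)) empty else u)
  n <- length(subs)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- as.numeric(dice(unions[[i]], unions[[j]]))
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  ids <- vapply(subs, function(s) s$center_id, character(1))
  dimnames(out) <- list(ids, ids)
  out
}

#' Ratings matrix for reliability analysis
#'
#' A complete subjects x raters matrix of agreement values, the input of
#' [icc_2_1()].
#'
#' @param values numeric matrix, no missing cells.
#' @param subject_ids,rater_ids optional dimnames.
#' @return An object of class `ratings_matrix` (a matrix).
#' @export
ratings_matrix <- function(values, subject_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("ratings matrix must be complete (no missing cells)")
  if (!is.null(subject_ids)) rownames(values) <- subject_ids
  if (!is.null(rater_ids)) colnames(values) <- rater_ids
  class(values) <- c("ratings_matrix", class(values))
  values
}

#' Ratings layout from per-case pairwise DSC matrices
#'
#' Flattens each case's pairwise matrix to its upper-triangle vector and
#' stacks cases as subjects (cases x pair-index). This is the default layout
#' for [icc_2_1()]; the alternative (cases x centers of reference DSCs) is
#' built by [ratings_from_reference()].
#'
#' @param pairwise_by_case named list of symmetric matrices from
#'   [pairwise_dsc()], one per case, identical dimensions.
#' @return A [ratings_matrix()].
#' @export
ratings_from_pairwise <- function(pairwise_by_case) {
  rows <- lapply(pairwise_by_case, function(m) m[upper.tri(m)])
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("per-case pairwise matrices have differing sizes")
  }
  ratings_matrix(do.call(rbind, rows), subject_ids = names(pairwise_by_case))
}

#' Ratings layout from reference DSCs (cases x centers)
#'
#' @param table an agreement table (see [agreement_table()]).
#' @param volume_kind `"GTV"` or `"PTV"`.
#' @return A [ratings_matrix()] with one row per case, one column per
#'   center.
#' @export
ratings_from_reference <- function(table, volume_kind = c("GTV", "PTV")) {
  volume_kind <- match.arg(volume_kind)
  sub <- table[table$volume_kind == volume_kind, , drop = FALSE]
  cases <- sort(unique(sub$case_id))
  centers <- sort(unique(sub$center_id))
  m <- matrix(NA_real_, length(cases), length(centers),
    dimnames = list(cases, centers)
  )
  for (r in seq_len(nrow(sub))) {
    m[sub$case_id[r], sub$center_id[r]] <- sub$dsc[r]
  }
  ratings_matrix(m)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square, for `n` subjects and `k` raters.
#'
#' @param m a [ratings_matrix()] (or plain complete matrix), n >= 2 subjects
#'   by k >= 2 raters.
#' @return The ICC value (<= 1), with the mean squares attached as attribute
#'   `anova` for audit. A matrix with zero total variance returns 1 with a
#'   warning.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ratings matrix must be complete (no missing cells)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  gm <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - gm)^2)
  if (ss_total == 0) {
    warning("zero total variance; ICC defined as 1")
    return(structure(1.0, anova = c(MSR = 0, MSC = 0, MSE = 0, n = n, k = k)))
  }
  ss_rows <- k * sum((row_means - gm)^2)
  ss_cols <- n * sum((col_means - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(icc, anova = c(MSR = msr, MSC = msc, MSE = mse, n = n, k = k))
}

# Per-resampling-unit voxel tallies for the bootstrap: |A|, |B|, |A n B| in
# every unit (axial slice or cubic block) intersecting the union support.
bootstrap_units <- function(a, b, unit, block_vox = 4L) {
  if (unit == "axial_slice") {
    ia <- apply(a$voxels, 3, sum)
    ib <- apply(b$voxels, 3, sum)
    ii <- apply(a$voxels & b$voxels, 3, sum)
    keep <- which(ia + ib > 0)
    list(na = ia[keep], nb = ib[keep], ni = ii[keep])
  } else {
    sh <- a$grid$shape
    idx <- which(a$voxels | b$voxels, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(list(na = integer(0), nb = integer(0), ni = integer(0)))
    }
    bid <- ((idx[, 1] - 1L) %/% block_vox) +
      ((idx[, 2] - 1L) %/% block_vox) * 10000L +
      ((idx[, 3] - 1L) %/% block_vox) * 100000000L
    f <- factor(bid)
    lin <- (idx[, 3] - 1L) * sh[1] * sh[2] + (idx[, 2] - 1L) * sh[1] + idx[, 1]
    av <- a$voxels[lin]
    bv <- b$voxels[lin]
    list(
      na = as.integer(tapply(av, f, sum)),
      nb = as.integer(tapply(bv, f, sum)),
      ni = as.integer(tapply(av & bv, f, sum))
    )
  }
}

#' Bootstrap 95% confidence interval for a DSC
#'
#' Non-parametric bootstrap: spatial units (axial slices of the union
#' support by default, or cubic voxel blocks) are resampled with
#' replacement, the DSC is recomputed for each replicate, and the 2.5th and
#' 97.5th percentiles of the replicate distribution are returned.
#'
#' @param a,b [structure_mask()]s on one grid.
#' @param n_boot number of replicates (default 1000).
#' @param seed integer seed; the interval is deterministic per seed.
#' @param unit `"axial_slice"` (default) or `"voxel_block"` (4^3-voxel
#'   blocks).
#' @return Named numeric `c(lo = , hi = )`. If both masks are empty in every
#'   unit the interval is `(0, 0)` with a warning.
#' @export
bootstrap_ci <- function(a, b, n_boot = 1000, seed = 1,
                         unit = c("axial_slice", "voxel_block")) {
  unit <- match.arg(unit)
  stopifnot(n_boot >= 1)
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch")
  u <- bootstrap_units(a, b, unit)
  m <- length(u$na)
  if (m == 0) {
    warning("both masks empty: bootstrap CI undefined, returning (0, 0)")
    return(c(lo = 0, hi = 0))
  }
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      s <- sample.int(m, m, replace = TRUE)
      den <- sum(u$na[s]) + sum(u$nb[s])
      if (den == 0) 1.0 else 2 * sum(u$ni[s]) / den
    }, numeric(1))
  })
  # percentiles of the relative frequency distribution (inverse ECDF)
  q <- quantile(reps, c(0.025, 0.975), type = 1, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Agreement table for a cohort (the shape of a per-center DSC table)
#'
#' For every submission, the DSC of its summed GTV and summed PTV against
#' the case reference, with bootstrap 95% CIs.
#'
#' @param subs list of [contour_submission()]s.
#' @param refs named list of case archetypes (names = case ids).
#' @param n_boot,seed bootstrap settings (the per-row seed is derived from
#'   `seed` and the row index).
#' @param unit bootstrap resampling unit, see [bootstrap_ci()].
#' @return A data.frame with columns `case_id`, `volume_kind`, `center_id`,
#'   `dsc`, `ci_low`, `ci_high`; DSC rounded half-up to 3 decimals.
#' @export
agreement_table <- function(subs, refs, n_boot = 1000, seed = 1,
                            unit = "axial_slice") {
  rows <- list()
  i <- 0L
  for (sub in subs) {
    ref <- refs[[sub$case_id]]
    if (is.null(ref)) stop("no reference for case ", sub$case_id)
    for (kind in c("GTV", "PTV")) {
      i <- i + 1L
      ref_masks <- if (kind == "GTV") ref$reference_gtvs else ref$reference_ptvs
      sub_masks <- if (kind == "GTV") sub$gtvs else sub$ptvs
      ref_u <- union_mask(ref_masks)
      grid <- ref_u$grid
      sub_u <- if (length(sub_masks) > 0) {
        union_mask(sub_masks)
      } else {
        structure_mask(grid, array(FALSE, grid$shape), "empty", kind)
      }
      d <- as.numeric(dice(sub_u, ref_u))
      ci <- bootstrap_ci(sub_u, ref_u,
        n_boot = n_boot,
        seed = (seed * 1000L + i) %% .Machine$integer.max, unit = unit
      )
      rows[[i]] <- data.frame(
        case_id = sub$case_id, volume_kind = kind, center_id = sub$center_id,
        dsc = round_half_up(d, 3),
        ci_low = round_half_up(ci[["lo"]], 3),
        ci_high = round_half_up(ci[["hi"]], 3),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
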