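# Dose-volume computations behind the plan review: DVH queries, PTV
# coverage, the SBRT moderate-dose spillage indices R50% and D2cm,
# high-dose spillage, and PTV-EVAL construction.

mask_doses <- function(mask, dose) {
  stopifnot(inherits(mask, "structure_mask"), inherits(dose, "dose_distribution"))
  if (!same_grid(mask$grid, dose$grid)) stop("mask and dose grids differ")
  dose$dose_gy[mask$voxels]
}

#' Cumulative dose-volume histogram
#'
#' @param mask a non-empty [structure_mask()].
#' @param dose a [dose_distribution()] on the same grid.
#' @param bin_gy dose-axis bin width in Gy (default 0.1).
#' @return An object of class `dvh_curve`: data.frame with `dose_gy`,
#'   `volume_cc`, `volume_pct` (volume receiving at least each dose level),
#'   plus attributes `structure_label` and `total_cc`. The curve is
#'   non-increasing and starts at the full structure volume at 0 Gy.
#' @export
dvh <- function(mask, dose, bin_gy = 0.1) {
  stopifnot(bin_gy > 0)
  dd <- mask_doses(mask, dose)
  if (length(dd) == 0) stop("empty mask: DVH undefined")
  vox_cc <- voxel_volume_cc(mask$grid)
  total <- length(dd) * vox_cc
  axis <- seq(0, ceiling(max(dd) / bin_gy) * bin_gy + bin_gy, by = bin_gy)
  vol <- vapply(axis, function(d) sum(dd >= d) * vox_cc, numeric(1))
  out <- data.frame(
    dose_gy = axis, volume_cc = vol, volume_pct = 100 * vol / total
  )
  attr(out, "structure_label") <- mask$label
  attr(out, "total_cc") <- total
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Point dose statistics: Dmax, D_cc, V_Gy
#'
#' `d_max` is the maximum voxel dose inside the structure; `d_cc(v)` the
#' minimum dose received by the hottest `v` cc; `v_gy(d)` the structure
#' volume receiving at least `d` Gy.
#'
#' @param mask a non-empty [structure_mask()].
#' @param dose a [dose_distribution()] on the same grid.
#' @return Gy for `d_max`/`d_cc`, cc for `v_gy`.
#' @export
d_max <- function(mask, dose) {
  dd <- mask_doses(mask, dose)
  if (length(dd) == 0) stop("empty mask")
  max(dd)
}

#' @rdname d_max
#' @param v_cc hottest volume in cc (0 < v_cc <= structure volume).
#' @export
d_cc <- function(mask, dose, v_cc) {
  dd <- mask_doses(mask, dose)
  if (length(dd) == 0) stop("empty mask")
  vox_cc <- voxel_volume_cc(mask$grid)
  total <- length(dd) * vox_cc
  if (v_cc > total + 1e-9) {
    stop(sprintf("v_cc = %g exceeds the structure volume %.3f cc", v_cc, total))
  }
  k <- max(1L, ceiling(v_cc / vox_cc - 1e-9))
  sort(dd, decreasing = TRUE)[k]
}

#' @rdname d_max
#' @param d_gy dose threshold in Gy.
#' @export
v_gy <- function(mask, dose, d_gy) {
  dd <- mask_doses(mask, dose)
  if (length(dd) == 0) stop("empty mask")
  sum(dd >= d_gy) * voxel_volume_cc(mask$grid)
}

#' PTV coverage
#'
#' Percentage of the target volume receiving at least the prescribed total
#' dose.
#'
#' @param ptv a non-empty [structure_mask()].
#' @param dose a [dose_distribution()].
#' @param rx a [prescription()].
#' @return Coverage in percent (0-100).
#' @export
coverage_pct <- function(ptv, dose, rx) {
  dd <- mask_doses(ptv, dose)
  if (length(dd) == 0) stop("empty PTV: coverage undefined")
  100 * sum(dd >= rx$total_dose_gy) / length(dd)
}

#' R50%: moderate-dose spillage ratio
#'
#' Ratio of the volume enclosed by the 50%-of-prescription isodose to the
#' target volume. When one prescription covers several target volumes the
#' denominator is their union and the numerator the full isodose cloud.
#'
#' @param ptvs a [structure_mask()] or list of them (the prescription's
#'   targets).
#' @param dose a [dose_distribution()].
#' @param rx a [prescription()].
#' @return The R50% ratio (dimensionless).
#' @export
r50 <- function(ptvs, dose, rx) {
  u <- union_mask(ptvs)
  n_ptv <- sum(u$voxels)
  if (n_ptv == 0) stop("zero PTV volume")
  n_iso <- sum(dose$dose_gy >= 0.5 * rx$total_dose_gy)
  n_iso / n_ptv
}

#' D2cm: maximum dose at 2 cm from the target, as % of prescription
#'
#' Maximum dose over all voxels whose 3D Euclidean distance from the
#' union-target surface is at least `shell_mm`, expressed as a percentage
#' of the prescribed total dose. Distances come from an exact anisotropic
#' distance transform of the target with a half-voxel surface correction
#' (see [surface_distance_mm()]).
#'
#' @param ptvs a [structure_mask()] or list of them.
#' @param dose a [dose_distribution()].
#' @param rx a [prescription()].
#' @param shell_mm shell distance in mm (default 20 = 2 cm); the grid
#'   spacing must be at most `shell_mm / 5`.
#' @return Percent of prescription dose.
#' @export
d2cm_pct <- function(ptvs, dose, rx, shell_mm = 20) {
  u <- union_mask(ptvs)
  if (!any(u$voxels)) stop("zero PTV volume")
  if (any(u$grid$spacing > shell_mm / 5)) {
    stop("grid spacing too coarse for the requested shell distance")
  }
  d <- surface_distance_mm(u)
  sel <- d >= shell_mm
  if (!any(sel)) stop("no voxel lies >= shell_mm from the PTV: grid too small")
  100 * max(dose$dose_gy[sel]) / rx$total_dose_gy
}

#' High-dose spillage
#'
#' Volume outside the target receiving at least `threshold_pct`% of the
#' prescription, as a percentage of the target volume.
#'
#' @param ptvs a [structure_mask()] or list of them.
#' @param dose a [dose_distribution()].
#' @param rx a [prescription()].
#' @param threshold_pct hot threshold as % of prescription (default 105).
#' @return Percent of the target volume.
#' @export
high_dose_spillage_pct <- function(ptvs, dose, rx, threshold_pct = 105) {
  u <- union_mask(ptvs)
  n_ptv <- sum(u$voxels)
  if (n_ptv == 0) stop("zero PTV volume")
  hot <- dose$dose_gy >= threshold_pct / 100 * rx$total_dose_gy
  100 * sum(hot & !u$voxels) / n_ptv
}

#' PTV-EVAL: target minus organs-at-risk
#'
#' Subtracts the (optionally expanded) union of OARs from a PTV so that
#' coverage can be judged without penalizing OAR sparing.
#'
#' @param ptv a [structure_mask()].
#' @param oars list of OAR [structure_mask()]s on the same grid.
#' @param margin_mm expansion applied to the OAR union before subtraction
#'   (default 0).
#' @return A [structure_mask()] with role `PTV_EVAL` and label
#'   `"<ptv>_EVAL"`. An empty result is returned with a warning (coverage is
#'   then undefined).
#' @export
ptv_eval <- function(ptv, oars, margin_mm = 0) {
  label <- paste0(ptv$label, "_EVAL")
  if (length(oars) == 0) {
    return(structure_mask(ptv$grid, ptv$voxels, label, "PTV_EVAL"))
  }
  stopifnot_same_grid(ptv$grid, oars, "OAR")
  oar_u <- union_mask(oars, label = "OAR_union")
  if (margin_mm > 0 && any(oar_u$voxels)) {
    oar_u <- expand_mask(oar_u, margin_mm)
  }
  vox <- ptv$voxels & !oar_u$voxels
  if (!any(vox)) {
    warning(sprintf("PTV-EVAL of '%s' is empty: OARs cover the whole PTV",
      ptv$label))
  }
  structure_mask(ptv$grid, vox, label, "PTV_EVAL")
}

#' Write a DVH curve to CSV
#'
#' @param curve a [dvh()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(curve, path) {
  write.csv(as.data.frame(curve)[, c("dose_gy", "volume_cc", "volume_pct")],
    path,
    row.names = FALSE
  )
  invisible(path)
}
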