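# Core domain types: voxel lattice, binary structures, dose fields,
# prescriptions, and the per-center submission objects evaluated by the
# agreement and compliance stages. All geometry is done on a common
# axis-aligned voxel grid in physical millimetres; volumes are reported in
# cc, doses in Gy, percentages on the 0-100 scale.

STRUCTURE_ROLES <- c("GTV", "PTV", "PTV_EVAL", "OAR", "DOSE_REGION")

#' Voxel grid geometry
#'
#' An axis-aligned 3D lattice. The centre of voxel `[1, 1, 1]` sits at
#' `origin`; voxel centres advance by `spacing` millimetres along each axis.
#'
#' @param shape integer triple `(nx, ny, nz)`, each >= 1.
#' @param spacing_mm positive mm triple (or a scalar, recycled).
#' @param origin_mm mm triple, default `c(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing_mm = 2, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(is.na(shape)) || any(shape < 1)) {
    stop("`shape` must be three integers >= 1")
  }
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be positive and finite")
  }
  origin_mm <- rep_len(as.numeric(origin_mm), 3)
  structure(
    list(shape = shape, spacing = spacing_mm, origin = origin_mm),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid %dx%dx%d @ %.3gx%.3gx%.3g mm, origin (%g, %g, %g) mm>\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%dx%dx%d@%gmm", x$shape[1], x$shape[2], x$shape[3], x$spacing[1])
}

voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_same_grid <- function(grid, masks, what = "mask") {
  for (i in seq_along(masks)) {
    if (!same_grid(grid, masks[[i]]$grid)) {
      stop(sprintf(
        "%s %d ('%s') is on grid %s, expected %s",
        what, i, masks[[i]]$label %||% "?",
        format(masks[[i]]$grid), format(grid)
      ))
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binary structure mask
#'
#' A binary occupancy array over a [voxel_grid()], tagged with a label and a
#' role (GTV, PTV, PTV_EVAL, OAR or DOSE_REGION).
#'
#' @param grid a [voxel_grid()].
#' @param voxels logical array with `dim` equal to `grid$shape` (a logical
#'   vector of matching length is reshaped).
#' @param label structure name, e.g. `"PTV1"`.
#' @param role one of `"GTV"`, `"PTV"`, `"PTV_EVAL"`, `"OAR"`,
#'   `"DOSE_REGION"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(grid, voxels, label = "structure", role = "GTV") {
  stopifnot(inherits(grid, "voxel_grid"))
  role <- match.arg(role, STRUCTURE_ROLES)
  voxels <- as.logical(voxels)
  if (length(voxels) != prod(grid$shape)) {
    stop("`voxels` length does not match the grid shape")
  }
  if (anyNA(voxels)) stop("`voxels` must not contain NA")
  dim(voxels) <- grid$shape
  structure(
    list(grid = grid, voxels = voxels, label = label, role = role),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "<structure_mask '%s' [%s] %s, %.2f cc (%d voxels)>\n",
    x$label, x$role, format(x$grid), volume_cc(x), sum(x$voxels)
  ))
  invisible(x)
}

#' Structure volume in cc
#'
#' @param mask a [structure_mask()].
#' @return Occupied-voxel count times the voxel volume, in cc; 0 for an
#'   empty mask.
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * voxel_volume_cc(mask$grid)
}

#' Voxelwise union of structure masks
#'
#' The "sum" of a set of structures: voxelwise OR. Used to pool multi-lesion
#' GTVs/PTVs before computing overlap statistics.
#'
#' @param masks non-empty list of [structure_mask()]s on one grid.
#' @param label label for the union (default: joined input labels).
#' @return A [structure_mask()]; the role is preserved when all inputs share
#'   one role, otherwise `"DOSE_REGION"`.
#' @export
union_mask <- function(masks, label = NULL) {
  if (inherits(masks, "structure_mask")) masks <- list(masks)
  if (length(masks) == 0) stop("`masks` must be a non-empty list")
  grid <- masks[[1]]$grid
  stopifnot_same_grid(grid, masks)
  vox <- masks[[1]]$voxels
  if (length(masks) > 1) {
    for (m in masks[-1]) vox <- vox | m$voxels
  }
  roles <- unique(vapply(masks, function(m) m$role, character(1)))
  role <- if (length(roles) == 1) roles else "DOSE_REGION"
  label <- label %||% paste(vapply(masks, function(m) m$label, character(1)),
    collapse = "+"
  )
  structure_mask(grid, vox, label = label, role = role)
}

#' Dose distribution
#'
#' A non-negative scalar dose field (Gy) over a [voxel_grid()].
#'
#' @param grid a [voxel_grid()].
#' @param dose_gy numeric array matching the grid shape; all values finite
#'   and >= 0.
#' @return An object of class `dose_distribution`.
#' @export
dose_distribution <- function(grid, dose_gy) {
  stopifnot(inherits(grid, "voxel_grid"))
  dose_gy <- as.numeric(dose_gy)
  if (length(dose_gy) != prod(grid$shape)) {
    stop("`dose_gy` length does not match the grid shape")
  }
  if (any(!is.finite(dose_gy)) || any(dose_gy < 0)) {
    stop("dose values must be finite and non-negative")
  }
  dim(dose_gy) <- grid$shape
  structure(list(grid = grid, dose_gy = dose_gy), class = "dose_distribution")
}

#' @export
print.dose_distribution <- function(x, ...) {
  cat(sprintf(
    "<dose_distribution %s, max %.2f Gy>\n", format(x$grid), max(x$dose_gy)
  ))
  invisible(x)
}

#' Dose prescription
#'
#' @param target_label PTV (or PTV_EVAL) label the prescription applies to.
#' @param total_dose_gy total dose TD in Gy, > 0.
#' @param fractions fraction count fx, integer >= 1.
#' @return An object of class `prescription` with a `dose_per_fraction_gy`
#'   field.
#' @export
prescription <- function(target_label, total_dose_gy, fractions) {
  total_dose_gy <- as.numeric(total_dose_gy)
  fractions <- as.integer(fractions)
  if (!is.finite(total_dose_gy) || total_dose_gy <= 0) {
    stop("`total_dose_gy` must be > 0")
  }
  if (is.na(fractions) || fractions < 1) stop("`fractions` must be >= 1")
  structure(
    list(
      target_label = as.character(target_label),
      total_dose_gy = total_dose_gy,
      fractions = fractions,
      dose_per_fraction_gy = total_dose_gy / fractions
    ),
    class = "prescription"
  )
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf(
    "<prescription %s: %g Gy / %d fx>\n",
    x$target_label, x$total_dose_gy, x$fractions
  ))
  invisible(x)
}

#' Phase-1 contour submission
#'
#' One institution's delineation of one case: its GTV and PTV masks. Either
#' list may be empty (a centre may have missed a lesion entirely).
#'
#' @param center_id,case_id identifiers.
#' @param gtvs,ptvs lists of [structure_mask()]s, all on one grid.
#' @return An object of class `contour_submission`.
#' @export
contour_submission <- function(center_id, case_id, gtvs = list(),
                               ptvs = list()) {
  all_masks <- c(gtvs, ptvs)
  if (length(all_masks) > 0) {
    grid <- all_masks[[1]]$grid
    stopifnot_same_grid(grid, all_masks, "submission mask")
  }
  structure(
    list(
      center_id = as.character(center_id), case_id = as.character(case_id),
      gtvs = gtvs, ptvs = ptvs
    ),
    class = "contour_submission"
  )
}

#' Phase-2 plan submission
#'
#' One institution's treatment plan for one case: the dose field, the
#' prescriptions, and the structure set used for evaluation.
#'
#' @param center_id,case_id identifiers.
#' @param dose a [dose_distribution()].
#' @param prescriptions list of [prescription()]s; each `target_label` must
#'   resolve to exactly one PTV or PTV_EVAL mask in `structures`.
#' @param structures list of [structure_mask()]s (PTVs, OARs, PTV_EVALs).
#' @param uses_ptv_eval logical; if `TRUE`, coverage rules are evaluated on
#'   the PTV-EVAL companion of each target (PTV minus OARs).
#' @return An object of class `plan_submission`.
#' @export
plan_submission <- function(center_id, case_id, dose, prescriptions,
                            structures, uses_ptv_eval = FALSE) {
  stopifnot(inherits(dose, "dose_distribution"))
  stopifnot_same_grid(dose$grid, structures, "plan structure")
  labels <- vapply(structures, function(s) s$label, character(1))
  roles <- vapply(structures, function(s) s$role, character(1))
  for (rx in prescriptions) {
    hit <- which(labels == rx$target_label & roles %in% c("PTV", "PTV_EVAL"))
    if (length(hit) != 1) {
      stop(sprintf(
        "prescription target '%s' resolves to %d PTV/PTV_EVAL structures",
        rx$target_label, length(hit)
      ))
    }
  }
  structure(
    list(
      center_id = as.character(center_id), case_id = as.character(case_id),
      dose = dose, prescriptions = prescriptions, structures = structures,
      uses_ptv_eval = isTRUE(uses_ptv_eval)
    ),
    class = "plan_submission"
  )
}

plan_structure <- function(plan, label, roles = NULL) {
  for (s in plan$structures) {
    if (s$label == label && (is.null(roles) || s$role %in% roles)) {
      return(s)
    }
  }
  stop(sprintf("structure '%s' not found in plan %s/%s",
    label, plan$center_id, plan$case_id))
}

plan_oars <- function(plan) {
  Filter(function(s) s$role == "OAR", plan$structures)
}

# ---- geometric helpers -----------------------------------------------------

#' Distance to a structure (3D Euclidean distance transform)
#'
#' Millimetre distance from every voxel centre to the nearest occupied voxel
#' centre of `mask` (0 inside the mask), respecting anisotropic spacing.
#'
#' @param mask a non-empty [structure_mask()].
#' @return Numeric array over the grid, distances in mm.
#' @export
distance_to_mask_mm <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!any(mask$voxels)) stop("distance to an empty mask is undefined")
  d2 <- .edt_squared_cpp(mask$voxels, mask$grid$shape, mask$grid$spacing)
  d <- sqrt(d2)
  dim(d) <- mask$grid$shape
  d
}

#' Distance to a structure surface
#'
#' [distance_to_mask_mm()] measures to the nearest occupied voxel centre,
#' which overstates the distance to the structure's physical boundary: the
#' boundary lies up to half a voxel beyond the outermost centres, while
#' lattice slack around the query direction takes back roughly half of
#' that. This variant subtracts a quarter of the mean spacing (clamped at
#' zero), which centres the discretization bias on regular solids (checked
#' against continuum geometry on sphere phantoms); it is the distance used
#' by the synthetic dose falloff and the D2cm shell.
#'
#' @param mask a non-empty [structure_mask()].
#' @return Numeric array of mm distances (0 inside the mask).
#' @export
surface_distance_mm <- function(mask) {
  d <- distance_to_mask_mm(mask)
  pmax(0, d - mean(mask$grid$spacing) / 4)
}

#' Isotropic margin expansion of a mask
#'
#' Grows (or, with a negative margin, shrinks) a structure by a physical
#' margin: the expanded mask contains every voxel within `margin_mm` of the
#' input. This is the GTV-to-PTV expansion.
#'
#' @param mask a [structure_mask()].
#' @param margin_mm margin in mm (negative to erode).
#' @param label,role passed to the result; defaults keep the input label.
#' @return A [structure_mask()].
#' @export
expand_mask <- function(mask, margin_mm, label = mask$label,
                        role = mask$role) {
  if (margin_mm == 0 || !any(mask$voxels)) {
    return(structure_mask(mask$grid, mask$voxels, label, role))
  }
  if (margin_mm > 0) {
    d <- distance_to_mask_mm(mask)
    vox <- d <= margin_mm + 1e-9
  } else {
    inv <- structure_mask(mask$grid, !mask$voxels, "complement", "DOSE_REGION")
    if (!any(inv$voxels)) {
      vox <- mask$voxels
    } else {
      d <- distance_to_mask_mm(inv)
      vox <- mask$voxels & d > abs(margin_mm) + 1e-9
    }
  }
  structure_mask(mask$grid, vox, label, role)
}

#' Connected components of a mask
#'
#' 6-connectivity labeling; used to count the distinct target volumes a
#' prescription covers (the multi-PTV exemption test).
#'
#' @param mask a [structure_mask()].
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
mask_components <- function(mask) {
  lab <- .label_components_cpp(mask$voxels, mask$grid$shape)
  n <- attr(lab, "n_components")
  dim(lab) <- mask$grid$shape
  attr(lab, "n_components") <- n
  lab
}

#' Count connected components
#' @param mask a [structure_mask()].
#' @return Number of 6-connected foreground components.
#' @export
n_components <- function(mask) {
  attr(mask_components(mask), "n_components")
}

#' Voxel-centre coordinates along one axis
#' @param grid a [voxel_grid()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of mm positions of the voxel centres.
#' @export
axis_mm <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Ellipsoid phantom mask
#'
#' @param grid a [voxel_grid()].
#' @param center_mm mm triple.
#' @param radii_mm semi-axes in mm (scalar = sphere).
#' @param label,role structure metadata.
#' @return A [structure_mask()] of the voxels whose centres fall inside the
#'   ellipsoid.
#' @export
ellipsoid_mask <- function(grid, center_mm, radii_mm, label = "sphere",
                           role = "PTV") {
  radii_mm <- rep_len(as.numeric(radii_mm), 3)
  x <- (axis_mm(grid, 1) - center_mm[1]) / radii_mm[1]
  y <- (axis_mm(grid, 2) - center_mm[2]) / radii_mm[2]
  z <- (axis_mm(grid, 3) - center_mm[3]) / radii_mm[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  structure_mask(grid, r2 <= 1, label, role)
}

#' Axis-aligned box phantom mask
#'
#' @param grid a [voxel_grid()].
#' @param lo_mm,hi_mm opposite corners in mm (voxel centres inside the
#'   closed box are included).
#' @param label,role structure metadata.
#' @return A [structure_mask()].
#' @export
box_mask <- function(grid, lo_mm, hi_mm, label = "box", role = "OAR") {
  inx <- axis_mm(grid, 1) >= lo_mm[1] & axis_mm(grid, 1) <= hi_mm[1]
  iny <- axis_mm(grid, 2) >= lo_mm[2] & axis_mm(grid, 2) <= hi_mm[2]
  inz <- axis_mm(grid, 3) >= lo_mm[3] & axis_mm(grid, 3) <= hi_mm[3]
  vox <- outer(outer(inx, iny, `&`), inz, `&`)
  structure_mask(grid, vox, label, role)
}
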