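# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: four case archetypes (nodal target, multiple
# lung nodules, a thin sub-diaphragmatic rind, peritoneal blobs abutting a
# bowel-like OAR), per-center contour variants with controllable Dice
# against the reference, and dose fields whose R50%/D2cm/Dmax are known
# analytically.

CASE_ARCHETYPES <- c("NODAL", "LUNG_MULTI", "LIVER_RIND", "PERITONEAL_MULTI")

grid_center_mm <- function(grid) {
  grid$origin + (grid$shape - 1) * grid$spacing / 2
}

# Separable linear interpolation of a small array up to `shape`.
# Used to turn a coarse random control lattice into a smooth voxelwise
# displacement field.
trilinear_resize <- function(arr, shape) {
  weights <- function(n_from, n_to) {
    if (n_from == 1) {
      return(matrix(1, n_to, 1))
    }
    t <- 1 + (seq_len(n_to) - 1) / (n_to - 1) * (n_from - 1)
    i0 <- pmin(floor(t), n_from - 1)
    fr <- t - i0
    w <- matrix(0, n_to, n_from)
    w[cbind(seq_len(n_to), i0)] <- 1 - fr
    w[cbind(seq_len(n_to), i0 + 1)] <- w[cbind(seq_len(n_to), i0 + 1)] + fr
    w
  }
  d <- dim(arr)
  # axis 1
  m <- weights(d[1], shape[1]) %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(m, c(shape[1], d[2], d[3]))
  # axis 2
  a <- aperm(arr, c(2, 1, 3))
  m <- weights(d[2], shape[2]) %*% matrix(a, d[2], shape[1] * d[3])
  arr <- aperm(array(m, c(shape[2], shape[1], d[3])), c(2, 1, 3))
  # axis 3
  a <- aperm(arr, c(3, 1, 2))
  m <- weights(d[3], shape[3]) %*% matrix(a, d[3], shape[1] * shape[2])
  aperm(array(m, c(shape[3], shape[1], shape[2])), c(2, 3, 1))
}

#' Synthetic case archetype
#'
#' Builds the reference structure set for one of four case archetypes,
#' deterministically for a fixed seed:
#' * `NODAL` — one retroperitoneal-node-like target at the 165 cc PTV
#'   scale, with bowel-like OARs nearby;
#' * `LUNG_MULTI` — five small, well-separated lung nodules (PTVs around
#'   3-10.5 cc);
#' * `LIVER_RIND` — a thin curved sub-diaphragmatic shell (PTV about
#'   49 cc);
#' * `PERITONEAL_MULTI` — two small (about 16 cc) and one large (about
#'   544 cc) peritoneal blob, the large one abutting a bowel-like OAR.
#'
#' Every PTV is the matching GTV expanded isotropically by `margin_mm`.
#'
#' @param archetype_id one of `"NODAL"`, `"LUNG_MULTI"`, `"LIVER_RIND"`,
#'   `"PERITONEAL_MULTI"`.
#' @param grid_spec a [voxel_grid()]; default 128^3 voxels at 2 mm.
#' @param seed integer seed.
#' @param margin_mm GTV-to-PTV margin (default 5 mm isotropic).
#' @param case_id case identifier (defaults to the archetype id).
#' @return An object of class `case_archetype`: list with `case_id`,
#'   `archetype`, `reference_gtvs`, `reference_ptvs`, `oars`,
#'   `default_prescription`, `grid`.
#' @export
make_case <- function(archetype_id,
                      grid_spec = voxel_grid(c(128, 128, 128), 2),
                      seed = 1, margin_mm = 5, case_id = archetype_id) {
  if (!archetype_id %in% CASE_ARCHETYPES) {
    stop(
      "unknown archetype '", archetype_id, "'; expected one of ",
      paste(CASE_ARCHETYPES, collapse = ", ")
    )
  }
  grid <- grid_spec
  ctr <- grid_center_mm(grid)
  with_seed(seed, {
    jit <- function(n = 3, frac = 0.04) {
      j <- exp(rnorm(n, 0, frac))
      j / prod(j)^(1 / n) # volume-preserving anisotropy jitter
    }
    gtvs <- list()
    oars <- list()
    rx <- NULL
    if (archetype_id == "NODAL") {
      # PTV-equivalent radius ~34 mm -> ~165 cc after the 5 mm expansion
      radii <- (34 - margin_mm) * jit()
      gtvs <- list(ellipsoid_mask(grid, ctr + runif(3, -2, 2), radii,
        "GTV1", "GTV"
      ))
      oars <- list(
        box_mask(grid, ctr + c(40, -35, -35), ctr + c(95, 35, 35),
          "small_bowel", "OAR"
        ),
        box_mask(grid, ctr + c(-20, 42, -15), ctr + c(20, 62, 15),
          "duodenum", "OAR"
        )
      )
      rx <- prescription("PTV1", 35, 10)
    } else if (archetype_id == "LUNG_MULTI") {
      ptv_r <- c(9.7, 14.4, 12.9, 11.0, 12.0) # PTV radii, ~3-10.5 cc
      offs <- list(
        c(-70, -30, 40), c(65, -25, 35), c(-60, 35, -45),
        c(70, 40, -30), c(0, -60, -60)
      )
      for (i in seq_along(ptv_r)) {
        gtvs[[i]] <- ellipsoid_mask(
          grid, ctr + offs[[i]] + runif(3, -3, 3),
          (ptv_r[i] - margin_mm) * jit(frac = 0.06),
          paste0("GTV", i), "GTV"
        )
      }
      rx <- prescription("PTV1", 40, 5)
    } else if (archetype_id == "LIVER_RIND") {
      # thin spherical-shell cap hugging a dome (liver/diaphragm interface)
      shell_r <- 55 * runif(1, 0.95, 1.05)
      thick <- 4 * runif(1, 0.9, 1.1)
      cos_lim <- 0.85
      c0 <- ctr + runif(3, -2, 2)
      x <- axis_mm(grid, 1) - c0[1]
      y <- axis_mm(grid, 2) - c0[2]
      z <- axis_mm(grid, 3) - c0[3]
      r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
      r <- sqrt(r2)
      cosang <- outer(outer(x * 0, y * 0, `+`), z, `+`) / pmax(r, 1e-9)
      vox <- r >= shell_r - thick / 2 & r <= shell_r + thick / 2 &
        cosang >= cos_lim
      gtvs <- list(structure_mask(grid, vox, "GTV1", "GTV"))
      rx <- prescription("PTV1", 24, 3)
    } else { # PERITONEAL_MULTI
      big_c <- ctr + c(-15, -10, 0) + runif(3, -2, 2)
      gtvs <- list(
        ellipsoid_mask(grid, big_c, (50.6 - margin_mm) * jit(), "GTV1", "GTV"),
        ellipsoid_mask(grid, ctr + c(75, 45, 30) + runif(3, -2, 2),
          (15.6 - margin_mm) * jit(frac = 0.06), "GTV2", "GTV"
        ),
        ellipsoid_mask(grid, ctr + c(70, -55, -35) + runif(3, -2, 2),
          (15.6 - margin_mm) * jit(frac = 0.06), "GTV3", "GTV"
        )
      )
      # bowel-like OAR slab abutting the large blob
      oars <- list(box_mask(
        grid, big_c + c(38, -45, -45), big_c + c(75, 45, 45),
        "small_bowel", "OAR"
      ))
      rx <- prescription("PTV1", 35, 10)
    }
    ptvs <- lapply(seq_along(gtvs), function(i) {
      expand_mask(gtvs[[i]], margin_mm,
        label = sub("GTV", "PTV", gtvs[[i]]$label), role = "PTV"
      )
    })
    structure(
      list(
        case_id = case_id, archetype = archetype_id,
        reference_gtvs = gtvs, reference_ptvs = ptvs, oars = oars,
        default_prescription = rx, grid = grid, margin_mm = margin_mm
      ),
      class = "case_archetype"
    )
  })
}

#' @export
print.case_archetype <- function(x, ...) {
  cat(sprintf(
    "<case_archetype %s [%s]: %d GTV(s), %d PTV(s), %d OAR(s), rx %g Gy/%d fx>\n",
    x$case_id, x$archetype, length(x$reference_gtvs),
    length(x$reference_ptvs), length(x$oars),
    x$default_prescription$total_dose_gy, x$default_prescription$fractions
  ))
  invisible(x)
}

#' Perturbation settings for synthetic contour variants
#'
#' @param target_dsc Dice agreement the perturbed contour should achieve
#'   against the reference, in `[0, 1]`.
#' @param deformation_scale_mm initial displacement-magnitude bracket for
#'   the bisection (mm).
#' @param seed integer seed.
#' @param max_bisection_iters iteration cap for the magnitude search.
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(target_dsc, deformation_scale_mm = 40,
                                seed = 1, max_bisection_iters = 25) {
  if (target_dsc < 0 || target_dsc > 1) stop("target_dsc must be in [0, 1]")
  structure(
    list(
      target_dsc = target_dsc, deformation_scale_mm = deformation_scale_mm,
      seed = as.integer(seed), max_bisection_iters = max_bisection_iters
    ),
    class = "perturbation_config"
  )
}

# Apply a smooth displacement field of magnitude s (mm) to a mask:
# out(x) = ref(x - s u(x)), nearest-neighbour sampling, out-of-grid = empty.
displace_mask <- function(ref, field, s) {
  sh <- ref$grid$shape
  sp <- ref$grid$spacing
  ix <- round(field$ix - s * field$ux / sp[1])
  iy <- round(field$iy - s * field$uy / sp[2])
  iz <- round(field$iz - s * field$uz / sp[3])
  ok <- ix >= 1 & ix <= sh[1] & iy >= 1 & iy <= sh[2] & iz >= 1 & iz <= sh[3]
  out <- logical(prod(sh))
  lin <- (iz[ok] - 1) * (sh[1] * sh[2]) + (iy[ok] - 1) * sh[1] + ix[ok]
  out[ok] <- ref$voxels[lin]
  structure_mask(ref$grid, out, ref$label, ref$role)
}

make_displacement_field <- function(grid, control = 6L) {
  sh <- grid$shape
  coarse <- function() array(rnorm(control^3), c(control, control, control))
  ux <- trilinear_resize(coarse(), sh)
  uy <- trilinear_resize(coarse(), sh)
  uz <- trilinear_resize(coarse(), sh)
  rms <- sqrt(mean(ux^2 + uy^2 + uz^2))
  ix <- array(rep(seq_len(sh[1]), times = sh[2] * sh[3]), sh)
  iy <- array(rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]), sh)
  iz <- array(rep(seq_len(sh[3]), each = sh[1] * sh[2]), sh)
  list(ux = ux / rms, uy = uy / rms, uz = uz / rms, ix = ix, iy = iy, iz = iz)
}

#' Perturb a contour to a target Dice agreement
#'
#' Generates an institutional-variability stand-in: a smooth random
#' displacement field is applied to the reference mask and its magnitude is
#' tuned by bisection until the Dice coefficient against the reference lands
#' within tolerance of `cfg$target_dsc`. Deterministic per seed.
#'
#' Special cases: `target_dsc = 1` returns an exact copy; `target_dsc = 0`
#' translates the structure beyond its bounding box (gross mismatch).
#'
#' @param reference a non-empty [structure_mask()].
#' @param cfg a [perturbation_config()].
#' @return A [structure_mask()] with attribute `achieved_dsc`. Errors if the
#'   target cannot be approached within +/- 0.05 after
#'   `max_bisection_iters`, reporting the best DSC achieved.
#' @export
perturb_contour <- function(reference, cfg) {
  stopifnot(inherits(reference, "structure_mask"),
    inherits(cfg, "perturbation_config"))
  if (!any(reference$voxels)) stop("reference mask is empty")
  target <- cfg$target_dsc
  if (target >= 1) {
    out <- structure_mask(reference$grid, reference$voxels,
      reference$label, reference$role)
    attr(out, "achieved_dsc") <- 1.0
    return(out)
  }
  if (target <= 0) {
    # rigid translation past the bounding box along the roomiest axis
    idx <- which(reference$voxels, arr.ind = TRUE)
    sh <- reference$grid$shape
    extent <- apply(idx, 2, function(v) diff(range(v))) + 2L
    room_lo <- apply(idx, 2, min) - 1L
    room_hi <- sh - apply(idx, 2, max)
    ax <- which.max(pmax(room_lo, room_hi))
    shift <- if (room_hi[ax] >= room_lo[ax]) extent[ax] else -extent[ax]
    out <- logical(prod(sh))
    nidx <- idx
    nidx[, ax] <- nidx[, ax] + shift
    keep <- nidx[, ax] >= 1 & nidx[, ax] <= sh[ax]
    nidx <- nidx[keep, , drop = FALSE]
    lin <- (nidx[, 3] - 1) * sh[1] * sh[2] + (nidx[, 2] - 1) * sh[1] + nidx[, 1]
    out[lin] <- TRUE
    out <- structure_mask(reference$grid, out, reference$label, reference$role)
    attr(out, "achieved_dsc") <- as.numeric(dice(out, reference))
    return(out)
  }
  field <- with_seed(cfg$seed, make_displacement_field(reference$grid))
  f <- function(s) {
    m <- displace_mask(reference, field, s)
    list(mask = m, d = as.numeric(dice(m, reference)))
  }
  tol <- 0.015
  lo <- 0
  d_lo <- 1
  hi <- cfg$deformation_scale_mm
  cur <- f(hi)
  iters <- 0
  # grow the bracket until the target is straddled
  while (cur$d > target && iters < cfg$max_bisection_iters) {
    lo <- hi
    d_lo <- cur$d
    hi <- hi * 2
    cur <- f(hi)
    iters <- iters + 1
  }
  best <- cur
  if (abs(d_lo - target) < abs(best$d - target)) best <- f(lo)
  while (iters < cfg$max_bisection_iters && abs(best$d - target) > tol) {
    mid <- (lo + hi) / 2
    cur <- f(mid)
    iters <- iters + 1
    if (abs(cur$d - target) < abs(best$d - target)) best <- cur
    if (cur$d > target) lo <- mid else hi <- mid
  }
  if (abs(best$d - target) > 0.05) {
    stop(sprintf(
      "could not reach target DSC %.3f after %d iterations (best %.3f)",
      target, cfg$max_bisection_iters, best$d
    ))
  }
  out <- best$mask
  attr(out, "achieved_dsc") <- best$d
  out
}

#' Synthetic dose field with analytically known metrics
#'
#' Dose equals `TD x hotspot_pct / 100` inside every target and falls off
#' linearly with the Euclidean distance `d` from the nearest target surface
#' (half-voxel-corrected, see [surface_distance_mm()]):
#' `dose(d) = TD x max(0, 1 - d / falloff_mm)`. Overlapping falloffs
#' combine by voxelwise maximum (a single distance transform of the target
#' union realizes this exactly).
#'
#' @param ptvs a [structure_mask()] or non-empty list of them.
#' @param rx a [prescription()].
#' @param falloff_mm distance at which the falloff reaches zero (> 0).
#' @param hotspot_pct plateau dose as % of prescription (>= 100).
#' @return A [dose_distribution()].
#' @export
synth_dose <- function(ptvs, rx, falloff_mm = 16, hotspot_pct = 100) {
  if (inherits(ptvs, "structure_mask")) ptvs <- list(ptvs)
  if (length(ptvs) == 0) stop("`ptvs` must be non-empty")
  stopifnot(falloff_mm > 0, hotspot_pct >= 100)
  u <- union_mask(ptvs)
  if (!any(u$voxels)) stop("target union is empty")
  d <- surface_distance_mm(u)
  td <- rx$total_dose_gy
  dose <- td * pmax(0, 1 - d / falloff_mm)
  dose[u$voxels] <- td * hotspot_pct / 100
  dose_distribution(u$grid, dose)
}

#' Generate a full synthetic dummy-run cohort
#'
#' One contour submission and one plan submission per center per case. The
#' contour submissions are DSC-controlled perturbations of the case
#' reference (the pooled GTV and pooled PTV are perturbed to the scheduled
#' target); the plan submissions reuse the reference structures (as in a
#' second-phase review, where standardized volumes are distributed) with
#' per-center dose falloff and hotspot variation.
#'
#' @param archetypes named list of [make_case()] results (names = case ids).
#' @param n_centers number of centers (>= 1); center ids are `LETTERS`.
#' @param dsc_schedule numeric matrix `[center id, case id]` of target DSCs;
#'   a missing entry is an error.
#' @param seed master seed; everything downstream is reproducible from it.
#' @param falloff_range_mm,hotspot_range_pct per-center dose-field variation
#'   (uniform draws).
#' @param ptv_eval_centers character vector of center ids whose plans carry
#'   `uses_ptv_eval = TRUE`.
#' @return List with `contours` (list of [contour_submission()]) and
#'   `plans` (list of [plan_submission()]).
#' @export
make_cohort <- function(archetypes, n_centers = 10, dsc_schedule, seed = 1,
                        falloff_range_mm = c(12, 24),
                        hotspot_range_pct = c(103, 112),
                        ptv_eval_centers = character(0)) {
  stopifnot(n_centers >= 1)
  centers <- LETTERS[seq_len(n_centers)]
  case_ids <- names(archetypes)
  for (ct in centers) {
    for (cs in case_ids) {
      bad <- !(ct %in% rownames(dsc_schedule)) ||
        !(cs %in% colnames(dsc_schedule)) ||
        is.na(dsc_schedule[ct, cs])
      if (bad) stop(sprintf("dsc_schedule has no entry for (%s, %s)", ct, cs))
    }
  }
  contours <- list()
  plans <- list()
  i <- 0L
  for (ci in seq_along(centers)) {
    ct <- centers[ci]
    for (cj in seq_along(case_ids)) {
      cs <- case_ids[cj]
      ref <- archetypes[[cs]]
      i <- i + 1L
      base_seed <- (seed * 10000L + ci * 100L + cj) %% .Machine$integer.max
      tgt <- dsc_schedule[ct, cs]
      gtv_u <- union_mask(ref$reference_gtvs, label = "GTV")
      ptv_u <- union_mask(ref$reference_ptvs, label = "PTV")
      g <- perturb_contour(gtv_u, perturbation_config(tgt, seed = base_seed))
      p <- perturb_contour(ptv_u,
        perturbation_config(tgt, seed = base_seed + 1L))
      contours[[i]] <- contour_submission(ct, cs,
        gtvs = list(g), ptvs = list(p))
      pars <- with_seed(base_seed + 2L, c(
        runif(1, falloff_range_mm[1], falloff_range_mm[2]),
        runif(1, hotspot_range_pct[1], hotspot_range_pct[2])
      ))
      rx0 <- ref$default_prescription
      dose <- synth_dose(ref$reference_ptvs, rx0,
        falloff_mm = pars[1], hotspot_pct = pars[2])
      rxs <- lapply(ref$reference_ptvs, function(m) {
        prescription(m$label, rx0$total_dose_gy, rx0$fractions)
      })
      plans[[i]] <- plan_submission(ct, cs, dose, rxs,
        structures = c(ref$reference_ptvs, ref$oars),
        uses_ptv_eval = ct %in% ptv_eval_centers
      )
    }
  }
  list(contours = contours, plans = plans)
}
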