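# Plain-text readers/writers for the internal voxel formats, plus a
# slice-wise contour representation with even-odd point-in-polygon
# rasterization (the geometry that underlies structure-set ingestion).

write_grid_header <- function(grid, con, kind, extra = character(0)) {
  writeLines(c(
    sprintf("# sabrqa %s v1", kind),
    sprintf("shape: %d %d %d", grid$shape[1], grid$shape[2], grid$shape[3]),
    sprintf("spacing: %.10g %.10g %.10g",
      grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    sprintf("origin: %.10g %.10g %.10g",
      grid$origin[1], grid$origin[2], grid$origin[3]),
    extra
  ), con)
}

read_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    if (startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([a-z_]+): (.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  kv
}

num3 <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

#' Write / read a structure mask as plain text
#'
#' Header (shape, spacing, origin, label, role) followed by a run-length
#' encoding of the flattened occupancy array.
#'
#' @param mask a [structure_mask()].
#' @param path file path.
#' @return `path` invisibly for the writer; a [structure_mask()] for the
#'   reader.
#' @export
write_mask_txt <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_grid_header(mask$grid, con, "mask", c(
    sprintf("label: %s", mask$label),
    sprintf("role: %s", mask$role),
    sprintf("first: %d", as.integer(mask$voxels[1]))
  ))
  r <- rle(as.vector(mask$voxels))
  writeLines(paste(r$lengths, collapse = " "), con)
  invisible(path)
}

#' @rdname write_mask_txt
#' @export
read_mask_txt <- function(path) {
  lines <- readLines(path)
  kv <- read_header(head(lines, 7))
  shape <- as.integer(num3(kv$shape))
  grid <- voxel_grid(shape, num3(kv$spacing), num3(kv$origin))
  lens <- as.numeric(strsplit(trimws(lines[length(lines)]), "\\s+")[[1]])
  vals <- rep(rep(c(kv$first == "1", kv$first != "1"),
    length.out = length(lens)), lens)
  structure_mask(grid, vals, kv$label, kv$role)
}

#' Write / read a dose distribution as plain text
#'
#' @param dose a [dose_distribution()].
#' @param path file path.
#' @param digits significant digits kept per voxel (default 6).
#' @return `path` invisibly for the writer; a [dose_distribution()] for the
#'   reader.
#' @export
write_dose_txt <- function(dose, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  write_grid_header(dose$grid, con, "dose")
  v <- signif(as.vector(dose$dose_gy), digits)
  nx <- dose$grid$shape[1]
  writeLines(
    vapply(split(v, ceiling(seq_along(v) / nx)),
      function(row) paste(row, collapse = " "), character(1)),
    con
  )
  invisible(path)
}

#' @rdname write_dose_txt
#' @export
read_dose_txt <- function(path) {
  lines <- readLines(path)
  kv <- read_header(head(lines, 4))
  shape <- as.integer(num3(kv$shape))
  grid <- voxel_grid(shape, num3(kv$spacing), num3(kv$origin))
  body <- lines[!startsWith(lines, "#") &
    !grepl("^[a-z_]+: ", lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  dose_distribution(grid, vals)
}

#' Extract slice-wise contours from a mask
#'
#' Builds, for every occupied axial slice, the convex hull of the occupied
#' voxel centres as an (x, y) polygon. Faithful for convex (or per-slice
#' convex) structures; concave in-slice detail is not recovered, which is
#' the documented limitation of this exchange format.
#'
#' @param mask a [structure_mask()].
#' @return Data.frame with columns `label`, `role`, `slice_k`, `ring`,
#'   `x_mm`, `y_mm` (polygon vertices in order).
#' @export
contours_from_mask <- function(mask) {
  grid <- mask$grid
  xs <- axis_mm(grid, 1)
  ys <- axis_mm(grid, 2)
  rows <- list()
  n <- 0L
  for (k in seq_len(grid$shape[3])) {
    sl <- mask$voxels[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    px <- xs[idx[, 1]]
    py <- ys[idx[, 2]]
    if (nrow(idx) < 3) {
      # degenerate slice: represent as a small box around the voxels
      hx <- grid$spacing[1] / 2
      hy <- grid$spacing[2] / 2
      px <- c(min(px) - hx, max(px) + hx, max(px) + hx, min(px) - hx)
      py <- c(min(py) - hy, min(py) - hy, max(py) + hy, max(py) + hy)
    } else {
      h <- grDevices::chull(px, py)
      cx <- mean(px[h])
      cy <- mean(py[h])
      # nudge outward so hull vertices (voxel centres) rasterize as inside
      px <- cx + (px[h] - cx) * (1 + 1e-9) + sign(px[h] - cx) * 1e-6
      py <- cy + (py[h] - cy) * (1 + 1e-9) + sign(py[h] - cy) * 1e-6
    }
    n <- n + 1L
    rows[[n]] <- data.frame(
      label = mask$label, role = mask$role, slice_k = k, ring = 1L,
      x_mm = px, y_mm = py, stringsAsFactors = FALSE
    )
  }
  if (n == 0) {
    warning("mask '", mask$label, "' is empty: no contours extracted")
    return(data.frame(
      label = character(0), role = character(0), slice_k = integer(0),
      ring = integer(0), x_mm = numeric(0), y_mm = numeric(0)
    ))
  }
  do.call(rbind, rows)
}

# Even-odd (ray crossing) point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  inside <- rep(FALSE, length(px))
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize slice-wise contours to structure masks
#'
#' Slice-wise even-odd rule: a voxel centre is inside a slice's structure
#' if it is inside an odd number of that structure's rings.
#'
#' @param contours data.frame as produced by [contours_from_mask()] (or
#'   read from CSV).
#' @param grid the case [voxel_grid()].
#' @return Named list of [structure_mask()]s, one per `label`. An empty
#'   contour table yields an empty list with a warning.
#' @export
rasterize_contours <- function(contours, grid) {
  if (nrow(contours) == 0) {
    warning("empty contour set")
    return(list())
  }
  xs <- axis_mm(grid, 1)
  ys <- axis_mm(grid, 2)
  px <- rep(xs, times = grid$shape[2])
  py <- rep(ys, each = grid$shape[1])
  out <- list()
  for (lbl in unique(contours$label)) {
    sub <- contours[contours$label == lbl, , drop = FALSE]
    vox <- array(FALSE, grid$shape)
    for (k in unique(sub$slice_k)) {
      sl <- sub[sub$slice_k == k, , drop = FALSE]
      plane <- rep(FALSE, length(px))
      for (rg in unique(sl$ring)) {
        ring <- sl[sl$ring == rg, , drop = FALSE]
        plane <- xor(
          plane,
          points_in_polygon(px, py, ring$x_mm, ring$y_mm)
        )
      }
      vox[, , k] <- plane
    }
    out[[lbl]] <- structure_mask(grid, vox, lbl, sub$role[1])
  }
  out
}

#' Write / read a contour table as CSV
#'
#' @param contours data.frame from [contours_from_mask()].
#' @param path file path.
#' @return `path` invisibly for the writer; the contour data.frame for the
#'   reader.
#' @export
write_contours_csv <- function(contours, path) {
  write.csv(contours, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
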