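# Per-object 3D morphometry and localization: projection metrics (area,
# Feret diameters, aspect ratio), volume/height/sphericity, QC filtering with
# tail trimming, organelle-to-cell assignment, and apical/lateral distances.
# 2D metrics are measured on the z-projection (epithelial cells grow as a
# monolayer); 3D metrics keep all three dimensions on the physical grid.

# convex hull + rotating calipers over the corner points of the footprint
# pixels (a pixel is the closed square around its centre, so an s-pixel
# axis-aligned square has Feret diameters exactly s and s*sqrt(2))
feret_diameters <- function(foot, dx, dy) {
  w <- which(foot, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty footprint")
  # boundary pixels suffice for the hull
  inner <- foot
  inner[] <- FALSE
  if (nrow(foot) > 2 && ncol(foot) > 2)
    inner[2:(nrow(foot) - 1), 2:(ncol(foot) - 1)] <-
      foot[1:(nrow(foot) - 2), 2:(ncol(foot) - 1)] &
      foot[3:nrow(foot), 2:(ncol(foot) - 1)] &
      foot[2:(nrow(foot) - 1), 1:(ncol(foot) - 2)] &
      foot[2:(nrow(foot) - 1), 3:ncol(foot)]
  bd <- which(foot & !inner, arr.ind = TRUE)
  px <- c((bd[, 1] - 1) * dx, (bd[, 1] - 1) * dx, bd[, 1] * dx, bd[, 1] * dx)
  py <- c((bd[, 2] - 1) * dy, bd[, 2] * dy, (bd[, 2] - 1) * dy, bd[, 2] * dy)
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  n <- length(h)
  if (n == 1L) return(c(feret_min = 0, feret_max = 0))
  dmat <- outer(hx, hx, `-`)^2 + outer(hy, hy, `-`)^2
  fmax <- sqrt(max(dmat))
  # min Feret: smallest width over directions normal to hull edges
  ex <- hx[c(2:n, 1)] - hx; ey <- hy[c(2:n, 1)] - hy
  len <- sqrt(ex^2 + ey^2)
  ok <- len > 0
  widths <- vapply(which(ok), function(i) {
    nxv <- -ey[i] / len[i]; nyv <- ex[i] / len[i]
    pr <- hx * nxv + hy * nyv
    max(pr) - min(pr)
  }, numeric(1))
  c(feret_min = min(widths), feret_max = fmax)
}

#' Projection shape metrics of a 3D object
#'
#' Measures the z-projection footprint of an object: cross-sectional area,
#' minimum and maximum Feret (caliper) diameters via convex-hull rotating
#' calipers, and the aspect ratio max/min Feret (1.0 for a circle, larger for
#' elongated shapes).
#'
#' @param obj logical/integer 3D (or 2D) mask of one object.
#' @param voxel a [voxel_spec()].
#' @return list with `area` (um^2), `feret_min`, `feret_max` (um),
#'   `aspect_ratio`.
#' @examples
#' sq <- array(TRUE, c(10, 10, 1))
#' projection_metrics(sq, voxel_spec(1, 1, 1))  # feret 10 and 10*sqrt(2)
#' @export
projection_metrics <- function(obj, voxel = voxel_spec()) {
  voxel <- as_voxel_spec(voxel)
  if (length(dim(obj)) == 3L) foot <- apply(obj != 0, c(1, 2), any)
  else foot <- obj != 0
  if (!any(foot)) stop("empty object mask")
  fer <- feret_diameters(foot, voxel$dx, voxel$dy)
  list(area = sum(foot) * voxel$dx * voxel$dy,
       feret_min = unname(fer["feret_min"]),
       feret_max = unname(fer["feret_max"]),
       aspect_ratio = unname(fer["feret_max"] / fer["feret_min"]))
}

#' Volume and height of a 3D object
#'
#' Volume is the voxel count times the physical voxel volume; height is the
#' number of occupied z-planes times the plane spacing (a single-plane object
#' is one plane tall, `dz`).
#'
#' @param obj logical/integer 3D mask.
#' @param voxel a [voxel_spec()].
#' @return list with `volume` (um^3) and `height` (um).
#' @export
volume_height <- function(obj, voxel = voxel_spec()) {
  voxel <- as_voxel_spec(voxel)
  m <- obj != 0
  if (!any(m)) stop("empty object mask")
  zs <- which(apply(m, 3L, any))
  list(volume = sum(m) * voxel_volume(voxel),
       height = (max(zs) - min(zs) + 1L) * voxel$dz)
}

# Surface area of a binary object (um^2): co-area estimator, integral of
# |grad| of the Gaussian-smoothed indicator on the physical grid, evaluated
# at two smoothing scales and extrapolated linearly to sigma -> 0. Flat
# axis-aligned interfaces are exact at any sigma (the gradient sum
# telescopes); the sharp-edge rounding deficit is linear in sigma, which the
# extrapolation cancels.
surface_area <- function(obj, voxel = voxel_spec(), sigma_um = 0.35) {
  voxel <- as_voxel_spec(voxel)
  pit <- c(voxel$dx, voxel$dy, voxel$dz)
  # floor of 0.7 voxels per axis keeps the erf profile resolved on the grid;
  # the doubled scale for the extrapolation is doubled after flooring
  sig1 <- pmax(0.7, sigma_um / pit)
  a1 <- surface_area_single(obj, voxel, sig1)
  a2 <- surface_area_single(obj, voxel, 2 * sig1)
  2 * a1 - a2
}

surface_area_single <- function(obj, voxel, sig_vox) {
  m <- obj != 0
  bb <- mask_bbox(m)
  if (is.null(bb)) stop("empty object mask")
  pad <- pmax(2L, ceiling(4 * sig_vox))
  sub <- m[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
           drop = FALSE]
  d <- dim(sub) + 2L * pad
  u <- array(0, d)
  u[pad[1] + seq_len(dim(sub)[1]), pad[2] + seq_len(dim(sub)[2]),
    pad[3] + seq_len(dim(sub)[3])] <- sub
  u <- gauss_smooth3(u, sig_vox)
  ctr <- function(a, axis, h) {
    n <- dim(a)[axis]
    idx <- function(k) switch(axis,
      a[k, , , drop = FALSE], a[, k, , drop = FALSE], a[, , k, drop = FALSE])
    g <- array(0, dim(a))
    fwd <- idx(c(2:n, n)); bwd <- idx(c(1, 1:(n - 1)))
    (fwd - bwd) / (2 * h)
  }
  gx <- ctr(u, 1L, voxel$dx); gy <- ctr(u, 2L, voxel$dy)
  gz <- ctr(u, 3L, voxel$dz)
  sum(sqrt(gx^2 + gy^2 + gz^2)) * voxel_volume(voxel)
}

#' Sphericity of a 3D object
#'
#' Surface-normalized compactness \eqn{\pi^{1/3} (6V)^{2/3} / A}: 1 for a
#' perfect sphere, smaller for flatter or rougher shapes. The surface area A
#' is estimated from the 0.5 level of the smoothed binary mask (co-area
#' estimator on the physical grid). Undefined for single-plane objects,
#' which return `NA`.
#'
#' @param obj logical/integer 3D mask.
#' @param voxel a [voxel_spec()].
#' @return sphericity in (0, 1\]; `NA_real_` for single-plane objects.
#' @export
sphericity <- function(obj, voxel = voxel_spec()) {
  voxel <- as_voxel_spec(voxel)
  m <- obj != 0
  if (!any(m)) stop("empty object mask")
  if (length(unique(which(m, arr.ind = TRUE)[, 3])) < 2L) return(NA_real_)
  V <- sum(m) * voxel_volume(voxel)
  A <- surface_area(m, voxel)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

# iterate over labels of a volume with bounding-box cropping
label_bboxes <- function(vol) {
  w <- which(vol > 0)
  if (!length(w)) return(list())
  d <- dim(vol)
  x <- (w - 1) %% d[1] + 1
  y <- ((w - 1) %/% d[1]) %% d[2] + 1
  z <- (w - 1) %/% (d[1] * d[2]) + 1
  lab <- vol[w]
  sp <- split(data.frame(x = x, y = y, z = z), lab)
  lapply(sp, function(s) list(
    bb = rbind(c(min(s$x), min(s$y), min(s$z)), c(max(s$x), max(s$y), max(s$z))),
    n = nrow(s),
    centroid_idx = c(mean(s$x), mean(s$y), mean(s$z))))
}

#' Morphometry table for every cell in a label volume
#'
#' Computes the full per-cell record: volume, height, projection metrics,
#' sphericity, centroid (um), and a border-touching flag (any voxel on a
#' lateral, top or bottom face of the stack).
#'
#' @param cells integer 3D label volume.
#' @param voxel a [voxel_spec()].
#' @param fov field-of-view identifier carried into the table.
#' @param condition optional named list of condition keys (treatment, week,
#'   line, ...) added as constant columns.
#' @return data.frame, one row per cell label.
#' @export
cell_morphometry <- function(cells, voxel = voxel_spec(), fov = 1L,
                             condition = NULL) {
  voxel <- as_voxel_spec(voxel)
  info <- label_bboxes(cells)
  if (!length(info)) stop("no cells in volume")
  d <- dim(cells)
  rows <- lapply(names(info), function(id) {
    i <- as.integer(id); bi <- info[[id]]
    bb <- bi$bb
    sub <- cells[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
                 drop = FALSE] == i
    vh <- volume_height(sub, voxel)
    pm <- projection_metrics(sub, voxel)
    sp <- sphericity(sub, voxel)
    data.frame(
      fov = fov, cell = i,
      volume = vh$volume, height = vh$height,
      area = pm$area, feret_min = pm$feret_min, feret_max = pm$feret_max,
      aspect_ratio = pm$aspect_ratio, sphericity = sp,
      centroid_x = bi$centroid_idx[1] * voxel$dx - voxel$dx / 2,
      centroid_y = bi$centroid_idx[2] * voxel$dy - voxel$dy / 2,
      centroid_z = bi$centroid_idx[3] * voxel$dz - voxel$dz / 2,
      apical_plane = bb[2, 3],
      border_touching = bb[1, 1] == 1L || bb[2, 1] == d[1] ||
        bb[1, 2] == 1L || bb[2, 2] == d[2] ||
        bb[1, 3] == 1L || bb[2, 3] == d[3])
  })
  out <- do.call(rbind, rows)
  if (!is.null(condition)) for (nm in names(condition)) out[[nm]] <- condition[[nm]]
  rownames(out) <- NULL
  out
}

#' Quality-control configuration
#'
#' Default cutoffs: volume within \[50, 100000\] um^3, width (min Feret of
#' the projection) at least 1.5 um, height at least 1.0 um, and trimming of
#' the top and bottom 5 percent of each shape metric at the single-cell
#' level. Objects outside the hard cutoffs are segmentation artifacts, not
#' biology; the distribution tails are trimmed because segmentation errors
#' concentrate there.
#'
#' @param volume_min,volume_max volume window, um^3.
#' @param min_width minimum width (min Feret), um.
#' @param min_height minimum height, um.
#' @param tail_fraction fraction trimmed from each tail per metric, in
#'   \[0, 0.5).
#' @param exclude_border drop cells touching the stack boundary.
#' @return A `qc_config` list.
#' @export
qc_config <- function(volume_min = 50, volume_max = 1e5, min_width = 1.5,
                      min_height = 1.0, tail_fraction = 0.05,
                      exclude_border = TRUE) {
  if (tail_fraction < 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in [0, 0.5)")
  structure(list(volume_min = volume_min, volume_max = volume_max,
                 min_width = min_width, min_height = min_height,
                 tail_fraction = tail_fraction,
                 exclude_border = exclude_border), class = "qc_config")
}

#' Filter a cell table by the QC rules
#'
#' Applies, in order: removal of border-touching cells; the volume window;
#' the width and height minima; then per-metric trimming of the top and
#' bottom `tail_fraction` of values (rows keep their other metrics -- the
#' trimmed metric is set to `NA`, preserving per-metric n). A removal log
#' records one row per (cell, reason). Trimming is recorded in the result's
#' provenance, so applying the filter a second time at the same thresholds
#' is a no-op.
#'
#' @param cells data.frame from [cell_morphometry()].
#' @param cfg a [qc_config()].
#' @param metrics shape metrics to trim.
#' @return list with `cells` (filtered table), `log` (data.frame cell /
#'   metric / reason).
#' @export
qc_filter <- function(cells, cfg = qc_config(),
                      metrics = c("volume", "height", "area", "feret_min",
                                  "feret_max", "aspect_ratio", "sphericity")) {
  if (nrow(cells) == 0L) stop("empty cell table")
  log <- data.frame(cell = integer(0), metric = character(0),
                    reason = character(0))
  note <- function(ids, metric, reason) {
    if (length(ids))
      log <<- rbind(log, data.frame(cell = ids, metric = metric,
                                    reason = reason))
  }
  trimmed_before <- isTRUE(attr(cells, "qc_tail_trimmed"))
  drop_where <- function(cells, bad_idx, metric, reason) {
    note(cells$cell[bad_idx], metric, reason)
    if (length(bad_idx)) cells <- cells[-bad_idx, , drop = FALSE]
    cells
  }
  if (isTRUE(cfg$exclude_border) && "border_touching" %in% names(cells))
    cells <- drop_where(cells, which(cells$border_touching), "",
                        "border_touching")
  cells <- drop_where(cells, which(cells$volume < cfg$volume_min),
                      "volume", sprintf("volume<%g", cfg$volume_min))
  cells <- drop_where(cells, which(cells$volume > cfg$volume_max),
                      "volume", sprintf("volume>%g", cfg$volume_max))
  cells <- drop_where(cells, which(cells$feret_min < cfg$min_width),
                      "feret_min", sprintf("width<%g", cfg$min_width))
  cells <- drop_where(cells, which(cells$height < cfg$min_height),
                      "height", sprintf("height<%g", cfg$min_height))
  if (!trimmed_before && cfg$tail_fraction > 0) {
    for (m in intersect(metrics, names(cells))) {
      v <- cells[[m]]
      ok <- which(!is.na(v))
      k <- floor(cfg$tail_fraction * length(ok))
      if (k < 1L) next
      o <- ok[order(v[ok])]
      lo <- o[seq_len(k)]
      hi <- o[seq.int(length(o) - k + 1L, length(o))]
      note(cells$cell[lo], m, "tail_low")
      note(cells$cell[hi], m, "tail_high")
      cells[[m]][c(lo, hi)] <- NA
    }
    attr(cells, "qc_tail_trimmed") <- TRUE
  }
  rownames(cells) <- NULL
  list(cells = cells, log = log)
}

#' Assign organelle objects to their parent cells
#'
#' Each organelle label is assigned to the cell containing the majority of
#' its voxels. Objects whose voxels lie mostly in the background are dropped
#' and logged; exact ties between cells go to the lower cell id (logged).
#'
#' @param organelles,cells integer label volumes on the same grid.
#' @return list with `parents` (named integer vector, organelle id ->
#'   cell id) and `log` (dropped / tie records).
#' @export
assign_to_cells <- function(organelles, cells) {
  if (!identical(dim(organelles), dim(cells))) stop("grids differ")
  w <- which(organelles > 0)
  log <- data.frame(object = integer(0), note = character(0))
  if (!length(w)) return(list(parents = integer(0), log = log))
  ol <- organelles[w]; cl <- cells[w]
  sizes <- table(ol)
  tb <- table(ol[cl > 0], cl[cl > 0])
  parents <- integer(0)
  for (id in names(sizes)) {
    tot <- as.integer(sizes[[id]])
    counts <- if (id %in% rownames(tb))
      stats::setNames(as.integer(tb[id, ]), colnames(tb))
    else integer(0)
    counts <- counts[counts > 0]
    bg <- tot - sum(counts)
    if (!length(counts) || bg > tot / 2) {
      log <- rbind(log, data.frame(object = as.integer(id),
                                   note = "majority_background"))
      next
    }
    best <- max(counts)
    winners <- as.integer(names(counts)[counts == best])
    if (length(winners) > 1L)
      log <- rbind(log, data.frame(object = as.integer(id),
                                   note = "tie_lowest_id"))
    parents[id] <- min(winners)
  }
  list(parents = parents, log = log)
}

#' Localization of organelles within their parent cells
#'
#' For every organelle object: `lateral_distance`, the 2D distance from the
#' closest organelle voxel to the closest lateral cell border (distance
#' transform of the parent-cell z-projection footprint); `apical_distance`,
#' the z distance from the object's highest voxel to the cell's apical
#' border (its top occupied plane), clipped at 0; and `centroid_offset`, the
#' 3D distance between organelle and cell centroids. When a nucleus volume
#' is supplied, the offset of the organelle centroid from the parent nucleus
#' centroid is also reported (`nucleus_dz`, signed, apical positive, and
#' `nucleus_dist`) -- the reference used for nucleolar structures.
#' Organelles with voxels outside their parent footprint are flagged with a
#' negative lateral distance and logged.
#'
#' @param organelles integer organelle label volume.
#' @param cells integer cell label volume on the same grid.
#' @param parents assignment from [assign_to_cells()] (computed if missing).
#' @param voxel a [voxel_spec()].
#' @param nuclei optional nucleus label volume (parent-matched ids).
#' @param class_name structure class carried into the table.
#' @return data.frame, one row per assigned organelle.
#' @export
localization <- function(organelles, cells, parents = NULL,
                         voxel = voxel_spec(), nuclei = NULL,
                         class_name = "organelle") {
  voxel <- as_voxel_spec(voxel)
  if (is.null(parents)) parents <- assign_to_cells(organelles, cells)$parents
  if (!length(parents))
    return(data.frame(object = integer(0)))
  if (is.null(names(parents))) names(parents) <- seq_along(parents)
  d <- dim(cells)
  cell_ids <- sort(unique(parents))
  foot_edt <- list(); foot_edt_out <- list(); apical <- numeric(0)
  cent_cell <- list(); cent_nuc <- list()
  for (ci in cell_ids) {
    m <- cells == ci
    foot <- apply(m, c(1, 2), any)
    foot_edt[[as.character(ci)]] <- edt2d(foot, voxel$dx, voxel$dy)
    foot_edt_out[[as.character(ci)]] <- edt2d(!foot, voxel$dx, voxel$dy,
                                              border_is_background = FALSE)
    zs <- which(apply(m, 3L, any))
    apical[as.character(ci)] <- max(zs)
    wc <- which(m, arr.ind = TRUE)
    cent_cell[[as.character(ci)]] <-
      c(mean(wc[, 1]) * voxel$dx, mean(wc[, 2]) * voxel$dy,
        mean(wc[, 3]) * voxel$dz)
    if (!is.null(nuclei)) {
      wn <- which(nuclei == ci, arr.ind = TRUE)
      if (nrow(wn))
        cent_nuc[[as.character(ci)]] <-
          c(mean(wn[, 1]) * voxel$dx, mean(wn[, 2]) * voxel$dy,
            mean(wn[, 3]) * voxel$dz)
    }
  }
  w <- which(organelles > 0)
  x <- (w - 1) %% d[1] + 1
  y <- ((w - 1) %/% d[1]) %% d[2] + 1
  z <- (w - 1) %/% (d[1] * d[2]) + 1
  lab <- organelles[w]
  sp <- split(seq_along(w), lab)
  rows <- lapply(names(sp), function(id) {
    if (!id %in% names(parents)) return(NULL)
    ci <- parents[[id]]
    key <- as.character(ci)
    ii <- sp[[id]]
    ein <- foot_edt[[key]][cbind(x[ii], y[ii])]
    eout <- foot_edt_out[[key]][cbind(x[ii], y[ii])]
    signed <- ifelse(ein > 0, ein, -eout)
    lat <- min(signed)
    cx <- mean(x[ii]) * voxel$dx; cy <- mean(y[ii]) * voxel$dy
    cz <- mean(z[ii]) * voxel$dz
    cc <- cent_cell[[key]]
    out <- data.frame(
      object = as.integer(id), cell = ci, class = class_name,
      volume = length(ii) * voxel_volume(voxel),
      centroid_x = cx, centroid_y = cy, centroid_z = cz,
      lateral_distance = lat,
      apical_distance = max(0, (apical[[key]] - max(z[ii])) * voxel$dz),
      centroid_offset = sqrt(sum((c(cx, cy, cz) - cc)^2)),
      outside_footprint = lat < 0)
    if (!is.null(nuclei) && !is.null(cent_nuc[[key]])) {
      cn <- cent_nuc[[key]]
      out$nucleus_dz <- cz - cn[3]
      out$nucleus_dist <- sqrt(sum((c(cx, cy, cz) - cn)^2))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell organelle summaries and FOV aggregation
#'
#' Per cell and structure class: object count, mean and total object volume,
#' and the relative volume fraction (percent of the cell volume occupied).
#' `fov_summary()` then averages every cell-level metric over the cells of
#' each field of view -- the FOV is the statistical unit downstream.
#'
#' @param cell_records data.frame from [cell_morphometry()] (possibly
#'   QC-filtered).
#' @param organelle_records data.frame from [localization()] (may be empty).
#' @return `per_cell_summaries`: one row per cell x class;
#'   `fov_summary`: one row per fov x class with columns `n_cells` and the
#'   means of all numeric metrics.
#' @export
per_cell_summaries <- function(cell_records, organelle_records) {
  cls <- unique(organelle_records$class)
  if (is.null(cls)) cls <- character(0)
  base <- cell_records[, c("fov", "cell", "volume", "height", "area",
                           "feret_min", "feret_max", "aspect_ratio",
                           "sphericity")]
  names(base)[3:9] <- paste0("cell_", names(base)[3:9])
  out <- list()
  for (cl in if (length(cls)) cls else NA_character_) {
    b <- base
    b$class <- cl
    if (!is.na(cl) && nrow(organelle_records)) {
      o <- organelle_records[organelle_records$class == cl, ]
      agg <- function(f, v) stats::aggregate(o[[v]], list(cell = o$cell), f)
      cnt <- as.data.frame(table(cell = o$cell), stringsAsFactors = FALSE)
      b$count <- cnt$Freq[match(b$cell, as.integer(cnt$cell))]
      b$count[is.na(b$count)] <- 0L
      for (v in c("volume", "lateral_distance", "apical_distance",
                  "centroid_offset")) {
        a <- agg(mean, v)
        b[[paste0("org_", v)]] <- a$x[match(b$cell, a$cell)]
      }
      tv <- agg(sum, "volume")
      b$org_total_volume <- tv$x[match(b$cell, tv$cell)]
      b$org_total_volume[is.na(b$org_total_volume)] <- 0
      b$relative_fraction <- 100 * b$org_total_volume / b$cell_volume
    } else {
      b$count <- 0L; b$org_total_volume <- 0; b$relative_fraction <- 0
    }
    out[[length(out) + 1L]] <- b
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname per_cell_summaries
#' @export
fov_summary <- function(cell_records, organelle_records) {
  pc <- per_cell_summaries(cell_records, organelle_records)
  num <- names(pc)[vapply(pc, is.numeric, logical(1))]
  num <- setdiff(num, c("fov", "cell"))
  sp <- split(pc, list(fov = pc$fov, class = pc$class), drop = TRUE)
  rows <- lapply(sp, function(s) {
    r <- data.frame(fov = s$fov[1], class = s$class[1],
                    n_cells = nrow(s))
    for (v in num) r[[v]] <- mean(s[[v]], na.rm = TRUE)
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
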