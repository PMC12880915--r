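# Synthetic epithelial monolayer phantoms: hexagonally packed prismatic cells
# with ellipsoidal nuclei and organelles drawn from class-specific placement
# laws, plus paired intensity channels (Gaussian PSF + Poisson/Gaussian noise).
# Phantoms carry voxel-exact ground truth so every downstream stage of the
# pipeline can be tested without microscopy data.

# Evaluate code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an integer 'seed' is required")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lo = mean - 3 * sd, hi = mean + 3 * sd) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Regular hexagon helpers. Orientation: vertices at 30 + k*60 degrees, edge
# normals at k*60 degrees; apothem a = sqrt(3)/2 * R (circumradius R).
# width := average of min (sqrt(3) R) and max (2 R) Feret diameters.
hex_R_from_width <- function(width) 2 * width / (2 + sqrt(3))
hex_width_from_R <- function(R) R * (2 + sqrt(3)) / 2

# inside test for points (x, y) relative to the hexagon centre; optional
# elongation stretches the shape along its local x-axis before the test.
hex_inside <- function(x, y, R, elongation = 1) {
  x <- x / elongation
  a <- sqrt(3) / 2 * R
  u1 <- abs(x)
  u2 <- abs(0.5 * x + sqrt(3) / 2 * y)
  u3 <- abs(-0.5 * x + sqrt(3) / 2 * y)
  pmax(u1, u2, u3) <= a
}

# distance from centre to the hexagon boundary along direction phi (radians)
hex_radius_at <- function(phi, R) {
  a <- sqrt(3) / 2 * R
  th <- (0:5) * pi / 3
  den <- vapply(phi, function(p) max(cos(p - th)), numeric(1))
  a / den
}

# z-planes whose centres fall in (z0, z0 + h]; plane k centre = (k - 0.5) dz
planes_in <- function(z0, h, dz, nz) {
  k <- seq_len(nz)
  which((k - 0.5) * dz > z0 & (k - 0.5) * dz <= z0 + h)
}

#' Generate a hexagonal-prism test cell
#'
#' Rasterizes a single regular hexagonal prism of known circumradius and
#' height on an (an)isotropic voxel grid, by centre-of-voxel inclusion. This
#' is the classical quality-control object: every morphometric quantity of
#' the prism has a closed form (volume \eqn{(3\sqrt3/2) R^2 h}, max Feret
#' \eqn{2R}, min Feret \eqn{\sqrt3 R}, ...), so measured values can be checked
#' against analytic ones to within rasterization error.
#'
#' @param circumradius hexagon circumradius R in um (centre to vertex).
#' @param height prism height in um.
#' @param voxel a [voxel_spec()].
#' @param margin_um empty margin around the object, um.
#' @return Integer 3D label array (1 = prism, 0 = background) with the voxel
#'   spec attached as attribute `"voxel"`.
#' @examples
#' p <- generate_hexagonal_prism(10, 5)
#' sum(p > 0) * prod(unlist(voxel_spec())[1:3])  # ~ 1299 um^3
#' @export
generate_hexagonal_prism <- function(circumradius, height,
                                     voxel = voxel_spec(), margin_um = 1) {
  voxel <- as_voxel_spec(voxel)
  if (circumradius < 3 * max(voxel$dx, voxel$dy))
    stop("circumradius below voxel resolution (need >= 3 lateral pitches)")
  if (height < voxel$dz)
    stop("height below voxel resolution (need >= one z pitch)")
  R <- circumradius
  cx <- R + margin_um; cy <- R + margin_um
  nxp <- ceiling((2 * R + 2 * margin_um) / voxel$dx)
  nyp <- ceiling((2 * R + 2 * margin_um) / voxel$dy)
  z0 <- voxel$dz  # one empty basal plane
  nzp <- ceiling((z0 + height) / voxel$dz) + 1L
  xs <- axis_centers(nxp, voxel$dx) - cx
  ys <- axis_centers(nyp, voxel$dy) - cy
  foot <- outer(xs, ys, function(x, y) hex_inside(x, y, R))
  vol <- array(0L, c(nxp, nyp, nzp))
  zz <- planes_in(z0, height, voxel$dz, nzp)
  vol[, , zz] <- rep(as.integer(foot), length(zz))
  attr(vol, "voxel") <- voxel
  vol
}

# rasterize an ellipsoid (centre um, semi-axes um) into an existing array,
# returning linear indices of inside voxels (centre-of-voxel inclusion)
ellipsoid_indices <- function(dims, voxel, center, semi) {
  lo <- pmax(1L, floor((center - semi) / c(voxel$dx, voxel$dy, voxel$dz)))
  hi <- pmin(dims, ceiling((center + semi) / c(voxel$dx, voxel$dy, voxel$dz)) + 1L)
  if (any(lo > hi)) return(integer(0))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  ex <- ((ix - 0.5) * voxel$dx - center[1]) / semi[1]
  ey <- ((iy - 0.5) * voxel$dy - center[2]) / semi[2]
  ez <- ((iz - 0.5) * voxel$dz - center[3]) / semi[3]
  g <- outer(outer(ex^2, ey^2, `+`), ez^2, `+`) <= 1
  w <- which(g, arr.ind = TRUE)
  if (nrow(w) == 0L) return(integer(0))
  (ix[w[, 1]]) + dims[1] * ((iy[w[, 2]] - 1L) + dims[2] * (iz[w[, 3]] - 1L))
}

#' Generate a synthetic RPE monolayer phantom
#'
#' Draws a hexagonally packed monolayer of prismatic cells whose per-cell
#' heights and widths are jittered around the supplied polarity state, with
#' one ellipsoidal nucleus per cell, and synthesizes the matching cell-border
#' and nucleus intensity channels. The ground truth (cell and nucleus label
#' volumes plus a per-cell provenance table) is exact by construction.
#'
#' Cells sit on a regular hexagonal lattice with centre jitter; lattice
#' spacing is chosen so that no two sampled footprints can collide, leaving a
#' thin intercellular gap that plays the role of the border stain. The basal
#' plane of every cell is one z-plane above the stack bottom, so interior
#' cells never touch the stack boundary; a `border_touching` flag is computed
#' from the rasterized labels regardless.
#'
#' @param n_cells_x,n_cells_y lattice dimensions (>= 2 each).
#' @param state a [polarity_state()].
#' @param voxel a [voxel_spec()].
#' @param seed integer RNG seed (one stream per dataset).
#' @param jitter_um centre jitter amplitude, um.
#' @param gap_um intercellular gap, um.
#' @param margin_um lateral margin, um.
#' @param field_um optional c(x, y) physical field limit; an error is raised
#'   if the requested grid cannot fit.
#' @param make_intensity synthesize intensity channels (default TRUE).
#' @param snr signal-to-noise ratio of the synthesized channels.
#' @return A `phantom_dataset`: list with `cells`, `nuclei` (integer label
#'   volumes), `channels` (named list of intensity volumes), `cells_table`
#'   (per-cell provenance), `organelles` (filled by [sample_organelles()]),
#'   `state`, `voxel`, `seed`.
#' @examples
#' ph <- generate_monolayer(2, 2, polarity_state("polarized"), seed = 1,
#'                          voxel = voxel_spec(0.434, 0.434, 0.5),
#'                          make_intensity = FALSE)
#' max(ph$cells)
#' @export
generate_monolayer <- function(n_cells_x, n_cells_y,
                               state = polarity_state(),
                               voxel = voxel_spec(), seed = 0,
                               jitter_um = 0.3, gap_um = 0.6, margin_um = 1,
                               field_um = NULL, make_intensity = TRUE,
                               snr = 10) {
  voxel <- as_voxel_spec(voxel)
  if (n_cells_x < 2 || n_cells_y < 2) stop("grid must be at least 2 x 2 cells")
  stopifnot(inherits(state, "polarity_state"))
  with_seed(seed, {
    n <- n_cells_x * n_cells_y
    h <- rnorm_trunc(n, state$cell_height_mean, state$cell_height_sd)
    h <- pmax(h, 2 * voxel$dz)
    w <- rnorm_trunc(n, state$cell_width_mean, state$cell_width_sd)
    R <- hex_R_from_width(w)
    s <- sqrt(3) * max(R) + gap_um       # flat-to-flat lattice spacing
    jit <- min(jitter_um, 0.45 * gap_um)
    col <- rep(seq_len(n_cells_x) - 1L, n_cells_y)
    row <- rep(seq_len(n_cells_y) - 1L, each = n_cells_x)
    cx <- margin_um + (col + 0.5 + 0.5 * (row %% 2)) * s +
      stats::runif(n, -jit, jit)
    cy <- margin_um + (0.5 + row * sqrt(3) / 2) * s + stats::runif(n, -jit, jit)
    Xext <- max(cx) + max(R) + margin_um
    Yext <- max(cy) + max(R) + margin_um
    if (!is.null(field_um) && (Xext > field_um[1] || Yext > field_um[2]))
      stop("requested cell widths/grid exceed the field size")
    nxp <- ceiling(Xext / voxel$dx)
    nyp <- ceiling(Yext / voxel$dy)
    z0 <- voxel$dz
    nzp <- ceiling((z0 + max(h)) / voxel$dz) + 2L
    dims <- c(nxp, nyp, nzp)
    cells <- array(0L, dims)
    nuclei <- array(0L, dims)
    xs <- axis_centers(nxp, voxel$dx)
    ys <- axis_centers(nyp, voxel$dy)
    nuc_a <- numeric(n); nuc_c <- numeric(n); nuc_zc <- numeric(n)
    for (i in seq_len(n)) {
      ix <- which(xs >= cx[i] - R[i] & xs <= cx[i] + R[i])
      iy <- which(ys >= cy[i] - R[i] & ys <= cy[i] + R[i])
      foot <- outer(xs[ix] - cx[i], ys[iy] - cy[i],
                    function(x, y) hex_inside(x, y, R[i]))
      zz <- planes_in(z0, h[i], voxel$dz, nzp)
      idx2 <- which(foot, arr.ind = TRUE)
      if (nrow(idx2) == 0L) next
      lin2 <- ix[idx2[, 1]] + nxp * (iy[idx2[, 2]] - 1L)
      for (k in zz) cells[lin2 + as.double(nxp) * nyp * (k - 1L)] <- i
      # nucleus: ellipsoid clipped to the parent cell
      apoth <- sqrt(3) / 2 * R[i]
      a <- min(state$nucleus_width_mean / 2, 0.8 * apoth)
      cz <- min(state$nucleus_height_mean / 2, (h[i] - 2 * voxel$dz) / 2)
      cz <- max(cz, voxel$dz / 2)
      zcen <- z0 + min(max(state$nucleus_center_frac * h[i], cz + 0.05),
                       h[i] - cz - 0.05)
      nidx <- ellipsoid_indices(dims, voxel, c(cx[i], cy[i], zcen),
                                c(a, a, cz))
      nidx <- nidx[cells[nidx] == i]
      nuclei[nidx] <- i
      nuc_a[i] <- a; nuc_c[i] <- cz; nuc_zc[i] <- zcen
    }
    border_touching <- vapply(seq_len(n), function(i) {
      w3 <- which(cells == i, arr.ind = TRUE)
      any(w3[, 1] %in% c(1L, nxp)) || any(w3[, 2] %in% c(1L, nyp)) ||
        any(w3[, 3] %in% c(1L, nzp))
    }, logical(1))
    cells_table <- data.frame(
      cell = seq_len(n), cx = cx, cy = cy, circumradius = R,
      width = w, height = h, z0 = z0,
      apothem = sqrt(3) / 2 * R,
      nucleus_a = nuc_a, nucleus_c = nuc_c, nucleus_zc = nuc_zc,
      border_touching = border_touching)
    channels <- list()
    if (make_intensity) {
      border <- array(0, dims)
      for (k in seq_len(nzp)) {
        pl <- cells[, , k]
        if (!any(pl > 0)) next
        grown <- dilate_plane(pl, radius = max(1L, ceiling(gap_um / voxel$dx)))
        border[, , k] <- as.numeric(grown > 0 & pl == 0)
      }
      channels$border <- synth_intensity(border, voxel, snr = snr)
      channels$nucleus <- synth_intensity(nuclei > 0, voxel, snr = snr)
    }
    attr(cells, "voxel") <- voxel
    attr(nuclei, "voxel") <- voxel
    structure(list(cells = cells, nuclei = nuclei, channels = channels,
                   cells_table = cells_table, organelles = list(),
                   state = state, voxel = voxel, seed = seed),
              class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  d <- dim(x$cells)
  cat(sprintf(
    "phantom_dataset: %d cells, %d x %d x %d voxels, state '%s', seed %s\n",
    nrow(x$cells_table), d[1], d[2], d[3], x$state$label,
    format(x$seed)))
  if (length(x$organelles))
    cat("  organelle channels:", paste(names(x$organelles), collapse = ", "),
        "\n")
  invisible(x)
}

#' Synthesize a fluorescence channel from a binary structure map
#'
#' Convolves the structure indicator with an isotropic Gaussian PSF (sigma one
#' voxel laterally, half a plane axially, by default) and adds Poisson shot
#' noise plus Gaussian read noise. The SNR is defined as peak signal over the
#' read-noise SD.
#'
#' @param mask logical/numeric 3D array (structure present / amplitude).
#' @param voxel a [voxel_spec()] (kept for interface symmetry; the PSF is
#'   specified in voxel units).
#' @param amplitude peak photon count of the clean signal.
#' @param snr ratio amplitude / read-noise SD.
#' @param psf_sigma_vox PSF sigma per axis in voxels.
#' @return Numeric 3D array, non-negative.
#' @export
synth_intensity <- function(mask, voxel = voxel_spec(), amplitude = 100,
                            snr = 10, psf_sigma_vox = c(1, 1, 0.5)) {
  sig <- amplitude * gauss_smooth3(array(as.numeric(mask != 0), dim(mask)),
                                   psf_sigma_vox)
  shot <- array(stats::rpois(length(sig), pmax(sig, 0)), dim(sig))
  read <- array(stats::rnorm(length(sig), 0, amplitude / snr), dim(sig))
  out <- pmax(shot + read, 0)
  array(out, dim(sig))
}

#' Add organelles of one class to a phantom
#'
#' Draws organelle instances for every cell of a phantom monolayer according
#' to the class's archetype (spot, blob, filament, shell) and placement law,
#' with per-cell counts Poisson-distributed around the state's class mean.
#' Objects are clipped to their parent cell, so ground-truth containment is
#' exact. Placement laws:
#' apical-central objects are centred above the parent-nucleus centroid plane
#' and within half the lateral radius; basal-central is its mirror below the
#' nucleus plane (same lateral law); perinuclear objects hug the nucleus
#' border; lateral-dispersed objects are uniform in the cell; border-bound
#' objects sit against the lateral border.
#'
#' @param cells integer cell label volume (or a `phantom_dataset`).
#' @param class_name one of the classes in the state's organelle table.
#' @param state a [polarity_state()]; defaults to the phantom's own state.
#' @param seed RNG seed.
#' @param nuclei nucleus label volume (required for nucleus-referenced laws;
#'   taken from the phantom when `cells` is a `phantom_dataset`).
#' @param cells_table per-cell provenance table (from the phantom).
#' @param voxel a [voxel_spec()].
#' @param snr,make_intensity intensity-channel synthesis controls.
#' @param count_mean,object_volume_mean optional overrides of the class table.
#' @param placement optional override of the class placement law.
#' @return If `cells` is a `phantom_dataset`, the phantom with the new channel
#'   appended under `organelles[[class_name]]`; otherwise a list with
#'   `labels`, `intensity`, `parents` (named integer vector object -> cell).
#' @export
sample_organelles <- function(cells, class_name, state = NULL, seed = 0,
                              nuclei = NULL, cells_table = NULL,
                              voxel = NULL, snr = 10, make_intensity = TRUE,
                              count_mean = NULL, object_volume_mean = NULL,
                              placement = NULL) {
  ph <- NULL
  if (inherits(cells, "phantom_dataset")) {
    ph <- cells
    if (is.null(state)) state <- ph$state
    if (is.null(nuclei)) nuclei <- ph$nuclei
    if (is.null(cells_table)) cells_table <- ph$cells_table
    if (is.null(voxel)) voxel <- ph$voxel
    cells <- ph$cells
  }
  if (is.null(state)) stop("a polarity_state is required")
  if (is.null(voxel)) voxel <- attr(cells, "voxel")
  voxel <- as_voxel_spec(voxel)
  if (!any(cells > 0)) stop("cell volume is empty")
  cls <- state$organelles
  if (!class_name %in% cls$class)
    stop(sprintf("unknown organelle class '%s'; known: %s", class_name,
                 paste(cls$class, collapse = ", ")))
  row <- cls[cls$class == class_name, ]
  if (!is.null(count_mean)) row$count_mean <- count_mean
  if (!is.null(object_volume_mean)) row$object_volume_mean <- object_volume_mean
  if (!is.null(placement)) row$placement <- placement
  if (is.null(cells_table))
    stop("cells_table (per-cell provenance) is required")
  needs_nuc <- row$placement %in% c("apical-central", "perinuclear") ||
    row$archetype == "shell"
  if (needs_nuc && is.null(nuclei))
    stop("nuclei are required for the '", row$placement, "' placement law")
  dims <- dim(cells)
  res <- with_seed(seed, {
    labels <- array(0L, dims)
    parents <- integer(0)
    next_id <- 0L
    for (i in cells_table$cell) {
      ct <- cells_table[cells_table$cell == i, ]
      if (row$archetype == "shell") {
        # one shell per cell on the nucleus surface
        nmask <- nuclei == i
        if (!any(nmask)) next
        bb <- mask_bbox(nmask)
        sub <- nmask[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
                     drop = FALSE]
        d <- edt3d(sub, voxel)
        shell <- sub & d <= max(0.35, voxel$dz * 0.71)
        next_id <- next_id + 1L
        tgt <- labels[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2],
                      bb[1, 3]:bb[2, 3], drop = FALSE]
        tgt[shell] <- next_id
        labels[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3]] <- tgt
        parents[next_id] <- i
        next
      }
      k <- stats::rpois(1L, row$count_mean)
      if (k == 0L) next
      for (j in seq_len(k)) {
        V <- max(row$object_volume_mean *
                   exp(stats::rnorm(1, 0, 0.25) - 0.25^2 / 2),
                 2 * voxel_volume(voxel))
        r <- (3 * V / (4 * pi))^(1 / 3)
        zlo <- ct$z0; zhi <- ct$z0 + ct$height
        pos <- switch(row$placement,
          "apical-central" = {
            rho <- 0.5 * ct$apothem * sqrt(stats::runif(1))
            phi <- stats::runif(1, 0, 2 * pi)
            zc <- stats::runif(1, min(ct$nucleus_zc + 0.1 + r, zhi - r),
                               max(zhi - r, ct$nucleus_zc + 0.1 + r))
            c(ct$cx + rho * cos(phi), ct$cy + rho * sin(phi), zc)
          },
          "basal-central" = {
            # mirror of apical-central: same lateral law, below the nucleus
            rho <- 0.5 * ct$apothem * sqrt(stats::runif(1))
            phi <- stats::runif(1, 0, 2 * pi)
            zc <- stats::runif(1, max(zlo + r, min(zlo + r, ct$nucleus_zc - 0.1 - r)),
                               max(zlo + r, ct$nucleus_zc - 0.1 - r))
            c(ct$cx + rho * cos(phi), ct$cy + rho * sin(phi), zc)
          },
          "perinuclear" = {
            phi <- stats::runif(1, 0, 2 * pi)
            rho <- ct$nucleus_a + r + abs(stats::rnorm(1, 0, 0.3))
            zc <- ct$nucleus_zc + stats::rnorm(1, 0, ct$nucleus_c / 2)
            c(ct$cx + rho * cos(phi), ct$cy + rho * sin(phi),
              min(max(zc, zlo + r), zhi - r))
          },
          "lateral-dispersed" = {
            repeat {
              xx <- stats::runif(1, -ct$apothem, ct$apothem)
              yy <- stats::runif(1, -ct$circumradius, ct$circumradius)
              if (hex_inside(xx, yy, ct$circumradius * 0.95)) break
            }
            c(ct$cx + xx, ct$cy + yy,
              stats::runif(1, min(zlo + r, zhi - r), max(zlo + r, zhi - r)))
          },
          "border-bound" = {
            phi <- stats::runif(1, 0, 2 * pi)
            rho <- max(hex_radius_at(phi, ct$circumradius) - r - 0.1, 0)
            c(ct$cx + rho * cos(phi), ct$cy + rho * sin(phi),
              stats::runif(1, min(zlo + r, zhi - r), max(zlo + r, zhi - r)))
          },
          stop(sprintf("unknown placement law '%s'", row$placement)))
        idx <- switch(row$archetype,
          spot = ellipsoid_indices(dims, voxel, pos, rep(r, 3)),
          blob = {
            f <- exp(stats::runif(1, -0.5, 0.5))
            ellipsoid_indices(dims, voxel, pos,
                              c(r * f, r / f, r) * 1.0)
          },
          filament = {
            L <- stats::runif(1, 2, 4)           # um
            rt <- sqrt(V / (pi * L))             # tube radius
            nst <- max(4L, ceiling(L / (voxel$dx)))
            th <- stats::runif(1, 0, 2 * pi)
            dir <- c(cos(th), sin(th), stats::runif(1, -0.15, 0.15))
            pts <- t(sapply(seq_len(nst), function(q) {
              pos - dir * L / 2 + dir * L * (q - 1) / (nst - 1)
            }))
            unique(unlist(lapply(seq_len(nst), function(q)
              ellipsoid_indices(dims, voxel, pts[q, ], rep(max(rt, 0.15), 3)))))
          },
          stop(sprintf("unknown archetype '%s'", row$archetype)))
        idx <- idx[cells[idx] == i]              # ground-truth containment
        idx <- idx[labels[idx] == 0L]            # organelles do not interpenetrate
        if (length(idx) == 0L) next
        next_id <- next_id + 1L
        labels[idx] <- next_id
        parents[next_id] <- i
      }
    }
    intensity <- NULL
    if (make_intensity) intensity <- synth_intensity(labels > 0, voxel,
                                                     snr = snr)
    list(labels = labels, intensity = intensity, parents = parents)
  })
  attr(res$labels, "voxel") <- voxel
  res$class <- class_name
  if (!is.null(ph)) {
    ph$organelles[[class_name]] <- res
    return(ph)
  }
  res
}
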