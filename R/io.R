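# Volume I/O (multi-page TIFF + JSON sidecar carrying the voxel spec) and
# the end-to-end pipeline orchestration: phantom -> stitch -> segment ->
# morphometry/QC -> reference maps & interaction maps -> trend GLMs ->
# networks -> polarity classification, writing CSV artifacts per stage.

#' Write a volume as multi-page TIFF with a JSON sidecar
#'
#' Pages are z-planes (most basal first). Integer label volumes are stored
#' as 16-bit with the integer scale in the sidecar (round-trip exact for
#' labels below 65536); intensity volumes as 32-bit float scaled to \[0, 1\]
#' with the scale factor recorded. The sidecar (`<path>.json`) stores the
#' voxel spec, kind, scale and optional metadata, because every downstream
#' metric is um-denominated.
#'
#' @param vol 3D array (2D allowed, treated as one plane).
#' @param path output TIFF path.
#' @param voxel a [voxel_spec()] (defaults to the array's `voxel`
#'   attribute).
#' @param kind `"label"` or `"intensity"` (guessed from integerness).
#' @param meta optional list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel = NULL, kind = NULL, meta = NULL) {
  if (is.null(voxel)) voxel <- attr(vol, "voxel")
  if (is.null(voxel)) stop("a voxel spec is required to write a volume")
  voxel <- as_voxel_spec(voxel)
  if (length(dim(vol)) == 2L) dim(vol) <- c(dim(vol), 1L)
  if (is.null(kind))
    kind <- if (is.integer(vol) || all(vol == round(vol))) "label"
  else "intensity"
  if (kind == "label") {
    mx <- max(vol)
    if (mx > 65535) stop("label ids above 65535 are not supported")
    scale <- 65535
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] / scale)
    bits <- 16L
  } else {
    mx <- max(vol)
    scale <- if (mx > 0) mx else 1
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] / scale)
    bits <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  side <- list(voxel = unclass(voxel), kind = kind, scale = scale,
               dims = dim(vol))
  if (!is.null(meta)) side$meta <- meta
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()] (or any grayscale TIFF)
#'
#' The voxel size is taken from the JSON sidecar when present, else from
#' the `voxel` argument; if neither is available the read fails (metrics
#' are um-denominated). Integer-scaled files are restored to integer
#' labels.
#'
#' @param path TIFF path.
#' @param voxel fallback [voxel_spec()] when no sidecar exists.
#' @return 3D array with attributes `voxel` and `kind`.
#' @export
read_volume <- function(path, voxel = NULL) {
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
  else NULL
  if (!is.null(side) && !is.null(side$voxel))
    voxel <- voxel_spec(side$voxel$dx, side$voxel$dy, side$voxel$dz)
  if (is.null(voxel))
    stop("no voxel size available (no sidecar and no 'voxel' argument); ",
         "metrics are um-denominated")
  voxel <- as_voxel_spec(voxel)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) > 2L)
    stop("unsupported multi-channel (RGB) TIFF; expected grayscale pages")
  vol <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  kind <- if (!is.null(side)) side$kind else "intensity"
  scale <- if (!is.null(side)) side$scale else 1
  vol <- vol * scale
  if (identical(kind, "label")) vol <- array(as.integer(round(vol)), dim(vol))
  attr(vol, "voxel") <- voxel
  attr(vol, "kind") <- kind
  vol
}

#' Default pipeline configuration
#'
#' Demo-scale settings: a coarse 0.434 um lateral grid (2x binning of the
#' acquisition pitch), 4x3-cell phantoms, one field of view per condition,
#' three structure classes, both treatment arms over weeks 1-4. Every knob
#' of the stage configs can be overridden.
#'
#' @param ... overrides of any top-level field.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 0,
    voxel = voxel_spec(0.434, 0.434, 0.5),
    grid = c(4, 3),
    n_fov = 1,
    treatments = c("PGE2", "HPI4"),
    weeks = 1:4,
    classes = c("LAMP1", "TOMM20", "TJP1"),
    # lysosomes relocate apically as polarization proceeds (PGE2 arm)
    dynamic_placement = list(PGE2 = list(
      LAMP1 = c("lateral-dispersed", "lateral-dispersed",
                "apical-central", "apical-central"))),
    snr = 10,
    stitch = stitch_config(),
    qc = qc_config(),
    template_dims = c(32, 32, 8),
    pcc_change_threshold = 0.45,
    unit = "cell",     # statistical unit for the polarity classifier
    out_dir = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on phantom data
#'
#' Executes phantom generation, plane-wise slicing and 3D re-stitching of
#' the cell masks, organelle segmentation, morphometry with QC, reference
#' maps, hexagon alignment + morphing + PCC per condition, weekly trend
#' GLMs, interaction networks with first-change weeks, and per-organelle
#' polarity Random Forests. Writes one CSV per table into `out_dir` (when
#' set) together with a resolved-config JSON, and returns all tables
#' invisibly. Deterministic for a fixed config seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) list of result tables.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$voxel)) stop("config must carry a voxel spec")
  voxel <- as_voxel_spec(config$voxel)
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  cells_all <- list(); orgs_all <- list(); fov_all <- list()
  pcc_store <- list(); refmaps <- list()
  seed0 <- as.integer(config$seed)
  fov_counter <- 0L
  for (tr in config$treatments) for (wk in config$weeks) {
    st <- condition_state(tr, wk)
    dyn <- config$dynamic_placement[[tr]]
    for (f in seq_len(config$n_fov)) {
      fov_counter <- fov_counter + 1L
      seed <- seed0 + 1000L * fov_counter
      ph <- generate_monolayer(config$grid[1], config$grid[2], st,
                               voxel = voxel, seed = seed,
                               make_intensity = FALSE)
      # stitch the plane-sliced ground truth back into 3D
      cells3d <- stitch(slice_volume(ph$cells), config$stitch, voxel)
      ev <- evaluate_preset(cells3d, ph$cells)
      say("[%s w%d fov%d] stitched %d cells (gt %d, mean IoU %.3f)",
          tr, wk, f, max(cells3d), max(ph$cells), ev$mean_iou)
      cm <- cell_morphometry(ph$cells, voxel, fov = fov_counter,
                             condition = list(treatment = tr, week = wk))
      nm <- cell_morphometry(ph$nuclei, voxel, fov = fov_counter)
      qc <- qc_filter(cm, config$qc)
      refmaps[[sprintf("%s_w%d", tr, wk)]] <-
        reference_map(cm, nm, condition = sprintf("%s_week%d", tr, wk))
      org_records <- list()
      templates <- list()
      aligns <- NULL
      for (cl in config$classes) {
        placement <- if (!is.null(dyn[[cl]])) dyn[[cl]][wk] else NULL
        so <- sample_organelles(ph$cells, cl, state = st,
                                seed = seed + match(cl, config$classes),
                                nuclei = ph$nuclei,
                                cells_table = ph$cells_table,
                                voxel = voxel, snr = config$snr,
                                placement = placement)
        arch <- organelle_class_defaults()
        preset <- seg_preset(arch$archetype[arch$class == cl])
        seg <- segment_structure(so$intensity, preset, voxel)
        loc <- localization(seg, ph$cells, voxel = voxel,
                            nuclei = ph$nuclei, class_name = cl)
        if (!is.null(loc) && nrow(loc)) {
          loc$fov <- fov_counter; loc$treatment <- tr; loc$week <- wk
          org_records[[cl]] <- loc
        }
        if (is.null(aligns)) {
          ids <- qc$cells$cell
          aligns <- stats::setNames(lapply(ids, function(ci) {
            foot <- apply(ph$cells == ci, c(1, 2), any)
            wnuc <- which(ph$nuclei == ci, arr.ind = TRUE)
            ncent <- if (nrow(wnuc)) c(mean(wnuc[, 1]) * voxel$dx,
                                       mean(wnuc[, 2]) * voxel$dy) else NULL
            hexagon_align(foot, ncent, voxel = voxel,
                          rotation_step_deg = 6, n_sizes = 5)
          }), ids)
        }
        templates[[cl]] <- morph_to_mean_shape(ph$cells, so$intensity,
                                               aligns, voxel,
                                               config$template_dims)
      }
      orecs <- do.call(rbind, org_records)
      cells_all[[length(cells_all) + 1L]] <- qc$cells
      if (!is.null(orecs)) orgs_all[[length(orgs_all) + 1L]] <- orecs
      fs <- fov_summary(qc$cells, if (is.null(orecs))
        data.frame(class = character(0)) else orecs)
      fs$treatment <- tr; fs$week <- wk
      fov_all[[length(fov_all) + 1L]] <- fs
      if (length(templates) >= 2 && f == 1L)
        pcc_store[[tr]][[as.character(wk)]] <- pairwise_pcc(templates)
    }
  }
  cells_tab <- do.call(rbind, cells_all)
  orgs_tab <- do.call(rbind, orgs_all)
  fov_tab <- do.call(rbind, fov_all)
  say("fitting weekly trend GLMs")
  glm_tab <- fit_trend_table(fov_tab)
  nets <- list(); firsts <- list(); cents <- list()
  for (tr in names(pcc_store)) {
    by_week <- pcc_store[[tr]]
    if (!"1" %in% names(by_week)) next
    nets[[tr]] <- do.call(rbind, lapply(names(by_week), function(w)
      network_edges(by_week[[w]], condition = sprintf("%s_w%s", tr, w))))
    fc <- first_change_week(by_week, config$pcc_change_threshold)
    fc$treatment <- tr
    firsts[[tr]] <- fc
    cs <- centrality_series(by_week)
    cs$treatment <- tr
    cents[[tr]] <- cs
  }
  # polarity classification: last-week PGE2 (polarized) vs HPI4
  models <- list()
  if (all(c("PGE2", "HPI4") %in% config$treatments) && !is.null(orgs_tab)) {
    wlast <- max(config$weeks)
    feats <- polarity_feature_table(cells_tab, orgs_tab,
                                    weeks = wlast, unit = config$unit)
    for (cl in unique(feats$class)) {
      sub <- feats[feats$class == cl, setdiff(names(feats), "class")]
      m <- try(train_polarity_model(sub, seed = seed0, organelle = cl),
               silent = TRUE)
      if (!inherits(m, "try-error")) models[[cl]] <- m
    }
  }
  res <- list(cells = cells_tab, organelles = orgs_tab, fov_summary = fov_tab,
              glm_fits = glm_tab, reference_maps = refmaps,
              pcc = pcc_store,
              networks = if (length(nets)) do.call(rbind, nets) else NULL,
              first_change = if (length(firsts)) do.call(rbind, firsts) else NULL,
              centrality = if (length(cents)) do.call(rbind, cents) else NULL,
              polarity_models = models,
              importance = if (length(models)) weighted_importance(models)
              else NULL,
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, nm) if (!is.null(x) && is.data.frame(x))
      utils::write.csv(x, file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    wr(res$cells, "cells"); wr(res$organelles, "organelles")
    wr(res$fov_summary, "fov_summary"); wr(res$glm_fits, "glm_fits")
    wr(res$networks, "networks"); wr(res$first_change, "first_change")
    wr(res$centrality, "centrality"); wr(res$importance, "polarity_importance")
    cfg_out <- config
    cfg_out$voxel <- unclass(as_voxel_spec(cfg_out$voxel))
    cfg_out$stitch <- unclass(cfg_out$stitch)
    cfg_out$qc <- unclass(cfg_out$qc)
    jsonlite::write_json(cfg_out, file.path(config$out_dir,
                                            "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  say("pipeline complete in %.1f s",
      as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(res)
}

#' Feature table for the polarity classifiers
#'
#' One row per statistical unit (cell or FOV) and structure class, with the
#' organelle features (count, mean/total object volume, relative volume
#' fraction, lateral and apical distances, centroid offset) and the
#' polarity label (treatment arm). Structures without shape metrics (LMNB1)
#' should be excluded by the caller.
#'
#' @param cells cell table with `treatment`/`week` columns.
#' @param organelles organelle localization table.
#' @param weeks weeks to include (default: all).
#' @param unit `"cell"` or `"fov"`.
#' @return data.frame with a `label` column (treatment) per class.
#' @export
polarity_feature_table <- function(cells, organelles, weeks = NULL,
                                   unit = c("cell", "fov")) {
  unit <- match.arg(unit)
  if (!is.null(weeks)) {
    cells <- cells[cells$week %in% weeks, ]
    organelles <- organelles[organelles$week %in% weeks, ]
  }
  pc <- per_cell_summaries(cells, organelles)
  key <- unique(cells[, c("fov", "cell", "treatment", "week", "height")])
  pc <- merge(pc, key, by = c("fov", "cell"))
  featcols <- c("count", "org_volume", "org_total_volume",
                "relative_fraction", "org_lateral_distance",
                "org_apical_distance", "org_centroid_offset")
  featcols <- intersect(featcols, names(pc))
  if (unit == "fov") {
    sp <- split(pc, list(pc$fov, pc$class, pc$treatment), drop = TRUE)
    pc <- do.call(rbind, lapply(sp, function(s) {
      r <- s[1, c("fov", "class", "treatment")]
      for (v in featcols) r[[v]] <- mean(s[[v]], na.rm = TRUE)
      r
    }))
  }
  out <- pc[, c("class", featcols)]
  out$label <- pc$treatment
  out
}
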