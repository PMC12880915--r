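# Classical segmentation toolbox: determinism, monotonicity, preset
# recovery against phantom ground truth, watershed splitting, scoring.

make_spheres <- function(centers, r, dims, voxel = voxel_spec(1, 1, 1)) {
  lab <- array(0L, dims)
  for (i in seq_len(nrow(centers))) {
    idx <- polaris3d:::ellipsoid_indices(dims, voxel, centers[i, ],
                                         rep(r, 3))
    lab[idx] <- i
  }
  lab
}

test_that("blank input yields zero objects, not an error", {
  lab <- segment_structure(array(0, c(20, 20, 5)), seg_preset("spot"),
                           voxel_spec(1, 1, 1))
  expect_equal(max(lab), 0L)
})

test_that("spot preset recovers separated spheres at SNR 10", {
  v <- voxel_spec()                              # acquisition grid, um
  g <- as.matrix(expand.grid(x = seq(3, 18, by = 5),
                             y = seq(3, 23, by = 5)))
  centers <- cbind(g, z = 4)                     # 20 spheres, r = 0.7 um
  dims <- c(ceiling(21 / v$dx), ceiling(26 / v$dy), 16L)
  truth <- array(0L, dims)
  for (i in seq_len(nrow(centers))) {
    idx <- polaris3d:::ellipsoid_indices(dims, v, centers[i, ], rep(0.7, 3))
    truth[idx] <- i
  }
  int <- with_seed(9, synth_intensity(truth > 0, v, snr = 10))
  pred <- segment_structure(int, seg_preset("spot"), v)
  ev <- evaluate_preset(pred, truth)
  expect_equal(length(unique(pred[pred > 0])), 20)
  expect_gte(ev$mean_iou, 0.7)
  # centroids within one voxel pitch of ground truth (um)
  wp <- which(pred > 0, arr.ind = TRUE)
  pit <- c(v$dx, v$dy, v$dz)
  for (i in seq_len(nrow(centers))) {
    tl <- truth[cbind(round(centers[i, 1] / v$dx), round(centers[i, 2] / v$dy),
                      round(centers[i, 3] / v$dz))]
    pl <- ev$matches$pred[ev$matches$truth == tl]
    cen <- (colMeans(wp[pred[pred > 0] == pl, , drop = FALSE]) - 0.5) * pit
    expect_lt(max(abs(cen - centers[i, ]) / pit), 1 + 1e-9)
  }
})

test_that("watershed separates touching spheres; disabled keeps one object", {
  v <- voxel_spec(1, 1, 1)
  truth <- make_spheres(rbind(c(15, 15, 11), c(25, 15, 11)), 5,
                        c(40, 30, 21), v)
  int <- gauss_smooth3(array(as.numeric(truth > 0), dim(truth)), c(1, 1, 1))
  on <- segment_structure(int, seg_preset("blob", watershed = TRUE,
                                          threshold_value = 0.5,
                                          seed_dist_um = 3), v)
  off <- segment_structure(int, seg_preset("blob", watershed = FALSE,
                                           threshold_value = 0.5,
                                           steps = c("normalize", "smooth",
                                                     "threshold",
                                                     "size_filter")), v)
  expect_equal(length(unique(on[on > 0])), 2L)
  expect_equal(length(unique(off[off > 0])), 1L)
})

test_that("segmentation is deterministic", {
  ph <- small_phantom()
  so <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 3,
                          nuclei = ph$nuclei, cells_table = ph$cells_table,
                          voxel = ph$voxel, snr = 10)
  a <- segment_structure(so$intensity, seg_preset("spot"), ph$voxel)
  b <- segment_structure(so$intensity, seg_preset("spot"), ph$voxel)
  expect_identical(a, b)
})

test_that("raising the percentile threshold never grows the foreground", {
  ph <- small_phantom()
  so <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 3,
                          nuclei = ph$nuclei, cells_table = ph$cells_table,
                          voxel = ph$voxel, snr = 10)
  fg <- vapply(c(0.90, 0.95, 0.99), function(q) {
    p <- seg_preset("shell", threshold_method = "percentile",
                    threshold_value = q, min_size_vox = 0)
    sum(segment_structure(so$intensity, p, ph$voxel) > 0)
  }, numeric(1))
  expect_true(all(diff(fg) <= 0))
})

test_that("default presets reach benchmark IoU on archetype phantoms", {
  v <- voxel_spec()
  ph <- cached("seg_bench_phantom", function()
    generate_monolayer(2, 2, polarity_state("polarized"), voxel = v,
                       seed = 41, make_intensity = FALSE))
  # spot benchmark: moderately sized, mostly separated objects
  spot <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 42,
                            nuclei = ph$nuclei, cells_table = ph$cells_table,
                            voxel = v, snr = 10, count_mean = 8,
                            object_volume_mean = 1.5,
                            placement = "lateral-dispersed")
  ev_spot <- evaluate_preset(segment_structure(spot$intensity,
                                               seg_preset("spot"), v),
                             spot$labels)
  expect_gte(ev_spot$mean_iou, 0.7)
  # blob benchmark
  blob <- sample_organelles(ph$cells, "ST6GAL1", state = ph$state, seed = 43,
                            nuclei = ph$nuclei, cells_table = ph$cells_table,
                            voxel = v, snr = 10, count_mean = 3,
                            object_volume_mean = 3)
  ev_blob <- evaluate_preset(segment_structure(blob$intensity,
                                               seg_preset("blob"), v),
                             blob$labels)
  expect_gte(ev_blob$mean_iou, 0.55)
  # filament benchmark (thin anisotropic tubes cap the achievable IoU)
  fil <- sample_organelles(ph$cells, "TOMM20", state = ph$state, seed = 44,
                           nuclei = ph$nuclei, cells_table = ph$cells_table,
                           voxel = v, snr = 10, count_mean = 6)
  ev_fil <- evaluate_preset(segment_structure(fil$intensity,
                                              seg_preset("filament"), v),
                            fil$labels)
  expect_gte(ev_fil$mean_iou, 0.55)
})

test_that("evaluate_preset scores identity and dropout correctly", {
  v <- voxel_spec(1, 1, 1)
  g <- as.matrix(expand.grid(x = seq(12, 92, by = 20),
                             y = seq(12, 32, by = 20)))
  truth <- make_spheres(cbind(g, z = 11), 5, c(104, 44, 21), v)
  ev <- evaluate_preset(truth, truth)
  expect_equal(ev$count_error, 0)
  expect_equal(ev$mean_iou, 1)
  drop1 <- truth; drop1[truth == max(truth)] <- 0L
  ev2 <- evaluate_preset(drop1, truth)
  expect_equal(ev2$count_error, 1)
  expect_equal(ev2$n_unmatched_truth, 1)
})

test_that("eroded spheres give the analytic IoU ratio", {
  v <- voxel_spec(1, 1, 1)
  g <- as.matrix(expand.grid(x = c(15, 45, 75), y = 15))
  truth <- make_spheres(cbind(g, z = 13), 10, c(90, 30, 25), v)
  # Euclidean erosion by one voxel = digital spheres of radius r - 1
  eroded <- make_spheres(cbind(g, z = 13), 9, c(90, 30, 25), v)
  pred <- truth; pred[eroded == 0L] <- 0L
  ev <- evaluate_preset(pred, truth)
  target <- (9 / 10)^3    # eroded-to-full volume ratio = IoU here
  expect_lt(abs(ev$mean_iou - target) / target, 0.05)
})

test_that("preset validation rejects invalid operator chains", {
  expect_error(seg_preset("spot", steps = c("normalize", "smooth")),
               "thresholding or detection")
  expect_error(seg_preset("spot", steps = c("normalize", "explode")),
               "invalid operator")
  expect_error(segment_structure(array(-1, c(4, 4, 2)), seg_preset("spot")),
               "non-negative")
})

test_that("preset tuning improves or matches the starting score", {
  v <- voxel_spec(1, 1, 1)
  g <- as.matrix(expand.grid(x = c(12, 32, 52), y = c(12, 32)))
  truth <- make_spheres(cbind(g, z = 9), 4, c(64, 44, 17), v)
  int <- with_seed(10, synth_intensity(truth > 0, v, snr = 10,
                                       psf_sigma_vox = c(1, 1, 1)))
  base <- seg_preset("spot", min_size_vox = 20)
  tuned <- tune_preset(int, truth, base,
                       grid = list(threshold_value = c(0.5, 0.7, 0.9)), v)
  base_row <- tuned$results$score[tuned$results$threshold_value == 0.7]
  expect_gte(max(tuned$results$score), base_row)
  expect_s3_class(tuned$best, "seg_preset")
})
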