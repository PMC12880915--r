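# Shape metrics against closed-form geometry, QC filter arithmetic,
# organelle assignment and localization distances.

test_that("projection metrics match disk, square and hexagon geometry", {
  v1 <- voxel_spec(1, 1, 1)
  n <- 111; xs <- seq_len(n) - 0.5 - n / 2
  disk <- array(outer(xs^2, xs^2, `+`) <= 50^2, c(n, n, 1))
  pm <- projection_metrics(disk, v1)
  expect_lt(abs(pm$aspect_ratio - 1), 0.02)
  sq <- array(TRUE, c(20, 20, 1))
  pms <- projection_metrics(sq, v1)
  expect_equal(pms$feret_min, 20)
  expect_equal(pms$feret_max, 20 * sqrt(2))
  expect_equal(pms$aspect_ratio, sqrt(2))
  hexp <- generate_hexagonal_prism(10, 2, voxel_spec())
  pmh <- projection_metrics(hexp, voxel_spec())
  expect_lt(abs(pmh$aspect_ratio - 2 / sqrt(3)) / (2 / sqrt(3)), 0.02)
  expect_error(projection_metrics(array(FALSE, c(3, 3, 1))), "empty")
})

test_that("volume and height follow the voxel arithmetic", {
  v <- voxel_spec()
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  vh <- volume_height(one, v)
  expect_equal(vh$volume, 0.217 * 0.217 * 0.5)
  expect_equal(vh$height, 0.5)
  plane <- array(FALSE, c(5, 5, 3)); plane[, , 2] <- TRUE
  expect_equal(volume_height(plane, v)$height, 0.5)
})

test_that("sphericity is calibrated on ball, cube and rod", {
  v1 <- voxel_spec(1, 1, 1)
  expect_gte(sphericity(unit_ball(20), v1), 0.95)
  cu <- array(FALSE, c(26, 26, 26)); cu[4:23, 4:23, 4:23] <- TRUE
  target <- pi^(1 / 3) * 6^(2 / 3) / 6      # ~0.806
  expect_lt(abs(sphericity(cu, v1) - target) / target, 0.05)
  # rods thin towards zero sphericity as they elongate (3x3 cross-section:
  # structures must be thicker than the smoothing scale of the estimator)
  rod_sph <- vapply(c(6, 15, 40), function(k) {
    r <- array(FALSE, c(7, 7, k + 4)); r[3:5, 3:5, 3:(k + 2)] <- TRUE
    sphericity(r, v1)
  }, numeric(1))
  expect_true(all(diff(rod_sph) < 0))
  expect_lt(rod_sph[3], 0.55)
  single <- array(FALSE, c(5, 5, 3)); single[2:4, 2:4, 2] <- TRUE
  expect_true(is.na(sphericity(single, v1)))
})

test_that("metrics are scale-equivariant in physical units", {
  a <- generate_hexagonal_prism(10, 5, voxel_spec(0.217, 0.217, 0.5))
  b <- generate_hexagonal_prism(10, 5, voxel_spec(0.434, 0.434, 1.0))
  va <- volume_height(a, voxel_spec(0.217, 0.217, 0.5))
  vb <- volume_height(b, voxel_spec(0.434, 0.434, 1.0))
  expect_lt(abs(va$volume - vb$volume) / va$volume, 0.03)
  expect_lt(abs(va$height - vb$height), 1.0 + 1e-9)
  pa <- projection_metrics(a, voxel_spec(0.217, 0.217, 0.5))
  pb <- projection_metrics(b, voxel_spec(0.434, 0.434, 1.0))
  expect_lt(abs(pa$feret_max - pb$feret_max), 0.434 + 1e-9)
})

test_that("qc_filter applies cutoffs in order with a reason log", {
  cells <- data.frame(fov = 1, cell = 1:6,
                      volume = c(40, 2e5, 500, 600, 700, 800),
                      height = c(3, 3, 0.5, 3, 3, 3),
                      area = 100, feret_min = c(5, 5, 5, 1.0, 5, 5),
                      feret_max = 10, aspect_ratio = 1.5, sphericity = 0.7,
                      border_touching = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                                          FALSE))
  qc <- qc_filter(cells, qc_config(tail_fraction = 0))
  expect_equal(qc$cells$cell, 6L)
  lg <- qc$log
  expect_equal(lg$reason[lg$cell == 1], "volume<50")
  expect_equal(lg$reason[lg$cell == 2], "volume>100000")
  expect_equal(lg$reason[lg$cell == 4], "width<1.5")
  expect_equal(lg$reason[lg$cell == 3], "height<1")
  expect_equal(lg$reason[lg$cell == 5], "border_touching")
})

test_that("tail trimming removes exactly 5% per tail and is idempotent", {
  set.seed(42)
  n <- 1000
  cells <- data.frame(fov = 1, cell = seq_len(n),
                      volume = sample(seq(100, 2000, length.out = n)),
                      height = 3, area = 100, feret_min = 5, feret_max = 10,
                      aspect_ratio = 1.5, sphericity = 0.7,
                      border_touching = FALSE)
  qc <- qc_filter(cells, qc_config(),
                  metrics = "volume")
  expect_equal(sum(qc$log$reason == "tail_low"), 50)
  expect_equal(sum(qc$log$reason == "tail_high"), 50)
  expect_equal(sum(is.na(qc$cells$volume)), 100)
  # trimmed values are the extremes
  kept <- qc$cells$volume[!is.na(qc$cells$volume)]
  expect_equal(length(kept), 900)
  expect_true(min(kept) > sort(cells$volume)[50])
  # idempotent: re-applying removes nothing
  qc2 <- qc_filter(qc$cells, qc_config(), metrics = "volume")
  expect_equal(nrow(qc2$log), 0)
  expect_identical(qc2$cells$volume, qc$cells$volume)
})

test_that("mid-range interior cells pass untouched before trimming", {
  cells <- data.frame(fov = 1, cell = 1:5, volume = 500, height = 3,
                      area = 100, feret_min = 5, feret_max = 10,
                      aspect_ratio = 1.5, sphericity = 0.7,
                      border_touching = FALSE)
  qc <- qc_filter(cells, qc_config(tail_fraction = 0))
  expect_equal(nrow(qc$log), 0)
  expect_equal(nrow(qc$cells), 5)
})

test_that("organelles are assigned by voxel majority with tie-breaks", {
  cells <- array(0L, c(10, 10, 2))
  cells[1:5, , ] <- 1L; cells[6:10, , ] <- 2L
  org <- array(0L, c(10, 10, 2))
  org[3:4, 1:2, 1] <- 1L                    # fully inside cell 1
  org[4:8, 3, 1] <- 2L                      # 2 voxels in 1, 3 in 2
  org[5:6, 5, 1] <- 3L                      # 1 voxel each: tie -> cell 1
  asn <- assign_to_cells(org, cells)
  expect_equal(unname(asn$parents[c("1", "2", "3")]), c(1L, 2L, 1L))
  expect_true("tie_lowest_id" %in% asn$log$note)
  # majority background: dropped and logged
  org2 <- array(0L, c(10, 10, 2))
  cells2 <- cells; cells2[, 6:10, ] <- 0L
  org2[5:6, 5:8, 1] <- 1L
  asn2 <- assign_to_cells(org2, cells2)
  expect_false("1" %in% names(asn2$parents))
  expect_true("majority_background" %in% asn2$log$note)
})

test_that("localization distances follow the distance-transform geometry", {
  v <- voxel_spec()
  # ~10 um wide square cell, 6 planes tall
  npx <- round(10 / v$dx)
  cells <- array(0L, c(npx + 10, npx + 10, 8))
  cells[6:(npx + 5), 6:(npx + 5), 2:7] <- 1L
  org <- array(0L, dim(cells))
  ctr <- 5 + round(npx / 2)
  org[ctr, ctr, 4] <- 1L                     # single voxel at the centre
  org[6, 6:10, 2] <- 2L                      # voxels on the footprint border
  org[ctr, ctr + 2, 7] <- 3L                 # topmost voxel in apical plane
  loc <- localization(org, cells, voxel = v)
  loc <- loc[order(loc$object), ]
  expect_lt(abs(loc$lateral_distance[1] - 5), v$dx + 1e-9)
  expect_lt(loc$lateral_distance[2], v$dx + 1e-9)
  expect_equal(loc$apical_distance[3], 0)
  expect_equal(loc$apical_distance[1], 3 * v$dz)
})

test_that("per-cell summaries compute counts and volume fractions", {
  cellrec <- data.frame(fov = 1, cell = 1:2, volume = c(800, 900),
                        height = 3, area = 100, feret_min = 5,
                        feret_max = 10, aspect_ratio = 1.5, sphericity = 0.7)
  orgrec <- data.frame(object = 1:4, cell = c(1, 1, 1, 1),
                       class = "LAMP1", volume = c(20, 20, 20, 20),
                       lateral_distance = 1, apical_distance = 0.5,
                       centroid_offset = 2)
  pc <- per_cell_summaries(cellrec, orgrec)
  expect_equal(pc$relative_fraction[pc$cell == 1], 100 * 80 / 800)
  expect_equal(pc$count[pc$cell == 2], 0)
  expect_equal(pc$relative_fraction[pc$cell == 2], 0)
})

test_that("FOV-mean organelle counts recover the Poisson rate", {
  set.seed(7)
  n_cells <- 200
  cellrec <- data.frame(fov = rep(1:10, each = 20), cell = seq_len(n_cells),
                        volume = 800, height = 3, area = 100, feret_min = 5,
                        feret_max = 10, aspect_ratio = 1.5, sphericity = 0.7)
  counts <- rpois(n_cells, 5)
  orgrec <- data.frame(cell = rep(seq_len(n_cells), counts))
  orgrec$object <- seq_len(nrow(orgrec))
  orgrec$class <- "X"; orgrec$volume <- 0.5
  orgrec$lateral_distance <- 1; orgrec$apical_distance <- 1
  orgrec$centroid_offset <- 1
  fs <- fov_summary(cellrec, orgrec)
  expect_lt(abs(mean(fs$count) - 5), 2 * sqrt(5 / n_cells))
})
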