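# Synthetic monolayer generator: geometry oracles, determinism, containment.

test_that("hexagonal prism matches analytic volume and Feret geometry", {
  v <- voxel_spec()
  p <- generate_hexagonal_prism(10, 5, v)
  vh <- volume_height(p, v)
  expect_lt(abs(vh$volume - 3 * sqrt(3) / 2 * 100 * 5) /
              (3 * sqrt(3) / 2 * 100 * 5), 0.02)
  expect_equal(vh$height, 5, tolerance = 1e-9)
  pm <- projection_metrics(p, v)
  expect_lt(abs(pm$feret_max - 20), v$dx + 1e-9)
  expect_lt(abs(pm$feret_min - sqrt(3) * 10), v$dx + 1e-9)
})

test_that("single-plane prism is one z-pitch tall", {
  v <- voxel_spec()
  p <- generate_hexagonal_prism(5, v$dz, v)
  expect_equal(volume_height(p, v)$height, v$dz)
})

test_that("sub-resolution dimensions are rejected", {
  v <- voxel_spec()
  expect_error(generate_hexagonal_prism(0.4, 5, v), "resolution")
  expect_error(generate_hexagonal_prism(10, 0.2, v), "resolution")
})

test_that("monolayer has one cell and one contained nucleus per lattice site", {
  ph <- small_phantom()
  expect_equal(max(ph$cells), 4L)
  expect_equal(max(ph$nuclei), 4L)
  nz <- ph$nuclei > 0
  expect_true(all(ph$cells[nz] == ph$nuclei[nz]))
  expect_equal(sort(unique(ph$nuclei[nz])), 1:4)
})

test_that("monolayer generation is deterministic for a fixed seed", {
  ph <- small_phantom()
  ph2 <- generate_monolayer(2, 2, polarity_state("polarized"),
                            voxel = coarse_voxel(), seed = 11,
                            make_intensity = FALSE)
  expect_identical(ph$cells, ph2$cells)
  expect_identical(ph$nuclei, ph2$nuclei)
  ph3 <- generate_monolayer(2, 2, polarity_state("polarized"),
                            voxel = coarse_voxel(), seed = 12,
                            make_intensity = FALSE)
  expect_false(identical(ph$cells, ph3$cells))
})

test_that("generator means are recovered by morphometry (height and width)", {
  v <- coarse_voxel()
  states <- list(polarized = polarity_state("polarized"),
                 nonpolarized = polarity_state("nonpolarized"))
  got <- lapply(states, function(st) {
    ph <- generate_monolayer(5, 5, st, voxel = v, seed = 21,
                             make_intensity = FALSE)
    cm <- cell_morphometry(ph$cells, v)
    c(height = mean(cm$height),
      width = mean((cm$feret_min + cm$feret_max) / 2))
  })
  expect_lt(abs(got$polarized["height"] - 5.3) / 5.3, 0.05)
  expect_lt(abs(got$nonpolarized["height"] - 3.5) / 3.5, 0.05)
  expect_lt(abs(got$polarized["width"] - 17.1) / 17.1, 0.05)
  expect_lt(abs(got$nonpolarized["width"] - 21.8) / 21.8, 0.05)
  expect_gt(got$polarized["height"], got$nonpolarized["height"])
  expect_gt(got$nonpolarized["width"], got$polarized["width"])
})

test_that("organelle placement laws shape the spatial distributions", {
  ph <- small_phantom()
  # apical-central: centroids above the parent-nucleus centroid plane
  ap <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 3,
                          nuclei = ph$nuclei, cells_table = ph$cells_table,
                          voxel = ph$voxel, make_intensity = FALSE,
                          count_mean = 60, object_volume_mean = 0.3,
                          placement = "apical-central")
  loc <- localization(ap$labels, ph$cells, parents = ap$parents,
                      voxel = ph$voxel, nuclei = ph$nuclei)
  expect_gt(nrow(loc), 100)
  expect_gte(mean(loc$nucleus_dz > 0), 0.95)
  # perinuclear objects hug the nucleus; lateral-dispersed do not
  peri <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 4,
                            nuclei = ph$nuclei, cells_table = ph$cells_table,
                            voxel = ph$voxel, make_intensity = FALSE,
                            count_mean = 40, placement = "perinuclear")
  disp <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 4,
                            nuclei = ph$nuclei, cells_table = ph$cells_table,
                            voxel = ph$voxel, make_intensity = FALSE,
                            count_mean = 40, placement = "lateral-dispersed")
  xy_dist <- function(so) {
    l <- localization(so$labels, ph$cells, parents = so$parents,
                      voxel = ph$voxel, nuclei = ph$nuclei)
    med <- stats::median(sqrt(l$nucleus_dist^2 - l$nucleus_dz^2))
    med
  }
  expect_lt(xy_dist(peri), xy_dist(disp))
})

test_that("organelle ground truth is fully contained in parent cells", {
  ph <- small_phantom()
  for (law in c("apical-central", "perinuclear", "lateral-dispersed",
                "border-bound")) {
    so <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 5,
                            nuclei = ph$nuclei, cells_table = ph$cells_table,
                            voxel = ph$voxel, make_intensity = FALSE,
                            placement = law)
    w <- so$labels > 0
    expect_true(all(ph$cells[w] == so$parents[so$labels[w]]), label = law)
  }
})

test_that("zero count mean gives an empty organelle volume", {
  ph <- small_phantom()
  so <- sample_organelles(ph$cells, "RAB5A", state = ph$state, seed = 1,
                          nuclei = ph$nuclei, cells_table = ph$cells_table,
                          voxel = ph$voxel, make_intensity = FALSE,
                          count_mean = 0)
  expect_equal(sum(so$labels), 0)
})

test_that("unknown organelle class is an enumeration error", {
  ph <- small_phantom()
  expect_error(sample_organelles(ph$cells, "NOPE", state = ph$state,
                                 cells_table = ph$cells_table,
                                 voxel = ph$voxel),
               "unknown organelle class")
})

test_that("polarity states interpolate between treatment endpoints", {
  mid <- polarity_state(0.5)
  expect_equal(mid$cell_height_mean, (5.3 + 3.5) / 2)
  expect_equal(mid$cell_width_mean, (17.1 + 21.8) / 2)
  expect_error(polarity_state(1.5), "\\[0, 1\\]")
  st <- condition_state("PGE2", 4)
  expect_equal(st$cell_height_mean, 5.3)
  expect_equal(st$cell_width_mean, 17.1)
})

test_that("intensity synthesis is non-negative and PSF-limited", {
  ph <- small_phantom()
  so <- sample_organelles(ph$cells, "LAMP1", state = ph$state,
                          seed = 6, nuclei = ph$nuclei,
                          cells_table = ph$cells_table,
                          voxel = ph$voxel, snr = 10)
  expect_true(all(so$intensity >= 0))
  # signal concentrates on the structures
  expect_gt(mean(so$intensity[so$labels > 0]),
            5 * mean(so$intensity[so$labels == 0]))
})
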