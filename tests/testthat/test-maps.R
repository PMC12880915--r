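# Reference maps, confidence ellipses, hexagon alignment, shape morphing
# and PCC matrices.

test_that("reference map averages heights and half-widths with SD bands", {
  cells <- data.frame(cell = 1:3, height = c(5, 5, 5),
                      feret_min = sqrt(3) * 10, feret_max = 20,
                      centroid_x = 0, centroid_y = 0, centroid_z = 2.5)
  rm1 <- reference_map(cells)
  expect_equal(rm1$cell_height_sd, 0)
  # hexagon R = 10: half-width = (20 + 17.32) / 4
  expect_equal(rm1$cell_halfwidth_mean, (20 + sqrt(3) * 10) / 4,
               tolerance = 1e-6)
  expect_error(reference_map(cells[1, ]), "2 cells")
  nuc <- data.frame(cell = 1:3, height = 3, feret_min = 8, feret_max = 10,
                    centroid_x = 0, centroid_y = 0, centroid_z = 1.8)
  rm2 <- reference_map(cells, nuc)
  expect_equal(rm2$nucleus_offset_z, -0.7, tolerance = 1e-9)
})

test_that("the 2-SD band covers at least 95% of Gaussian heights", {
  set.seed(101)
  h <- rnorm(1e5, 5, 0.5)
  cover <- mean(abs(h - mean(h)) <= 2 * sd(h))
  expect_gte(cover, 0.95)
})

test_that("confidence ellipse geometry and coverage are calibrated", {
  # isotropic unit variance: semi-axes = sqrt(chi2_{0.90,2}) ~ 2.146 SD
  set.seed(7)
  p <- matrix(rnorm(2e5), ncol = 2)
  el <- confidence_ellipse(p, 0.90)
  expect_equal(unname(el$semi_axes), rep(sqrt(qchisq(0.90, 2)), 2),
               tolerance = 0.02)
  # Monte-Carlo coverage on correlated data
  S <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  L <- chol(S)
  q <- matrix(rnorm(2e5), ncol = 2) %*% L
  elq <- confidence_ellipse(q, 0.90)
  expect_lt(abs(mean(in_ellipse(q, elq)) - 0.90), 0.005)
  # degenerate: collinear points collapse with a warning
  line <- cbind(1:10, 2 * (1:10))
  expect_warning(eld <- confidence_ellipse(line), "degenerate")
  expect_lt(min(eld$semi_axes) / max(eld$semi_axes), 1e-4)
  expect_error(confidence_ellipse(p[1:2, ]), "3 points")
})

rot_hex_footprint <- function(angle, R = 12, elong = 1.5, v = voxel_spec(0.25, 0.25, 0.5)) {
  n <- 160
  xs <- (seq_len(n) - 0.5) * v$dx - n / 2 * v$dx
  th <- angle * pi / 180
  outer(xs, xs, function(x, y) {
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    polaris3d:::hex_inside(xr, yr, R, elongation = elong)
  })
}

test_that("hexagon alignment recovers a known rotation (mod symmetry)", {
  v <- voxel_spec(0.25, 0.25, 0.5)
  al <- hexagon_align(rot_hex_footprint(25), voxel = v)
  d <- abs(al$angle_deg - 25) %% 180
  expect_lte(min(d, 180 - d), 3)
  expect_gt(al$score, 0.85)
  # regular hexagon: any angle valid mod 60; re-orientation scores well
  alr <- hexagon_align(rot_hex_footprint(10, elong = 1), voxel = v)
  expect_gt(alr$score, 0.85)
  expect_true(alr$aligned)
})

test_that("a right-shifted nucleus triggers the 180-degree flip", {
  v <- voxel_spec(0.25, 0.25, 0.5)
  f <- rot_hex_footprint(0)
  al0 <- hexagon_align(f, voxel = v)
  ctr <- al0$centroid
  fl <- hexagon_align(f, nucleus_centroid = ctr + c(2, 0),
                      cell_centroid = ctr, voxel = v)
  expect_true(fl$flip)
  expect_equal(fl$angle_deg %% 360, (al0$angle_deg + 180) %% 360)
  nofl <- hexagon_align(f, nucleus_centroid = ctr + c(-2, 0),
                        cell_centroid = ctr, voxel = v)
  expect_false(nofl$flip)
})

align_phantom <- function(ph) {
  ids <- ph$cells_table$cell
  stats::setNames(lapply(ids, function(ci) {
    foot <- apply(ph$cells == ci, c(1, 2), any)
    hexagon_align(foot, voxel = ph$voxel, rotation_step_deg = 6, n_sizes = 5)
  }), ids)
}

test_that("morphing preserves uniform signals and mean intensity", {
  ph <- small_phantom()
  aligns <- cached("small_aligns", function() align_phantom(ph))
  U <- array(3, dim(ph$cells))
  tu <- morph_to_mean_shape(ph$cells, U, aligns, ph$voxel, c(32, 32, 8))
  expect_lt(diff(range(tu, na.rm = TRUE)), 1e-9)
  expect_equal(mean(tu, na.rm = TRUE), 3)
  # smooth non-uniform signal: mean preserved within 5%
  d <- dim(ph$cells)
  grad <- array(rep(seq(0, 1, length.out = d[1]), d[2] * d[3]), d)
  tg <- morph_to_mean_shape(ph$cells, grad, aligns, ph$voxel, c(32, 32, 8))
  expect_lt(abs(mean(tg, na.rm = TRUE) - mean(grad[ph$cells > 0])) /
              mean(grad[ph$cells > 0]), 0.05)
})

test_that("a cell morphed onto its own shape reproduces its smooth signal", {
  ph <- small_phantom()
  aligns <- cached("small_aligns", function() align_phantom(ph))
  d <- dim(ph$cells)
  # smooth apical-basal + radial signal
  sig <- array(0, d)
  for (k in seq_len(d[3])) sig[, , k] <- k
  sig <- sig + array(rep(seq(0, 2, length.out = d[1]), d[2] * d[3]), d)
  one <- aligns[1]
  tm <- morph_to_mean_shape(ph$cells, sig, one, ph$voxel, c(48, 48, 12))
  m1 <- ph$cells == 1
  back <- project_template_to_cell(tm, m1, one[[1]], ph$voxel)
  expect_gte(cor(back, sig[which(m1)], use = "complete.obs"), 0.95)
})

test_that("pairwise PCC has exact identities and white-noise decorrelation", {
  set.seed(3)
  a <- array(rnorm(1e5), c(100, 100, 10))
  b <- -(a - mean(a))
  noise <- array(rnorm(1e5), c(100, 100, 10))
  class(a) <- class(b) <- class(noise) <- "morph_template"
  m <- pairwise_pcc(list(x = a, y = b, z = noise))
  expect_equal(diag(m), c(x = 1, y = 1, z = 1))
  expect_equal(m["x", "y"], -1)
  expect_lt(abs(m["x", "z"]), 0.01)
  expect_equal(m, t(m))
  cst <- array(1, c(100, 100, 10)); class(cst) <- "morph_template"
  expect_warning(m2 <- pairwise_pcc(list(x = a, c = cst)), "constant")
  expect_true(is.na(m2["x", "c"]))
})

test_that("PCC of morphed signals is invariant to channel rescaling", {
  ph <- small_phantom()
  aligns <- cached("small_aligns", function() align_phantom(ph))
  so <- sample_organelles(ph$cells, "LAMP1", state = ph$state, seed = 8,
                          nuclei = ph$nuclei, cells_table = ph$cells_table,
                          voxel = ph$voxel, snr = 10)
  so2 <- sample_organelles(ph$cells, "TJP1", state = ph$state, seed = 9,
                           nuclei = ph$nuclei, cells_table = ph$cells_table,
                           voxel = ph$voxel, snr = 10)
  t1 <- morph_to_mean_shape(ph$cells, so$intensity, aligns, ph$voxel,
                            c(32, 32, 8))
  t2 <- morph_to_mean_shape(ph$cells, so2$intensity, aligns, ph$voxel,
                            c(32, 32, 8))
  t1s <- morph_to_mean_shape(ph$cells, 7.3 * so$intensity, aligns, ph$voxel,
                             c(32, 32, 8))
  m <- pairwise_pcc(list(a = t1, b = t2))
  ms <- pairwise_pcc(list(a = t1s, b = t2))
  expect_equal(m["a", "b"], ms["a", "b"], tolerance = 1e-9)
})

test_that("clustering merges the most correlated pair first", {
  m <- diag(3); dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  m["A", "B"] <- m["B", "A"] <- 0.9
  cl <- cluster_pcc(m)
  first <- cl$hclust$merge[1, ]
  expect_setequal(rownames(m)[-first], c("A", "B"))
  # identical rows: zero-height merge
  m2 <- matrix(0.5, 3, 3); diag(m2) <- 1
  dimnames(m2) <- dimnames(m)
  cl2 <- cluster_pcc(m2)
  expect_equal(cl2$hclust$height, rep(0.5, 2))
  # permutation invariance of tree heights
  perm <- c("C", "A", "B")
  cl3 <- cluster_pcc(m[perm, perm])
  expect_equal(sort(cl3$hclust$height), sort(cl$hclust$height))
})
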