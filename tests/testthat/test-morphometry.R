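test_that("hull and voxel volumes are exact on solid cubes", {
  vox <- as.matrix(expand.grid(x = 1:11, y = 1:11, z = 1:11))
  m <- cell_mask(vox, c(1, 1, 1))
  expect_equal(territorial_volume(m), 1331)
  expect_equal(cell_volume(m), 1331)
  f <- extract_features(m)
  expect_equal(f$ramification_index, 1)
  expect_equal(f$n_branchpoints, 0)

  # anisotropic spacing: 100 voxels at 0.5 x 0.5 x 1.0
  m2 <- cell_mask(as.matrix(expand.grid(1:10, 1:10, 1)), c(0.5, 0.5, 1))
  expect_equal(cell_volume(m2), 25)
})

test_that("hull of two diagonal voxels exceeds their union volume", {
  m <- cell_mask(rbind(c(1, 1, 1), c(2, 2, 2)), c(1, 1, 1))
  tv <- territorial_volume(m)
  expect_gte(tv, 2)
  expect_gte(tv, cell_volume(m))
})

test_that("hull volume matches the scipy qhull oracle on random masks", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  for (seed in c(3, 17)) {
    vox <- random_connected_mask(40, seed)
    m <- cell_mask(vox, c(1, 1, 1), check = FALSE)
    corners <- as.matrix(expand.grid(d1 = 0:1, d2 = 0:1, d3 = 0:1))
    pts <- unique(do.call(rbind, lapply(seq_len(nrow(corners)), function(i)
      sweep(vox, 2, corners[i, ], `+`))))
    f <- tempfile(fileext = ".csv")
    write.table(pts, f, row.names = FALSE, col.names = FALSE, sep = ",")
    out <- system2("python", c("-c", shQuote(paste0(
      "import numpy, scipy.spatial; ",
      "p = numpy.loadtxt('", f, "', delimiter=','); ",
      "print(scipy.spatial.ConvexHull(p).volume)"))), stdout = TRUE)
    expect_equal(territorial_volume(m), as.numeric(out), tolerance = 1e-9)
  }
})

test_that("hull containment holds on random masks (ramification index >= 1)", {
  for (seed in 1:20) {
    vox <- random_connected_mask(sample(5:60, 1), seed)
    m <- cell_mask(vox, c(0.5, 0.5, 1), check = FALSE)
    expect_gte(territorial_volume(m) - cell_volume(m), -1e-9)
  }
})

test_that("skeleton endpoints and branchpoints match the neighbor-count oracle", {
  shapes <- list(
    line = cbind(2:11, 5L, 5L),
    ell = rbind(cbind(2:8, 2L, 2L), cbind(8L, 3:8, 2L)),
    cross3d = unique(rbind(cbind(2:12, 7L, 7L), cbind(7L, 2:12, 7L),
                           cbind(7L, 7L, 2:6)))
  )
  for (nm in names(shapes)) {
    m <- cell_mask(shapes[[nm]], c(1, 1, 1))
    sk <- skeletonize_cell(m, prune_um = 0)
    deg <- oracle_degrees(sk$voxels)
    expect_equal(sort(sk$endpoints), which(deg == 1L), info = nm)
    expect_equal(sort(sk$branchpoints), which(deg >= 3L), info = nm)
  }
  # random thick masks: counts agree after thinning as well
  for (seed in 31:40) {
    vox <- random_connected_mask(80, seed)
    sk <- skeletonize_cell(cell_mask(vox, c(1, 1, 1), check = FALSE),
                           prune_um = 0)
    deg <- oracle_degrees(sk$voxels)
    expect_equal(sort(sk$endpoints), which(deg == 1L))
    expect_equal(sort(sk$branchpoints), which(deg >= 3L))
  }
})

test_that("thinning preserves curves and collapses blobs", {
  # straight line: two endpoints, no branchpoints
  sk <- skeletonize_cell(cell_mask(cbind(1:10, 5L, 5L), c(1, 1, 1)))
  expect_equal(length(sk$endpoints), 2L)
  expect_equal(length(sk$branchpoints), 0L)

  # solid sphere of radius 5 um collapses to a single voxel:
  # no endpoints, no branchpoints, all branch lengths zero
  sp <- as.matrix(expand.grid(x = 1:11, y = 1:11, z = 1:11))
  sp <- sp[rowSums(sweep(sp, 2, c(6, 6, 6))^2) <= 25, ]
  sk <- skeletonize_cell(cell_mask(sp, c(1, 1, 1)))
  expect_equal(nrow(sk$voxels), 1L)
  expect_equal(length(sk$endpoints), 0L)
  expect_equal(unname(branch_lengths(sk)), c(0, 0, 0))
})

test_that("geodesic branch lengths match the igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  for (seed in c(5, 9, 23)) {
    vox <- random_connected_mask(60, seed)
    m <- cell_mask(vox, c(0.5, 0.5, 1), check = FALSE)
    sk <- skeletonize_cell(m, prune_um = 0)
    if (length(sk$endpoints) == 0) next
    geo <- microglia3d:::cpp_skeleton_geodesics(sk$voxels, sk$spacing,
                                                sk$centroid)
    root <- geo$roots[1]
    ora <- oracle_geodesics(sk$voxels, sk$spacing, root)
    same <- geo$component == geo$component[root]
    expect_equal(geo$dist[same], unname(ora[same]), tolerance = 1e-9)
  }
})

test_that("branch length summaries follow the endpoint geometry", {
  # 13-voxel line; thinning consumes the two unanchored tip voxels, the
  # skeleton spans voxels 2..12 and the centroid sits on the middle voxel:
  # both endpoints are 5 um from the root
  sk <- skeletonize_cell(cell_mask(cbind(1:13, 5L, 5L), c(1, 1, 1)))
  bl <- branch_lengths(sk)
  expect_equal(unname(bl), c(5, 5, 5))

  # order statistics: max >= avg >= min on an asymmetric shape
  arm <- rbind(cbind(5:14, 5L, 3L), cbind(5L, 6:9, 3L))
  bl2 <- branch_lengths(skeletonize_cell(cell_mask(arm, c(1, 1, 1))))
  expect_gte(bl2["max"], bl2["avg"])
  expect_gte(bl2["avg"], bl2["min"])

  # no endpoints -> all zeros
  single <- skeletonize_cell(cell_mask(matrix(c(3L, 3L, 3L), 1), c(1, 1, 1)))
  expect_equal(unname(branch_lengths(single)), c(0, 0, 0))
})

test_that("features are scale covariant", {
  vox <- random_connected_mask(50, 77)
  m1 <- cell_mask(vox, c(0.5, 0.5, 1), check = FALSE)
  m2 <- cell_mask(vox, c(1, 1, 2), check = FALSE)
  f1 <- extract_features(m1)
  f2 <- extract_features(m2)
  expect_equal(f2$territorial_volume, 8 * f1$territorial_volume)
  expect_equal(f2$cell_volume, 8 * f1$cell_volume)
  expect_equal(f2$ramification_index, f1$ramification_index)
  expect_equal(f2$n_endpoints, f1$n_endpoints)
  expect_equal(f2$n_branchpoints, f1$n_branchpoints)
  expect_equal(f2$avg_branch_length, 2 * f1$avg_branch_length,
               tolerance = 1e-9)
})

test_that("segmentation finds synthetic cells and applies the border rule", {
  # background-only stack
  set.seed(1)
  vol <- voxel_volume(array(rnorm(40 * 40 * 8, 0.1, 0.02), c(40, 40, 8)),
                      c(1, 1, 1))
  expect_length(segment_cells(vol, min_voxels = 10), 0L)

  # constant image: no threshold
  expect_error(segment_cells(voxel_volume(array(0.5, c(5, 5, 5)))),
               "no threshold")

  # two bright blobs, one clipped at the x border
  img <- array(0.05, c(30, 30, 8))
  img[10:14, 10:14, 3:6] <- 0.9
  img[1:4, 22:26, 3:6] <- 0.9   # touches x = 1
  vol <- voxel_volume(img, c(1, 1, 1))
  expect_length(segment_cells(vol, min_voxels = 10), 1L)
  expect_length(segment_cells(vol, min_voxels = 10, exclude_border = FALSE),
                2L)
})

test_that("ramification index orders the three morphology presets", {
  pre <- morphology_presets()
  f <- lapply(pre, function(p) extract_features(generate_cell(p, seed = 7)))
  expect_gt(f$ramified$ramification_index, f$rod$ramification_index)
  expect_gt(f$rod$ramification_index, f$amoeboid$ramification_index)
  expect_gt(f$ramified$n_branchpoints, f$rod$n_branchpoints)
})
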