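# Cluster formation, GRF/permutation cluster-level inference, ROI rule.

test_that("cluster labelling matches a flood-fill oracle on random masks", {
  set.seed(61)
  for (rep in 1:20) {
    dm <- sample(3:7, 3, replace = TRUE)
    mask <- array(runif(prod(dm)) < 0.35, dm)
    lab <- neuroXmap:::labelClusters(mask, 6L)
    oracle <- bruteLabel6(mask)
    # same partition: component memberships agree up to relabelling
    expect_identical(lab > 0L, oracle > 0L)
    tab <- table(lab[lab > 0], oracle[oracle > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("labels partition supra-threshold voxels and sizes sum correctly", {
  f <- synthSmoothField(c(16, 16, 16), c(2, 2, 2), seed = 5)
  cl <- grfClusterThreshold(f, fwhm = c(6, 6, 6), voxelP = 0.05, clusterP = 1)
  lab <- mapData(cl@labels)
  expect_equal(sum(clusterTable(cl)$size), sum(lab > 0, na.rm = TRUE))
})

test_that("no supra-threshold voxel gives an empty result", {
  f <- VoxelMap(array(0, c(6, 6, 6)), voxelSize = c(3, 3, 3), kind = "z")
  cl <- grfClusterThreshold(f, fwhm = c(6, 6, 6), voxelP = 0.001)
  expect_identical(nrow(clusterTable(cl)), 0L)
})

test_that("raising voxel-threshold stringency never enlarges the retained set", {
  f <- synthSmoothField(c(16, 16, 16), c(2.5, 2.5, 2.5), seed = 8)
  d <- mapData(f); d[4:9, 4:9, 4:9] <- d[4:9, 4:9, 4:9] + 3.5
  f2 <- VoxelMap(d, mapMask(f), c(3, 3, 3), "z")
  loose <- grfClusterThreshold(f2, c(7.5, 7.5, 7.5), voxelP = 0.01, clusterP = 0.05)
  strict <- grfClusterThreshold(f2, c(7.5, 7.5, 7.5), voxelP = 0.001, clusterP = 0.05)
  vLoose <- mapData(loose@labels) > 0
  vStrict <- mapData(strict@labels) > 0
  expect_true(all(vLoose[vStrict]))
})

test_that("fwhm must be supplied", {
  f <- synthSmoothField(c(8, 8, 8), c(2, 2, 2), seed = 1)
  expect_error(grfClusterThreshold(f, NULL), "estimate")
})

test_that("GRF and permutation backends agree on an obvious planted effect", {
  set.seed(71)
  n <- 12; dims <- c(10, 10, 8)
  cov <- rnorm(n)
  maps <- lapply(1:n, function(s) {
    f <- synthSmoothField(dims, c(2, 2, 2), seed = 700 + s)
    d <- mapData(f); d[2:6, 2:6, 2:5] <- d[2:6, 2:6, 2:5] + 1.5 * cov[s]
    VoxelMap(d, mapMask(f), c(3, 3, 3), "z")
  })
  sm <- voxelwiseStatMap(maps, cov)
  fw <- estimateSmoothness(voxelResiduals(maps, cov))
  g <- grfClusterThreshold(sm, fw, voxelP = 0.005, clusterP = 0.05)
  p <- permClusterThreshold(maps, cov, voxelP = 0.005, clusterP = 0.05,
                            nPerm = 300, seed = 9)
  expect_gt(nrow(clusterTable(g)), 0)
  expect_gt(nrow(clusterTable(p)), 0)
  expect_setequal(which(mapData(g@labels) > 0) %in% which(mapData(p@labels) > 0), TRUE)
})

test_that("permutation backend is deterministic under a fixed seed", {
  set.seed(81)
  n <- 10
  maps <- lapply(1:n, function(s) synthSmoothField(c(8, 8, 6), c(2, 2, 2), seed = 80 + s))
  cov <- rnorm(n)
  a <- permClusterThreshold(maps, cov, nPerm = 50, seed = 4, voxelP = 0.05)
  b <- permClusterThreshold(maps, cov, nPerm = 50, seed = 4, voxelP = 0.05)
  expect_identical(clusterTable(a), clusterTable(b))
})

test_that("ROI rule counts overlap voxels exhaustively and applies the minimum", {
  lab <- array(0L, c(6, 4, 1))
  lab[1:3, , 1] <- 1L; lab[4:6, , 1] <- 2L   # parcels of 12 voxels each
  regs <- data.frame(id = 1:2, name = c("a", "b"), hemisphere = c("L", "R"))
  parc <- Parcellation(lab, regions = regs)
  # a cluster of 12 voxels: 7 in parcel 1, 5 in parcel 2
  cmask <- array(0, c(6, 4, 1))
  cmask[2:3, 1:3, 1] <- 1; cmask[3, 4, 1] <- 1   # 7 voxels in parcel 1
  cmask[4, 1:4, 1] <- 1; cmask[5, 4, 1] <- 1     # 5 voxels in parcel 2
  clmap <- VoxelMap(cmask, voxelSize = c(3, 3, 3), kind = "z")
  cl <- new("ClusterResult", labels = clmap,
            table = data.frame(cluster = 1L, size = 12L), voxelP = 0.005,
            clusterP = 0.05, fwhm = c(6, 6, 6))
  rois <- clustersToROIs(cl, parc, minVoxels = 6L)
  expect_identical(rois$id, 1L)         # only the 7-voxel parcel qualifies
  expect_identical(rois$n_voxels, 7L)
  all2 <- clustersToROIs(cl, parc, minVoxels = 1L)
  expect_identical(all2$n_voxels, c(7L, 5L))
  bad <- Parcellation(array(1L, c(2, 2, 2)),
                      regions = data.frame(id = 1, name = "x", hemisphere = "L"))
  expect_error(clustersToROIs(cl, bad), "grids")
})
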