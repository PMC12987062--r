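# Implicit-representation super-resolver: coordinate conventions, trilinear
# oracle agreement, explicit branch, feature-field contracts, scale
# contracts and the differential-learning-rate finetune protocol.

test_that("normalized grid follows the voxel-centre convention", {
  g <- normalizedGrid(c(2, 1, 1))
  expect_equal(g$coords[, "z"], c(-1, 1))
  expect_equal(g$coords[, "x"], c(0, 0))
  expect_equal(g$coords[, "y"], c(0, 0))
  g3 <- normalizedGrid(c(3, 3, 3))
  expect_equal(unname(g3$coords[14, ]), c(0, 0, 0))  # centre voxel
  set.seed(61)
  for (i in 1:5) {
    shp <- sample(1:6, 3, replace = TRUE)
    g <- normalizedGrid(shp)
    expect_equal(nrow(g$coords), prod(shp))
    expect_true(all(g$coords >= -1 & g$coords <= 1))
  }
})

test_that("trilinear sampling is exact at voxel centres and at midpoints", {
  v <- randomLabelVolume(c(4, 5, 6))
  oh <- toOneHot(v, 8)
  g <- normalizedGrid(dim(voxels(v)))
  anchors <- trilinearSample(oh, g)
  expect_equal(max(abs(anchors - t(matrix(probValues(oh), nrow = 8)))), 0)
  # midpoint between two voxels with channel values 0 and 1 -> 0.5
  f <- array(0, c(1, 2, 1, 1)); f[1, 2, 1, 1] <- 1
  mid <- trilinearSample(f, matrix(c(0, 0, 0), 1, 3))
  expect_equal(as.numeric(mid), 0.5)
})

test_that("trilinear sampling matches the 8-corner brute-force oracle", {
  set.seed(62)
  for (i in 1:10) {
    v <- randomLabelVolume(c(4, 4, 4), nClasses = 4)
    oh <- probValues(toOneHot(v, 4))
    coords <- matrix(runif(3 * 40, -1, 1), 40, 3)
    got <- trilinearSample(oh, coords)
    want <- oracleTrilinear(oh, coords)
    expect_lt(max(abs(got - want)), 1e-6)
    # anchors stay on the probability simplex
    expect_true(all(got >= -1e-12))
    expect_lt(max(abs(rowSums(got) - 1)), 1e-9)
  }
})

test_that("explicit upsampling interpolates depth only and keeps sums", {
  v <- randomLabelVolume(c(3, 4, 4))
  oh <- toOneHot(v, 8)
  expect_identical(explicitUpsample(oh, 1L), oh)
  up <- explicitUpsample(oh, 2L)
  expect_identical(dim(probValues(up))[2], 6L)
  sums <- colSums(matrix(probValues(up), nrow = 8))
  expect_lt(max(abs(sums - 1)), 1e-9)
  # slice 0 and the last slice are the original end slices
  expect_equal(probValues(up)[, 1, , ], probValues(oh)[, 1, , ])
  expect_equal(probValues(up)[, 6, , ], probValues(oh)[, 3, , ])
  expect_equal(spacing(up)[1], spacing(oh)[1] / 2)
})

test_that("the implicit feature field is pointwise and correctly shaped", {
  m <- buildASVModel(8, seed = 11)
  v <- randomLabelVolume(c(3, 4, 4))
  oh <- toOneHot(v, 8)
  g <- normalizedGrid(c(6, 4, 4))
  anchors <- trilinearSample(oh, g)
  F1 <- inrFeatures(m, g, anchors)
  expect_identical(dim(F1), c(16L, 6L, 4L, 4L))
  # permuting queries then unpermuting equals the unpermuted run
  set.seed(63)
  perm <- sample(nrow(g$coords))
  fm <- whrecon:::inrFeatureMatrix(m, g$coords, anchors)$out
  fmPerm <- whrecon:::inrFeatureMatrix(m, g$coords[perm, ],
                                       anchors[perm, ])$out
  expect_equal(fmPerm[order(perm), ], fm, tolerance = 1e-12)
  # chunked evaluation must not change results
  m2 <- m; m2@config$chunkSize <- 7L
  fmChunk <- whrecon:::inrFeatureMatrix(m2, g$coords, anchors)$out
  expect_equal(fmChunk, fm, tolerance = 1e-12)
})

test_that("super-resolution honours the scale contract", {
  p <- phantomParams(grid = c(12, 24, 24), spacing = c(4, 2, 2),
                     lvAxes = c(8, 10), rvAxes = c(7, 8.5),
                     atriumAxes = c(6, 7.5), myoThickness = c(3, 4),
                     vesselRadius = c(3, 4))
  hr <- generatePhantom(p, seed = 41)
  m <- trainASV(buildASVModel(8, seed = 12), list(hr), scales = 2L,
                epochs = 1, lr = 1e-3, seed = 21)
  for (s in c(2L)) {
    lr <- downsampleZ(hr, s)
    out <- superresolve(m, lr, s)
    expect_identical(dim(voxels(out))[1], s * dim(voxels(lr))[1])
    expect_identical(dim(voxels(out))[2:3], dim(voxels(lr))[2:3])
    expect_equal(spacing(out)[1], spacing(lr)[1] / s)
  }
  expect_error(superresolve(m, downsampleZ(hr, 3L), 3L), "scale")
  expect_error(superresolve(buildASVModel(8, seed = 1), hr, 2L),
               "untrained")
})

test_that("multi-scale training accepts {2,3,4} and reduces the loss", {
  p <- tinyPhantomParams()
  vols <- lapply(1:2, function(i) generatePhantom(p, seed = 600 + i))
  m <- buildASVModel(8, seed = 13)
  m <- trainASV(m, vols, epochs = 3, lr = 1e-3, seed = 22)
  expect_length(m@history, 3)
  expect_lt(m@history[3], m@history[1])
  for (s in c(2L, 3L, 4L)) {
    lr <- downsampleZ(vols[[1]], s)
    out <- superresolve(m, lr, s)
    expect_identical(dim(voxels(out))[1], dim(voxels(vols[[1]])) [1])
  }
})

test_that("differential-lr finetuning honours the multiplier limits", {
  p <- tinyPhantomParams()
  vols <- lapply(1:2, function(i) generatePhantom(p, seed = 700 + i))
  m <- trainASV(buildASVModel(8, seed = 14), vols, epochs = 1, lr = 1e-3,
                seed = 23)
  lrs <- lapply(vols, downsampleZ, zFactor = 2L)
  # multiplier 0: representation path untouched, fusion net moves
  f0 <- finetuneASV(m, lrs, vols, lrMultiplier = 0, epochs = 1, lr = 1e-3,
                    seed = 24)
  expect_identical(f0@mlpParams, m@mlpParams)
  expect_false(identical(f0@psiParams, m@psiParams))
  # multiplier 1: loss trajectory equals uniform-lr training on the same
  # (LR, HR) pairs under the same seed (the training route rebuilds the LR
  # inputs itself by depth decimation)
  f1 <- finetuneASV(m, lrs, vols, lrMultiplier = 1, epochs = 2, lr = 1e-3,
                    seed = 25)
  u1 <- trainASV(m, vols, scales = 2L, epochs = 2, lr = 1e-3,
                 warmupEpochs = 0L, seed = 25)
  expect_equal(f1@history[length(f1@history) - 1:0],
               u1@history[length(u1@history) - 1:0], tolerance = 1e-6)
  expect_warning(finetuneASV(buildASVModel(8, seed = 2), lrs, vols,
                             epochs = 1, seed = 1), "unpretrained")
})
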