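# Degradation operator contracts: neutral identity, integer-shift oracle,
# slice-index arithmetic, noise-event oracles, determinism, preset ordering.

test_that("a neutral configuration is the exact identity for every stage", {
  v <- randomLabelVolume(c(6, 10, 10))
  cfg <- neutralConfig()
  expect_identical(voxels(sliceMisalign(v, cfg, seed = 1)$vol), voxels(v))
  expect_identical(voxels(injectLabelNoise(v, cfg, seed = 1)$vol),
                   voxels(v))
  expect_identical(voxels(downsampleZ(v, 1L)), voxels(v))
  d <- degrade(v, cfg, seed = 1)
  expect_identical(voxels(d$vol), voxels(v))
  expect_equal(spacing(d$vol), spacing(v))
})

test_that("forced integer slice shifts match a roll-with-fill oracle", {
  set.seed(5)
  v <- randomLabelVolume(c(1, 7, 9))
  rec <- new("DegradationRecord",
             transforms = data.frame(slice = 0L, displaced = TRUE, dx = 3,
                                     dy = 0, theta = 0),
             keptSlices = 0L, noiseEvents = whrecon:::emptyNoiseLog(),
             seed = NA_integer_)
  out <- applyMisalignRecord(v, rec)
  sl <- voxels(v)[1, , ]
  expected <- matrix(0L, 7, 9)
  expected[, 4:9] <- sl[, 1:6]  # content moves +3 columns, background fill
  expect_identical(voxels(out)[1, , ], expected)

  rec@transforms$dx <- 0; rec@transforms$dy <- -2
  out2 <- applyMisalignRecord(v, rec)
  expected2 <- matrix(0L, 7, 9)
  expected2[1:5, ] <- sl[3:7, ]
  expect_identical(voxels(out2)[1, , ], expected2)
})

test_that("misalignment never increases foreground and stays in range", {
  cfg <- severityPreset("hard")
  set.seed(9)
  for (i in 1:5) {
    v <- randomLabelVolume(c(5, 12, 12))
    r <- sliceMisalign(v, cfg)
    expect_lte(sum(voxels(r$vol) != 0), sum(voxels(v) != 0))
    tr <- r$record@transforms
    expect_true(all(abs(tr$dx) <= cfg@translationRange))
    expect_true(all(abs(tr$dy) <= cfg@translationRange))
    expect_true(all(abs(tr$theta) <= cfg@rotationRange))
    expect_true(all(voxels(r$vol) %in% 0:7))
  }
})

test_that("downsampleZ keeps exactly the configured residue class", {
  for (D in 2:12) for (f in 1:4) {
    if (D < f) next
    for (ph in 0:(f - 1)) {
      v <- randomLabelVolume(c(D, 4, 4))
      out <- downsampleZ(v, f, ph)
      keptIdx <- seq(ph, D - 1, by = f)
      expect_identical(dim(voxels(out))[1], length(keptIdx))
      expect_identical(dim(voxels(out))[1],
                       as.integer(ceiling((D - ph) / f)))
      expect_identical(voxels(out),
                       voxels(v)[keptIdx + 1, , , drop = FALSE])
      expect_equal(spacing(out)[1], spacing(v)[1] * f)
    }
  }
  expect_error(downsampleZ(randomLabelVolume(c(6, 4, 4)), 2L, 2L), "zPhase")
})

test_that("speckle noise creates exactly the logged number of blobs", {
  cfg <- degradationConfig(noise = list(boundaryProb = 0, boundaryRadius = 1,
                                        speckleRate = 0.15, blobRadius = 1))
  bg <- LabelVolume(array(0L, c(8, 24, 24)))
  r <- injectLabelNoise(bg, cfg, seed = 31)
  log <- r$record@noiseEvents
  expect_gt(nrow(log), 0)
  # verify the blobs of this draw are pairwise disjoint, then count
  # components per slice against the log
  for (d in unique(log$d)) {
    m <- voxels(r$vol)[d + 1, , ] != 0
    lab <- whrecon:::.cc6_label(array(m, c(1, dim(m))), c(1L, dim(m)))
    expect_identical(max(lab), sum(log$d == d))
  }
})

test_that("boundary perturbation only changes voxels near a class boundary", {
  p <- tinyPhantomParams()
  v <- generatePhantom(p, seed = 13)
  cfg <- degradationConfig(noise = list(boundaryProb = 1, boundaryRadius = 2,
                                        speckleRate = 0, blobRadius = 1))
  r <- injectLabelNoise(v, cfg, seed = 8)
  orig <- voxels(v)
  pert <- voxels(r$vol)
  expect_gt(sum(pert != orig), 0)
  # distance-transform oracle, per logged event: a dilated voxel must lie
  # within the structuring radius of the original class mask, an eroded
  # voxel within the radius of its complement (slice plane distances)
  log <- r$record@noiseEvents
  radius <- cfg@noise$boundaryRadius
  for (ev in seq_len(nrow(log))) {
    d <- log$d[ev] + 1L
    cls <- log$class[ev]
    ch <- which(pert[d, , ] != orig[d, , ], arr.ind = TRUE)
    if (nrow(ch) == 0) next
    m2 <- array(orig[d, , ] == cls, c(1L, dim(orig)[2:3]))
    dToM <- whrecon:::.edt_mm(m2, dim(m2), c(1, 1, 1))
    dToC <- whrecon:::.edt_mm(!m2, dim(m2), c(1, 1, 1))
    for (rr in seq_len(nrow(ch))) {
      was <- orig[d, ch[rr, 1], ch[rr, 2]]
      dd <- if (was == cls) dToC[1, ch[rr, 1], ch[rr, 2]] else
        dToM[1, ch[rr, 1], ch[rr, 2]]
      expect_lte(dd, radius + 1e-9)
    }
  }
})

test_that("degradation is deterministic and composes the stage contracts", {
  p <- tinyPhantomParams()
  v <- generatePhantom(p, seed = 2)
  cfg <- severityPreset("medium")
  a <- degrade(v, cfg, seed = 17)
  b <- degrade(v, cfg, seed = 17)
  expect_identical(voxels(a$vol), voxels(b$vol))
  expect_identical(a$record@transforms, b$record@transforms)
  D <- dim(voxels(v))[1]
  expect_identical(dim(voxels(a$vol))[1],
                   as.integer(ceiling((D - cfg@zPhase) / cfg@zFactor)))
  # record re-application reproduces the pre-downsampling stage when no
  # noise events occurred
  cfg2 <- degradationConfig(translationRange = 3, misalignProb = 1)
  m <- sliceMisalign(v, cfg2, seed = 6)
  again <- applyMisalignRecord(v, m$record)
  expect_identical(voxels(again), voxels(m$vol))
})

test_that("severity presets are componentwise monotone", {
  e <- severityPreset("easy"); m <- severityPreset("medium")
  h <- severityPreset("hard")
  expect_identical(e@translationRange, 1); expect_identical(e@rotationRange, 0)
  expect_identical(e@misalignProb, 0.3)
  for (pair in list(list(e, m), list(m, h))) {
    lo <- pair[[1]]; hi <- pair[[2]]
    expect_lte(lo@translationRange, hi@translationRange)
    expect_lte(lo@rotationRange, hi@rotationRange)
    expect_lte(lo@misalignProb, hi@misalignProb)
    expect_lte(lo@noise$boundaryProb, hi@noise$boundaryProb)
    expect_lte(lo@noise$speckleRate, hi@noise$speckleRate)
    expect_identical(lo@zFactor, 2L); expect_identical(hi@zFactor, 2L)
  }
})

test_that("degradation inflates curvature intensity with severity", {
  # ventricular curvature intensity is non-decreasing from clean through
  # easy / medium / hard degradation (seed-averaged); easy barely perturbs
  p <- tinyPhantomParams()
  set.seed(3)
  kClean <- kEasy <- kMed <- kHard <- numeric(8)
  kv <- function(vol) mean(c(
    meanCurvatureIntensity(voxels(vol) == 1L, spacing(vol)),
    meanCurvatureIntensity(voxels(vol) == 2L, spacing(vol))))
  for (i in 1:8) {
    v <- generatePhantom(p, seed = 400 + i)
    kClean[i] <- kv(v)
    kEasy[i] <- kv(degradeToDepth(v, severityPreset("easy"),
                                  seed = 500 + i)$vol)
    kMed[i] <- kv(degradeToDepth(v, severityPreset("medium"),
                                 seed = 500 + i)$vol)
    kHard[i] <- kv(degradeToDepth(v, severityPreset("hard"),
                                  seed = 500 + i)$vol)
  }
  expect_gt(mean(kMed), mean(kClean))
  expect_gt(mean(kHard), mean(kClean))
  expect_gte(mean(kMed), mean(kEasy))
  expect_gte(mean(kHard), mean(kMed))
})
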