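# Surface area, curvature intensity, Dice, HD95/ASSD and the correlation
# analysis, against closed forms and brute-force oracles.

test_that("surface area matches closed forms and manual enumeration", {
  one <- array(TRUE, c(1, 1, 1))
  expect_equal(surfaceArea(one, c(1, 1, 1)), 6)
  # anisotropic single voxel (sz, sy, sx) = (0.5, 0.5, 2):
  # 2 z-faces of sy*sx = 1 each, 2 y-faces of sz*sx = 1 each,
  # 2 x-faces of sz*sy = 0.25 each
  expect_equal(surfaceArea(one, c(0.5, 0.5, 2)), 4.5)
  cube <- array(TRUE, c(10, 10, 10))
  expect_equal(surfaceArea(cube, c(1, 1, 1)), 600)
  # border voxels count outward faces even inside a larger grid
  m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE
  expect_equal(surfaceArea(m, c(1, 1, 1)), 6)
  expect_error(surfaceArea(array(2, c(2, 2, 2))), "binary")
})

test_that("curvature intensity obeys closed form and scaling law", {
  cube <- array(TRUE, c(10, 10, 10))
  expect_equal(meanCurvatureIntensity(cube, c(1, 1, 1)), 0.6)
  expect_equal(meanCurvatureIntensity(array(TRUE, c(1, 1, 1)),
                                      c(1, 1, 1)), 6)
  set.seed(55)
  for (i in 1:5) {
    m <- array(runif(6 * 6 * 6) < 0.4, c(6, 6, 6))
    if (sum(m) == 0) next
    s <- runif(3, 0.5, 2)
    k1 <- meanCurvatureIntensity(m, s)
    k2 <- meanCurvatureIntensity(m, 2 * s)
    expect_equal(k2, k1 / 2, tolerance = 1e-12)
  }
  expect_error(meanCurvatureIntensity(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("curvature variation rate is the relative absolute change", {
  expect_equal(curvatureVariationRate(0.6, 0.6), 0)
  expect_equal(curvatureVariationRate(0.6, 0.3), 0.5)
  expect_equal(curvatureVariationRate(0.6, 0.9), 0.5)
  expect_error(curvatureVariationRate(0, 1), "positive")
})

test_that("surface area equals the brute-force face-count oracle", {
  set.seed(56)
  for (i in 1:30) {
    d <- sample(3:8, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.45, d)
    s <- runif(3, 0.4, 2.5)
    expect_equal(surfaceArea(m, s), oracleSurfaceArea(m, s),
                 tolerance = 1e-9)
  }
})

test_that("Dice handles identity, disjoint and partial overlap", {
  v <- generatePhantom(tinyPhantomParams(), seed = 1)
  d <- diceCoefficient(v, v)
  expect_true(all(d$perClass == 1))
  expect_equal(d$mean, 1)

  a <- LabelVolume(array(0L, c(2, 5, 2)))
  b <- LabelVolume(array(0L, c(2, 5, 2)))
  a@voxels[1, 1:5, 1] <- 1L; a@voxels[2, 1:5, 1] <- 1L
  b@voxels[1, 1:5, 1] <- 1L; b@voxels[1, 1:5, 2] <- 1L
  # a: 10 voxels, b: 10 voxels, 5 overlapping
  expect_equal(unname(diceCoefficient(a, b)$perClass["LV"]), 0.5)

  c1 <- LabelVolume(array(c(1L, 0L), c(2, 1, 1)))
  c2 <- LabelVolume(array(c(0L, 1L), c(2, 1, 1)))
  expect_equal(unname(diceCoefficient(c1, c2)$perClass["LV"]), 0)
  # classes absent in both are excluded from the mean
  expect_true(is.na(diceCoefficient(c1, c2)$perClass["PA"]))
  expect_error(diceCoefficient(a, LabelVolume(array(0L, c(3, 3, 3)))),
               "mismatch")
})

test_that("HD95 and ASSD match the all-pairs brute-force oracle", {
  # two single voxels at offset (0, 0, 3)
  a <- array(FALSE, c(5, 5, 7)); a[3, 3, 2] <- TRUE
  b <- array(FALSE, c(5, 5, 7)); b[3, 3, 5] <- TRUE
  expect_equal(hd95(a, b, c(1, 1, 1)), 3)
  expect_equal(assd(a, b, c(1, 1, 1)), 3)
  expect_equal(hd95(a, a, c(1, 1, 1)), 0)
  expect_equal(assd(a, a, c(1, 1, 1)), 0)

  set.seed(57)
  for (i in 1:25) {
    d <- sample(4:8, 3, replace = TRUE)
    ma <- array(runif(prod(d)) < 0.3, d)
    mb <- array(runif(prod(d)) < 0.3, d)
    if (sum(ma) == 0 || sum(mb) == 0) next
    s <- runif(3, 0.5, 2)
    ds <- oracleSurfaceDistances(ma, mb, s)
    expect_equal(assd(ma, mb, s), mean(ds), tolerance = 1e-6)
    expect_equal(hd95(ma, mb, s),
                 unname(quantile(ds, 0.95, type = 7)), tolerance = 1e-6)
    # symmetry
    expect_equal(assd(ma, mb, s), assd(mb, ma, s), tolerance = 1e-9)
    expect_equal(hd95(ma, mb, s), hd95(mb, ma, s), tolerance = 1e-9)
  }
  expect_error(hd95(a, array(FALSE, c(5, 5, 7))), "empty")
})

test_that("isoperimetric ordering: compact shapes have lower curvature", {
  cube <- array(TRUE, c(6, 6, 6))            # 216 voxels
  slab <- array(TRUE, c(1, 6, 36))           # same volume, elongated
  rod <- array(TRUE, c(1, 1, 216))
  k <- function(m) meanCurvatureIntensity(m, c(1, 1, 1))
  expect_lt(k(cube), k(slab))
  expect_lt(k(slab), k(rod))
  # perforation raises curvature at nearly fixed volume
  holey <- array(TRUE, c(6, 6, 6))
  holey[seq(2, 6, 2), seq(2, 6, 2), seq(2, 6, 2)] <- FALSE
  expect_lt(k(cube), k(holey))
})

test_that("metrics are invariant to a common permutation of class labels", {
  v1 <- generatePhantom(tinyPhantomParams(), seed = 21)
  v2 <- degradeToDepth(v1, severityPreset("medium"), seed = 4)$vol
  perm <- c(0L, sample(1:7))
  relabel <- function(v) {
    LabelVolume(array(perm[voxels(v) + 1L], dim(voxels(v))),
                spacing(v), classNames(v))
  }
  d1 <- diceCoefficient(v1, v2)
  d2 <- diceCoefficient(relabel(v1), relabel(v2))
  expect_equal(unname(sort(d1$perClass)), unname(sort(d2$perClass)))
  expect_equal(d1$mean, d2$mean)
})

test_that("curvature-distance correlation behaves on exact and cohort data", {
  mkReport <- function(kappa, h, a) {
    tab <- data.frame(class = "mean", dice = 1, hd95 = h, assd = a,
                      kappaPre = NA, kappaPost = kappa, rKappa = NA)
    new("MetricsReport", table = tab, caseId = "x", severity = "custom")
  }
  reps <- lapply(1:6, function(i) mkReport(i, 2 * i, 3 * i))
  r <- curvatureDistanceCorrelation(reps)
  expect_equal(r$rHd95, 1)
  expect_equal(r$rAssd, 1)
  repsNeg <- lapply(1:6, function(i) mkReport(i, 10 - i, 10 - i))
  expect_equal(curvatureDistanceCorrelation(repsNeg)$rHd95, -1)
  const <- lapply(1:4, function(i) mkReport(1, 2, 3))
  expect_error(curvatureDistanceCorrelation(const), "constant")
})

test_that("severity drives curvature and surface error together", {
  # Monte-Carlo mirror of the validation-cohort analysis: across a
  # mixed-severity degraded cohort, curvature intensity of the evaluated
  # volume correlates positively with its surface-distance errors
  p <- tinyPhantomParams()
  set.seed(99)
  sevs <- rep(c("easy", "medium", "hard"), 3)
  reps <- lapply(seq_along(sevs), function(i) {
    clean <- generatePhantom(p, seed = 3000 + i)
    deg <- degradeToDepth(clean, severityPreset(sevs[i]),
                          seed = 4000 + i)$vol
    evaluateCase(deg, clean, caseId = paste0("c", i), severity = sevs[i])
  })
  r <- curvatureDistanceCorrelation(reps)
  expect_gt(r$rHd95, 0.5)
  expect_gt(r$rAssd, 0.5)
})

test_that("evaluateCase fills a complete, serializable report", {
  v <- generatePhantom(tinyPhantomParams(), seed = 31)
  deg <- degradeToDepth(v, severityPreset("medium"), seed = 5)$vol
  repIdent <- evaluateCase(v, v, caseId = "self")
  tab <- metricsTable(repIdent)
  expect_equal(tab$dice[tab$class == "mean"], 1)
  expect_equal(tab$hd95[tab$class == "mean"], 0)
  expect_equal(tab$assd[tab$class == "mean"], 0)

  rep2 <- evaluateCase(deg, v, pre = deg, caseId = "c1",
                       severity = "medium")
  df <- as.data.frame(rep2)
  expect_identical(names(df), c("class", "dice", "hd95", "assd", "kappaPre",
                                "kappaPost", "rKappa", "caseId", "severity"))
  expect_equal(nrow(df), 8)  # 7 classes + mean
  # pre == pred here, so rKappa must be 0 for present classes
  expect_true(all(df$rKappa[!is.na(df$rKappa)] < 1e-12))
})
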