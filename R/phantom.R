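# Synthetic whole-heart label phantoms.
#
# Geometry is defined analytically in physical millimetres (ellipsoidal
# chambers, an enclosing myocardial shell with a basal opening, curved
# vessel tubes) and rasterized onto a voxel grid at any requested spacing,
# so the same anatomy can be rendered at several resolutions. Structures are
# placed with precedence LV -> Myo -> RV -> LA -> RA -> AO -> PA; later
# structures never overwrite earlier ones.

#' Phantom generation parameters
#'
#' Ranges are sampled uniformly and independently per phantom. All geometric
#' quantities are in millimetres so that the same sampled anatomy can be
#' rasterized at any voxel spacing (see [rasterizePhantom()]).
#'
#' @param grid Integer `(D, H, W)` voxel grid.
#' @param spacing Numeric `(sz, sy, sx)` mm. The physical field of view is
#'   `grid * spacing`.
#' @param lvAxes Range (mm) of the LV cavity ellipsoid semi-axes.
#' @param rvAxes Range (mm) of the RV semi-axes.
#' @param atriumAxes Range (mm) of the LA/RA semi-axes.
#' @param myoThickness Range (mm) of the myocardial shell thickness.
#' @param vesselRadius Range (mm) of the aorta / pulmonary-artery tube radius.
#' @param poseRotation Max global in-plane rotation, degrees.
#' @param poseTranslation Max global translation, mm.
#' @return A named list of parameters (class `"phantomParams"`).
#' @export
#' @examples
#' p <- phantomParams(grid = c(32, 48, 48), spacing = c(2, 1.5, 1.5))
phantomParams <- function(grid = c(64, 96, 96), spacing = c(2, 1, 1),
                          lvAxes = c(10, 13), rvAxes = c(8.5, 11.5),
                          atriumAxes = c(7, 10), myoThickness = c(3.5, 5),
                          vesselRadius = c(3.5, 5), poseRotation = 10,
                          poseTranslation = 4) {
  stopifnot(length(grid) == 3L, all(grid >= 1), all(spacing > 0),
            myoThickness[1] >= 1e-6,
            all(vapply(list(lvAxes, rvAxes, atriumAxes, myoThickness,
                            vesselRadius),
                       function(r) r[1] > 0 && r[2] >= r[1], TRUE)))
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 lvAxes = lvAxes, rvAxes = rvAxes, atriumAxes = atriumAxes,
                 myoThickness = myoThickness, vesselRadius = vesselRadius,
                 poseRotation = poseRotation,
                 poseTranslation = poseTranslation),
            class = "phantomParams")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Sample one phantom geometry (all in mm, in the grid's physical frame with
# the origin at the first voxel centre). Independent of spacing.
samplePhantomGeometry <- function(params) {
  fov <- (params$grid - 1) * params$spacing  # extent between voxel centres
  c0 <- fov / 2                              # (z, y, x)
  theta <- stats::runif(1, -params$poseRotation, params$poseRotation) * pi / 180
  shift <- stats::runif(3, -params$poseTranslation, params$poseTranslation)
  aLV <- c(runif1(params$lvAxes), runif1(params$lvAxes), runif1(params$lvAxes))
  t <- runif1(params$myoThickness)
  aRV <- c(runif1(params$rvAxes), runif1(params$rvAxes), runif1(params$rvAxes))
  aLA <- c(runif1(params$atriumAxes), runif1(params$atriumAxes),
           runif1(params$atriumAxes))
  aRA <- c(runif1(params$atriumAxes), runif1(params$atriumAxes),
           runif1(params$atriumAxes))
  rAO <- runif1(params$vesselRadius)
  rPA <- runif1(params$vesselRadius)

  # unrotated layout (z, y, x) relative to c0; apex low (-z), base high (+z);
  # atria sit basally offset towards -y, both great vessels arc towards +y,
  # so tubes and atria never cross (collisions would split a clipped tube)
  cLV <- c(-0.12 * fov[1], 0, -0.16 * fov[3])
  cRV <- cLV + c(0, 0, aLV[3] + t + aRV[3] + 1.5)
  cLA <- cLV + c(aLV[1] + t + aLA[1] + 1.5, -0.6 * aLA[2] - 2, 0)
  cRA <- cRV + c(aRV[1] + aRA[1] + 1.5, -0.6 * aRA[2] - 2, 0)
  zCap <- cLV[1] + 0.62 * (aLV[1] + t)   # basal opening above this plane
  # aorta: arc rising from the LV basal opening, bending towards +y
  aoStart <- cLV + c(aLV[1] + t * 0.25, aLV[2] * 0.3, 0)
  aoLen <- aLV[1] + t + 14
  # pulmonary artery: arc rising from the RV roof, also bending towards +y
  # (the two tubes are separated by the LV-RV lateral offset)
  paStart <- cRV + c(aRV[1] * 0.55, aRV[2] * 0.3, 0)
  paLen <- aRV[1] + 12

  list(center = c0, theta = theta, shift = shift,
       cLV = cLV, aLV = aLV, myoT = t, cRV = cRV, aRV = aRV,
       cLA = cLA, aLA = aLA, cRA = cRA, aRA = aRA,
       zCap = zCap, aoStart = aoStart, aoLen = aoLen, rAO = rAO,
       paStart = paStart, paLen = paLen, rPA = rPA)
}

# Rotate (about the z axis, through the FOV centre) and shift a point set
# given as a list of coordinate arrays pz, py, px (mm).
applyPoseInverse <- function(pz, py, px, geom) {
  # map world coords back into the unrotated heart frame
  z <- pz - geom$center[1] - geom$shift[1]
  y <- py - geom$center[2] - geom$shift[2]
  x <- px - geom$center[3] - geom$shift[3]
  ct <- cos(-geom$theta); st <- sin(-geom$theta)
  list(z = z, y = ct * y - st * x, x = st * y + ct * x)
}

insideEllipsoid <- function(q, c, a) {
  ((q$z - c[1]) / a[1])^2 + ((q$y - c[2]) / a[2])^2 +
    ((q$x - c[3]) / a[3])^2 <= 1
}

# Distance-to-arc tube test: arc sampled densely, voxel inside if within
# radius of any sample point.
insideTube <- function(q, start, len, radius, bendSign) {
  ns <- 24L
  s <- seq(0, 1, length.out = ns)
  pz <- start[1] + s * len
  py <- start[2] + bendSign * 0.35 * len * s^2
  px <- start[3] + 0.1 * len * s^2
  inside <- rep(FALSE, length(q$z))
  r2 <- radius^2
  for (i in seq_len(ns)) {
    d2 <- (q$z - pz[i])^2 + (q$y - py[i])^2 + (q$x - px[i])^2
    inside <- inside | (d2 <= r2)
  }
  inside
}

#' Rasterize a sampled phantom geometry
#'
#' Renders a geometry returned by the internal sampler onto a voxel grid.
#' Exposed so that the same anatomy can be rendered at several spacings for
#' resolution-robustness studies.
#'
#' @param geom Geometry list from `samplePhantomGeometry`.
#' @param grid Integer `(D, H, W)`.
#' @param spacing Numeric `(sz, sy, sx)` mm.
#' @param classNames Class map for the result.
#' @return A [LabelVolume-class].
#' @keywords internal
rasterizePhantom <- function(geom, grid, spacing,
                             classNames = whsClassNames()) {
  D <- grid[1]; H <- grid[2]; W <- grid[3]
  pz <- array(rep((0:(D - 1)) * spacing[1], times = H * W), c(D, H, W))
  py <- array(rep(rep((0:(H - 1)) * spacing[2], each = D), times = W),
              c(D, H, W))
  px <- array(rep((0:(W - 1)) * spacing[3], each = D * H), c(D, H, W))
  q <- applyPoseInverse(pz, py, px, geom)

  lab <- array(0L, grid)
  place <- function(mask, cls) {
    sel <- mask & lab == 0L
    lab[sel] <<- cls
  }
  lv <- insideEllipsoid(q, geom$cLV, geom$aLV)
  place(lv, 1L)
  outer <- insideEllipsoid(q, geom$cLV, geom$aLV + geom$myoT)
  belowCap <- q$z <= geom$zCap
  place(outer & belowCap, 5L)
  place(insideEllipsoid(q, geom$cRV, geom$aRV), 2L)
  place(insideEllipsoid(q, geom$cLA, geom$aLA), 3L)
  place(insideEllipsoid(q, geom$cRA, geom$aRA), 4L)
  place(insideTube(q, geom$aoStart, geom$aoLen, geom$rAO, +1), 6L)
  place(insideTube(q, geom$paStart, geom$paLen, geom$rPA, +1), 7L)

  # enclosure repair: any background voxel 6-adjacent to LV below the basal
  # cap becomes myocardium, guaranteeing the shell has no discretization holes
  lvm <- lab == 1L
  nb <- array(FALSE, grid)
  nb[-1, , ] <- nb[-1, , ] | lvm[-D, , ]
  nb[-D, , ] <- nb[-D, , ] | lvm[-1, , ]
  nb[, -1, ] <- nb[, -1, ] | lvm[, -H, ]
  nb[, -H, ] <- nb[, -H, ] | lvm[, -1, ]
  nb[, , -1] <- nb[, , -1] | lvm[, , -W]
  nb[, , -W] <- nb[, , -W] | lvm[, , -1]
  repair <- nb & lab == 0L & belowCap
  lab[repair] <- 5L

  LabelVolume(lab, spacing = spacing, classNames = classNames)
}

#' Generate one synthetic whole-heart label phantom
#'
#' Produces an 8-class label volume with nested-chamber topology: an LV
#' cavity fully enclosed by a myocardial shell except at a basal opening,
#' adjacent non-overlapping RV/LA/RA ellipsoids, and curved aorta/pulmonary
#' tubes rising from the LV and RV regions. Every foreground class is a
#' single 6-connected component (verified, with bounded resampling retries).
#'
#' @param params A [phantomParams()] list.
#' @param seed Optional integer seed (the ambient RNG stream is used when
#'   `NULL`).
#' @param spacing Optional spacing override for rasterization (geometry is
#'   unchanged); defaults to `params$spacing`.
#' @param grid Optional grid override.
#' @param geometry Optional pre-sampled geometry (skips sampling).
#' @return A [LabelVolume-class].
#' @export
#' @examples
#' v <- generatePhantom(phantomParams(grid = c(24, 40, 40),
#'                                    spacing = c(2, 1.5, 1.5)), seed = 1)
#' table(voxels(v))
generatePhantom <- function(params, seed = NULL, spacing = params$spacing,
                            grid = params$grid, geometry = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 1:5) {
    geom <- if (is.null(geometry)) samplePhantomGeometry(params) else geometry
    vol <- rasterizePhantom(geom, grid, spacing)
    counts <- tabulate(vol@voxels, nbins = 7L)
    ok <- all(counts >= 1L)
    if (ok) {
      for (cls in 1:7) {
        ncc <- max(.cc6_label(vol@voxels == cls, dim(vol@voxels)))
        if (ncc != 1L) { ok <- FALSE; break }
      }
    }
    if (ok) {
      attr(vol, "geometry") <- geom
      return(vol)
    }
    if (!is.null(geometry))
      stop("supplied geometry does not rasterize to a valid phantom")
  }
  stop("could not place phantom structures without topology violations ",
       "after 5 retries; enlarge the grid or shrink the structure scales")
}

#' Generate a phantom dataset with a manifest
#'
#' Writes `n` phantoms as NIfTI files plus a CSV manifest recording the
#' per-case seed, split assignment and per-class voxel counts.
#'
#' @param n Number of phantoms (>= 1).
#' @param params A [phantomParams()] list.
#' @param outDir Output directory (created if needed).
#' @param seed Master seed; per-case seeds are derived from it and recorded.
#' @param splits Named numeric proportions summing to 1, assigned in order.
#' @return Invisibly, the manifest data.frame (also written to
#'   `manifest.csv` in `outDir`).
#' @export
generateDataset <- function(n, params, outDir, seed = 1L,
                            splits = c(pretrain = 0.6, finetune = 0.2,
                                       test = 0.2)) {
  stopifnot(n >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  caseSeeds <- sample.int(.Machine$integer.max - 1L, n)
  bounds <- round(cumsum(splits) * n)
  splitOf <- rep(names(splits), times = diff(c(0, bounds)))
  length(splitOf) <- n
  splitOf[is.na(splitOf)] <- names(splits)[length(splits)]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- generatePhantom(params, seed = caseSeeds[i])
    id <- sprintf("phantom_%03d", i)
    path <- file.path(outDir, paste0(id, ".nii.gz"))
    writeLabelVolume(vol, path)
    counts <- tabulate(vol@voxels + 1L, nbins = 8L)
    row <- data.frame(case_id = id, seed = caseSeeds[i], split = splitOf[i],
                      path = path)
    names(counts) <- paste0("n_", whsClassNames())
    rows[[i]] <- cbind(row, as.data.frame(as.list(counts)))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
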