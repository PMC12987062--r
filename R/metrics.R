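# Surface-curvature and overlap/surface-distance metrics. Surface area is
# the physical area of exposed voxel faces (volume-border faces count as
# exposed: the grid is conceptually padded with background); curvature
# intensity is the surface-to-volume ratio S/V (mm^-1); HD95/ASSD pool the
# directed boundary-to-boundary distances of both directions.

padFalse <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d + 2L)
  out[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  out
}

#' Exposed-face surface area of a binary mask
#'
#' Sums the physical area of every voxel face that separates a foreground
#' voxel from a background voxel or from the volume border. Faces normal to
#' z have area `sy * sx`, normal to y `sz * sx`, normal to x `sz * sy`.
#'
#' @param mask Logical (or 0/1) 3D array, slice axis first.
#' @param spacing Numeric `(sz, sy, sx)` in mm.
#' @return Surface area in mm^2.
#' @export
#' @examples
#' surfaceArea(array(TRUE, c(1, 1, 1)), c(1, 1, 1))  # 6
surfaceArea <- function(mask, spacing = c(1, 1, 1)) {
  if (!is.logical(mask)) {
    u <- unique(as.vector(mask))
    if (!all(u %in% c(0, 1))) stop("mask must be binary")
    mask <- mask == 1
  }
  p <- padFalse(mask)
  d <- dim(p)
  facesAlong <- function(ax) {
    idx <- lapply(d, seq_len)
    a <- idx; a[[ax]] <- seq_len(d[ax] - 1L)
    b <- idx; b[[ax]] <- 1L + seq_len(d[ax] - 1L)
    sum(p[a[[1]], a[[2]], a[[3]]] != p[b[[1]], b[[2]], b[[3]]])
  }
  nz <- facesAlong(1); ny <- facesAlong(2); nx <- facesAlong(3)
  nz * spacing[2] * spacing[3] + ny * spacing[1] * spacing[3] +
    nx * spacing[1] * spacing[2]
}

#' Mean curvature intensity (surface-to-volume ratio)
#'
#' `kappa = S / V` in mm^-1, with `S` the exposed-face surface area and `V`
#' the physical voxel volume of the mask. A proxy for boundary jaggedness:
#' by the isoperimetric principle, motion-induced stair-step artifacts
#' inflate `S` at fixed `V`.
#'
#' @inheritParams surfaceArea
#' @return Curvature intensity in mm^-1; error for an empty mask.
#' @export
#' @examples
#' m <- array(TRUE, c(10, 10, 10))
#' meanCurvatureIntensity(m, c(1, 1, 1))  # 6 / L = 0.6
meanCurvatureIntensity <- function(mask, spacing = c(1, 1, 1)) {
  if (!is.logical(mask)) mask <- mask == 1
  n <- sum(mask)
  if (n == 0) stop("curvature intensity undefined for an empty mask")
  surfaceArea(mask, spacing) / (n * prod(spacing))
}

#' Relative curvature variation rate
#'
#' `|kappa_post - kappa_pre| / kappa_pre`, the relative change of curvature
#' intensity between an uncorrected and a corrected state.
#'
#' @param kappaPre Curvature intensity before correction (> 0).
#' @param kappaPost Curvature intensity after correction.
#' @return Non-negative rate.
#' @export
curvatureVariationRate <- function(kappaPre, kappaPost) {
  if (any(kappaPre <= 0)) stop("kappaPre must be positive")
  abs(kappaPost - kappaPre) / kappaPre
}

#' Per-class Dice similarity coefficient
#'
#' For each foreground class `c`: `2 |A_c intersect B_c| / (|A_c| + |B_c|)`.
#' Classes empty in both volumes are excluded from the mean (scoring them 1
#' would inflate means on phantoms missing a structure).
#'
#' @param a,b [LabelVolume-class] objects of identical shape.
#' @return List with `perClass` (named numeric, NA for classes empty in
#'   both) and `mean`.
#' @export
diceCoefficient <- function(a, b) {
  va <- a@voxels; vb <- b@voxels
  if (!identical(dim(va), dim(vb))) stop("shape mismatch")
  C <- length(a@classNames) - 1L
  per <- numeric(C)
  names(per) <- a@classNames[-1]
  for (cls in seq_len(C)) {
    na <- sum(va == cls); nb <- sum(vb == cls)
    per[cls] <- if (na + nb == 0) NA_real_ else
      2 * sum(va == cls & vb == cls) / (na + nb)
  }
  list(perClass = per, mean = mean(per, na.rm = TRUE))
}

# Face-connected boundary voxels of a mask (mask voxels with at least one of
# their 6 neighbours background or outside the volume).
boundaryMask <- function(mask) {
  p <- padFalse(mask)
  d <- dim(mask)
  i1 <- 1 + seq_len(d[1]); i2 <- 1 + seq_len(d[2]); i3 <- 1 + seq_len(d[3])
  interior <- p[i1 - 1, i2, i3] & p[i1 + 1, i2, i3] &
    p[i1, i2 - 1, i3] & p[i1, i2 + 1, i3] &
    p[i1, i2, i3 - 1] & p[i1, i2, i3 + 1]
  mask & !interior
}

# Pooled directed boundary distances (mm) in both directions.
surfaceDistances <- function(aMask, bMask, spacing) {
  if (sum(aMask) == 0 || sum(bMask) == 0)
    stop("surface distances undefined for an empty mask")
  ba <- boundaryMask(aMask); bb <- boundaryMask(bMask)
  dToB <- .edt_mm(bb, dim(bb), spacing)
  dToA <- .edt_mm(ba, dim(ba), spacing)
  c(dToB[ba], dToA[bb])
}

#' 95th-percentile Hausdorff distance
#'
#' The 95th percentile (linear interpolation between order statistics) of
#' the pooled directed boundary-voxel distances of both directions, in mm,
#' honouring anisotropic spacing.
#'
#' @param aMask,bMask Non-empty logical 3D arrays.
#' @param spacing Numeric `(sz, sy, sx)` mm.
#' @return Distance in mm.
#' @export
hd95 <- function(aMask, bMask, spacing = c(1, 1, 1)) {
  unname(quantile(surfaceDistances(aMask, bMask, spacing), 0.95, type = 7))
}

#' Average symmetric surface distance
#'
#' Mean of the pooled directed boundary-voxel distances of both directions,
#' in mm.
#'
#' @inheritParams hd95
#' @return Distance in mm.
#' @export
assd <- function(aMask, bMask, spacing = c(1, 1, 1)) {
  mean(surfaceDistances(aMask, bMask, spacing))
}

#' Correlation of curvature intensity with surface-distance error
#'
#' Pearson correlation (with two-sided p-values) of the evaluated volumes'
#' mean curvature intensity against their HD95 and ASSD across a cohort of
#' case reports — curvature as a proxy for geometric fidelity.
#'
#' @param reports List of [MetricsReport-class] objects (>= 3).
#' @return Named list `rHd95`, `pHd95`, `rAssd`, `pAssd`, `n`.
#' @export
curvatureDistanceCorrelation <- function(reports) {
  if (length(reports) < 3) stop("need at least 3 reports")
  pull <- function(rep, col) {
    tab <- rep@table
    tab[tab$class == "mean", col]
  }
  kappa <- vapply(reports, pull, numeric(1), col = "kappaPost")
  h <- vapply(reports, pull, numeric(1), col = "hd95")
  a <- vapply(reports, pull, numeric(1), col = "assd")
  if (sd(kappa) == 0 || sd(h) == 0 || sd(a) == 0)
    stop("correlation undefined for a constant series")
  th <- cor.test(kappa, h)
  ta <- cor.test(kappa, a)
  list(rHd95 = unname(th$estimate), pHd95 = th$p.value,
       rAssd = unname(ta$estimate), pAssd = ta$p.value,
       n = length(reports))
}

#' Evaluate one case against its reference
#'
#' Computes per-class and mean Dice, HD95 and ASSD of `pred` against `gt`,
#' the curvature intensity of `pred` (post) and, when an uncorrected volume
#' `pre` is supplied, of `pre` along with the relative curvature variation
#' rate per class. Distances are NA for classes empty in either volume.
#'
#' @param pred Predicted [LabelVolume-class].
#' @param gt Reference [LabelVolume-class] (same shape and spacing).
#' @param pre Optional uncorrected [LabelVolume-class] (same shape).
#' @param caseId,severity Metadata recorded in the report.
#' @return A [MetricsReport-class].
#' @export
evaluateCase <- function(pred, gt, pre = NULL, caseId = "case",
                         severity = "custom") {
  if (!identical(dim(pred@voxels), dim(gt@voxels))) stop("shape mismatch")
  if (!isTRUE(all.equal(pred@spacing, gt@spacing)))
    stop("spacing mismatch")
  sp <- pred@spacing
  C <- length(pred@classNames) - 1L
  dice <- diceCoefficient(pred, gt)$perClass
  rows <- data.frame(class = pred@classNames[-1], dice = dice,
                     hd95 = NA_real_, assd = NA_real_,
                     kappaPre = NA_real_, kappaPost = NA_real_,
                     rKappa = NA_real_, stringsAsFactors = FALSE)
  for (cls in seq_len(C)) {
    pm <- pred@voxels == cls; gm <- gt@voxels == cls
    if (sum(pm) > 0 && sum(gm) > 0) {
      dists <- surfaceDistances(pm, gm, sp)
      rows$hd95[cls] <- unname(quantile(dists, 0.95, type = 7))
      rows$assd[cls] <- mean(dists)
    }
    if (sum(pm) > 0) rows$kappaPost[cls] <- meanCurvatureIntensity(pm, sp)
    if (!is.null(pre)) {
      prm <- pre@voxels == cls
      if (sum(prm) > 0) {
        rows$kappaPre[cls] <- meanCurvatureIntensity(prm, pre@spacing)
        if (!is.na(rows$kappaPost[cls]))
          rows$rKappa[cls] <- curvatureVariationRate(rows$kappaPre[cls],
                                                     rows$kappaPost[cls])
      }
    }
  }
  meanRow <- data.frame(class = "mean",
                        dice = mean(rows$dice, na.rm = TRUE),
                        hd95 = mean(rows$hd95, na.rm = TRUE),
                        assd = mean(rows$assd, na.rm = TRUE),
                        kappaPre = mean(rows$kappaPre, na.rm = TRUE),
                        kappaPost = mean(rows$kappaPost, na.rm = TRUE),
                        rKappa = mean(rows$rKappa, na.rm = TRUE),
                        stringsAsFactors = FALSE)
  new("MetricsReport", table = rbind(rows, meanRow),
      caseId = caseId, severity = severity)
}
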