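# Stochastic degradation of clean label volumes: per-slice rigid
# misalignment, label-noise injection and through-plane downsampling —
# emulating breath-hold inter-slice displacement, segmentation defects and
# anisotropic acquisition. Every draw is logged in a DegradationRecord.

#' Severity presets for the degradation operator
#'
#' Three graded parameterizations spanning sub-voxel to gross misalignment.
#' Every range and rate is componentwise non-decreasing from `easy` to
#' `hard`; all use through-plane factor 2 with phase 0 (clinical 1-based
#' "even slices removed", i.e. 0-based indices 0, 2, 4, ... kept).
#'
#' @param level One of `"easy"`, `"medium"`, `"hard"`.
#' @return A [DegradationConfig-class].
#' @export
#' @examples
#' severityPreset("medium")
severityPreset <- function(level = c("easy", "medium", "hard")) {
  level <- match.arg(level)
  switch(level,
    easy = degradationConfig(
      translationRange = 1, rotationRange = 0, misalignProb = 0.3,
      zFactor = 2L, zPhase = 0L,
      noise = list(boundaryProb = 0, boundaryRadius = 1,
                   speckleRate = 0, blobRadius = 1),
      severity = "easy"),
    medium = degradationConfig(
      translationRange = 3, rotationRange = 2, misalignProb = 0.6,
      zFactor = 2L, zPhase = 0L,
      noise = list(boundaryProb = 0.1, boundaryRadius = 1,
                   speckleRate = 0.2, blobRadius = 1),
      severity = "medium"),
    hard = degradationConfig(
      translationRange = 6, rotationRange = 5, misalignProb = 0.9,
      zFactor = 2L, zPhase = 0L,
      noise = list(boundaryProb = 0.3, boundaryRadius = 2,
                   speckleRate = 0.5, blobRadius = 2),
      severity = "hard"))
}

# Nearest-neighbour rigid resampling of one slice (H x W): rotate by theta
# (degrees) about the slice centre, then translate by (dy, dx) voxels.
# Out-of-range sources become background (0).
rigidResampleSlice <- function(slice, dy, dx, theta) {
  H <- nrow(slice); W <- ncol(slice)
  if (theta == 0 && dy == round(dy) && dx == round(dx)) {
    # pure integer shift: exact roll with background fill
    out <- matrix(0L, H, W)
    sh <- (1:H) - as.integer(round(dy)); sw <- (1:W) - as.integer(round(dx))
    okh <- sh >= 1 & sh <= H; okw <- sw >= 1 & sw <= W
    out[okh, okw] <- slice[sh[okh], sw[okw]]
    return(out)
  }
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  th <- theta * pi / 180
  gy <- rep(0:(H - 1), times = W); gx <- rep(0:(W - 1), each = H)
  # inverse map: un-translate, then rotate by -theta about the centre
  yy <- gy - dy - cy; xx <- gx - dx - cx
  sy <- round(cos(th) * yy + sin(th) * xx + cy)
  sx <- round(-sin(th) * yy + cos(th) * xx + cx)
  ok <- sy >= 0 & sy < H & sx >= 0 & sx < W
  out <- integer(H * W)
  out[ok] <- slice[cbind(sy[ok] + 1L, sx[ok] + 1L)]
  matrix(out, H, W)
}

emptyTransforms <- function(D) {
  data.frame(slice = seq_len(D) - 1L, displaced = FALSE, dx = 0, dy = 0,
             theta = 0)
}

emptyNoiseLog <- function() {
  data.frame(slice = integer(), type = character(), class = integer(),
             d = integer(), h = integer(), w = integer(), radius = numeric(),
             op = character())
}

#' Per-slice rigid misalignment
#'
#' Each slice is independently displaced with probability
#' `cfg@misalignProb` by an in-plane rigid transform with translation and
#' rotation sampled uniformly within the configured ranges. Labels are
#' resampled by nearest neighbour (they stay integral); content shifted
#' beyond the slice border becomes background.
#'
#' @param vol A [LabelVolume-class].
#' @param cfg A [DegradationConfig-class].
#' @param seed Optional integer seed.
#' @return List with elements `vol` (degraded [LabelVolume-class]) and
#'   `record` ([DegradationRecord-class] holding the exact applied
#'   transforms).
#' @export
sliceMisalign <- function(vol, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- vol@voxels
  D <- dim(v)[1]
  tr <- emptyTransforms(D)
  if (cfg@misalignProb > 0 &&
      (cfg@translationRange > 0 || cfg@rotationRange > 0)) {
    disp <- runif(D) < cfg@misalignProb
    tr$displaced <- disp
    n <- sum(disp)
    if (n > 0) {
      tr$dx[disp] <- runif(n, -cfg@translationRange, cfg@translationRange)
      tr$dy[disp] <- runif(n, -cfg@translationRange, cfg@translationRange)
      tr$theta[disp] <- runif(n, -cfg@rotationRange, cfg@rotationRange)
    }
  }
  rec <- new("DegradationRecord", transforms = tr,
             keptSlices = seq_len(D) - 1L, noiseEvents = emptyNoiseLog(),
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  list(vol = applyMisalignRecord(vol, rec), record = rec)
}

#' Re-apply a recorded misalignment
#'
#' Applies the exact per-slice transforms of a [DegradationRecord-class] to
#' another volume of the same depth, reproducing the original draw.
#'
#' @param vol A [LabelVolume-class].
#' @param record A [DegradationRecord-class].
#' @return The transformed [LabelVolume-class].
#' @export
applyMisalignRecord <- function(vol, record) {
  v <- vol@voxels
  tr <- record@transforms
  stopifnot(nrow(tr) == dim(v)[1])
  out <- v
  for (i in which(tr$displaced | tr$dx != 0 | tr$dy != 0 | tr$theta != 0)) {
    out[i, , ] <- rigidResampleSlice(v[i, , ], tr$dy[i], tr$dx[i],
                                     tr$theta[i])
  }
  LabelVolume(out, spacing = vol@spacing, classNames = vol@classNames)
}

#' Through-plane downsampling
#'
#' Keeps slices with 0-based index congruent to `zPhase` modulo `zFactor`;
#' the slice spacing is multiplied accordingly.
#'
#' @param vol A [LabelVolume-class] with depth >= `zFactor`.
#' @param zFactor Integer downsampling factor >= 1.
#' @param zPhase Residue class kept, `0 <= zPhase < zFactor`.
#' @return A [LabelVolume-class] of depth `ceiling((D - zPhase) / zFactor)`.
#' @export
downsampleZ <- function(vol, zFactor, zPhase = 0L) {
  zFactor <- as.integer(zFactor); zPhase <- as.integer(zPhase)
  D <- dim(vol@voxels)[1]
  if (zPhase < 0L || zPhase >= zFactor)
    stop("zPhase must be in [0, zFactor)")
  stopifnot(D >= zFactor)
  keep <- seq(zPhase + 1L, D, by = zFactor)
  sp <- vol@spacing; sp[1] <- sp[1] * zFactor
  LabelVolume(vol@voxels[keep, , , drop = FALSE], spacing = sp,
              classNames = vol@classNames)
}

#' Nearest-neighbour through-plane re-expansion
#'
#' Repeats every slice `zFactor` times (optionally cropping/padding to a
#' target depth), the stair-step counterpart of [downsampleZ()]. Used to
#' compare low-resolution stacks against full-depth references and to build
#' stair-step degraded training inputs at the original depth.
#'
#' @param vol A [LabelVolume-class].
#' @param zFactor Integer repetition factor >= 1.
#' @param targetDepth Optional output depth (crop or background-pad at the
#'   end); defaults to `D * zFactor`.
#' @return A [LabelVolume-class]; slice spacing is divided by `zFactor`.
#' @export
zRepeat <- function(vol, zFactor, targetDepth = NULL) {
  zFactor <- as.integer(zFactor)
  v <- vol@voxels
  idx <- rep(seq_len(dim(v)[1]), each = zFactor)
  out <- v[idx, , , drop = FALSE]
  if (!is.null(targetDepth)) {
    D <- dim(out)[1]
    if (targetDepth <= D) {
      out <- out[seq_len(targetDepth), , , drop = FALSE]
    } else {
      pad <- array(0L, c(targetDepth - D, dim(out)[2], dim(out)[3]))
      out <- abind3(out, pad)
    }
  }
  sp <- vol@spacing; sp[1] <- sp[1] / zFactor
  LabelVolume(out, spacing = sp, classNames = vol@classNames)
}

abind3 <- function(a, b) {
  out <- array(0L, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# 2D disk structuring-element offsets for a given voxel radius.
diskOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dh = -r:r, dw = -r:r)
  g[g$dh^2 + g$dw^2 <= radius^2 + 1e-9, ]
}

dilate2d <- function(mask, off) {
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  for (k in seq_len(nrow(off))) {
    h <- idx[, 1] + off$dh[k]; w <- idx[, 2] + off$dw[k]
    ok <- h >= 1 & h <= H & w >= 1 & w <= W
    out[cbind(h[ok], w[ok])] <- TRUE
  }
  out
}

erode2d <- function(mask, off) {
  !dilate2d(!mask, off)
}

#' Inject synthetic label noise
#'
#' Emulates segmentation defects: (a) per slice, with probability
#' `noise$boundaryProb`, one randomly chosen foreground class is dilated or
#' eroded within a random sub-window by a disk of radius
#' `noise$boundaryRadius`; (b) per slice, `Poisson(noise$speckleRate)` small
#' blobs of radius `noise$blobRadius` are flipped to a random wrong
#' foreground class. All events are logged in the record.
#'
#' @inheritParams sliceMisalign
#' @return List with elements `vol` and `record`.
#' @export
injectLabelNoise <- function(vol, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- vol@voxels
  D <- dim(v)[1]; H <- dim(v)[2]; W <- dim(v)[3]
  nz <- cfg@noise
  events <- list()
  if (nz$boundaryProb > 0) {
    offB <- diskOffsets(nz$boundaryRadius)
    for (d in seq_len(D)) {
      if (runif(1) >= nz$boundaryProb) next
      sl <- v[d, , ]
      present <- setdiff(unique(as.vector(sl)), 0L)
      if (length(present) == 0) next
      cls <- present[sample.int(length(present), 1)]
      # random sub-window covering about a quarter of the slice
      wh <- max(4L, H %/% 2L); ww <- max(4L, W %/% 2L)
      h0 <- sample.int(H - wh + 1L, 1); w0 <- sample.int(W - ww + 1L, 1)
      op <- sample(c("dilate", "erode"), 1)
      win <- sl[h0:(h0 + wh - 1L), w0:(w0 + ww - 1L)]
      m <- win == cls
      m2 <- if (op == "dilate") dilate2d(m, offB) else erode2d(m, offB)
      # dilation claims neighbouring voxels; erosion reverts to background
      win[m2 & !m] <- cls
      win[m & !m2] <- 0L
      sl[h0:(h0 + wh - 1L), w0:(w0 + ww - 1L)] <- win
      v[d, , ] <- sl
      events[[length(events) + 1L]] <- data.frame(
        slice = d - 1L, type = "boundary", class = cls, d = d - 1L,
        h = h0 - 1L, w = w0 - 1L, radius = nz$boundaryRadius, op = op)
    }
  }
  if (nz$speckleRate > 0) {
    offS <- diskOffsets(nz$blobRadius)
    C <- length(vol@classNames) - 1L
    for (d in seq_len(D)) {
      nb <- rpois(1, nz$speckleRate)
      for (b in seq_len(nb)) {
        h <- sample.int(H, 1); w <- sample.int(W, 1)
        cur <- v[d, h, w]
        cls <- sample(setdiff(1:C, cur), 1)
        hh <- h + offS$dh; ww <- w + offS$dw
        ok <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
        sl <- v[d, , ]
        sl[cbind(hh[ok], ww[ok])] <- cls
        v[d, , ] <- sl
        events[[length(events) + 1L]] <- data.frame(
          slice = d - 1L, type = "speckle", class = cls, d = d - 1L,
          h = h - 1L, w = w - 1L, radius = nz$blobRadius, op = "flip")
      }
    }
  }
  log <- if (length(events)) do.call(rbind, events) else emptyNoiseLog()
  rec <- new("DegradationRecord", transforms = emptyTransforms(D),
             keptSlices = seq_len(D) - 1L, noiseEvents = log,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  list(vol = LabelVolume(v, spacing = vol@spacing,
                         classNames = vol@classNames),
       record = rec)
}

#' Full stochastic degradation
#'
#' Composition misalign -> noise -> through-plane downsampling with a single
#' merged record; deterministic under a fixed seed. A neutral configuration
#' (zero ranges and rates, factor 1) is the exact identity.
#'
#' @inheritParams sliceMisalign
#' @return List with elements `vol` and `record`.
#' @seealso [severityPreset()], [zRepeat()]
#' @export
degrade <- function(vol, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sliceMisalign(vol, cfg)
  n <- injectLabelNoise(m$vol, cfg)
  out <- downsampleZ(n$vol, cfg@zFactor, cfg@zPhase)
  D <- dim(vol@voxels)[1]
  kept <- seq(cfg@zPhase, D - 1L, by = cfg@zFactor)
  rec <- new("DegradationRecord", transforms = m$record@transforms,
             keptSlices = as.integer(kept),
             noiseEvents = n$record@noiseEvents,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  list(vol = out, record = rec)
}

#' Degrade and re-expand to the original depth
#'
#' Convenience composition used to build motion-correction training pairs:
#' [degrade()] followed by [zRepeat()] back to the input depth, producing a
#' stair-step, misaligned, noisy volume on the clean volume's grid.
#'
#' @inheritParams sliceMisalign
#' @return List with elements `vol` (same shape as the input) and `record`.
#' @export
degradeToDepth <- function(vol, cfg, seed = NULL) {
  d <- degrade(vol, cfg, seed = seed)
  vol2 <- zRepeat(d$vol, cfg@zFactor, targetDepth = dim(vol@voxels)[1])
  vol2@spacing <- vol@spacing
  list(vol = vol2, record = d$record)
}
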