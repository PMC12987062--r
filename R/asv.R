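# Anisotropic z-axis super-resolution (ASV): the label field is modelled as
# a continuous function of normalized coordinates. Trilinear sampling of the
# low-resolution one-hot stack provides coarse semantic anchors; a
# coordinate-conditioned MLP turns [x, y, z, anchors] into a continuous
# feature field; a shallow fusion conv net combines that field with an
# explicitly z-interpolated label tensor into per-class logits. Trained
# multi-scale by dynamically decimating clean high-resolution volumes.

#' ASVModel: implicit-representation through-plane super-resolver
#'
#' @slot mlpParams Dense stack parameters of the coordinate MLP.
#' @slot psiLayers,psiParams Fusion conv net specification and parameters.
#' @slot config Named list: `nClasses`, `cPrime`, `hidden`, `scales`,
#'   `chunkSize`.
#' @slot trained Logical.
#' @slot history Numeric per-epoch training loss.
#' @export
setClass("ASVModel",
  representation(mlpParams = "list", psiLayers = "list", psiParams = "list",
                 config = "list", trained = "logical", history = "numeric"))

setMethod("show", "ASVModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ASVModel: %d classes + 3 coords -> C' = %d, scales {%s}, %s\n",
    cfg$nClasses, cfg$cPrime, paste(cfg$scales, collapse = ","),
    if (object@trained) sprintf("trained (%d epochs)",
                                length(object@history)) else "untrained"))
})

#' Build the through-plane super-resolution model
#'
#' @param nClasses Label classes including background (MLP input width is
#'   `nClasses + 3`).
#' @param cPrime Width of the implicit feature field.
#' @param hidden Hidden widths of the coordinate MLP.
#' @param psiChannels Width of the fusion net's intermediate layers.
#' @param scales Integer super-resolution scales the model is trained for.
#' @param chunkSize Number of coordinate queries processed per block
#'   (bounds memory; results are independent of it).
#' @param seed Optional seed for initialization.
#' @return An untrained [ASVModel-class].
#' @export
#' @examples
#' buildASVModel(8, seed = 1)
buildASVModel <- function(nClasses = 8L, cPrime = 16L, hidden = c(32L, 32L),
                          psiChannels = 16L, scales = c(2L, 3L, 4L),
                          chunkSize = 65536L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mlp <- mlpInit(c(nClasses + 3L, hidden, cPrime))
  psi <- list(
    convLayer(nClasses + cPrime, psiChannels, c(1, 3, 3)),
    convLayer(psiChannels, psiChannels, c(3, 1, 1)),
    convLayer(psiChannels, nClasses, c(1, 1, 1), act = "linear")
  )
  new("ASVModel", mlpParams = mlp, psiLayers = psi, psiParams = nnInit(psi),
      config = list(nClasses = as.integer(nClasses),
                    cPrime = as.integer(cPrime), hidden = as.integer(hidden),
                    psiChannels = as.integer(psiChannels),
                    scales = as.integer(scales),
                    chunkSize = as.integer(chunkSize)),
      trained = FALSE, history = numeric())
}

#' Normalized coordinate grid of a target shape
#'
#' Voxel-centre convention: index `i` along an axis of length `n` maps to
#' `-1 + 2 i / (n - 1)` (an axis of length 1 maps to 0), so the first and
#' last voxel centres sit exactly at -1 and +1. Points are ordered
#' depth-fastest, then rows, then columns, matching the channel-first array
#' layout.
#'
#' @param targetShape Integer `(D, H, W)`, all >= 1.
#' @return List with `coords` (`N x 3` matrix, columns x, y, z in
#'   `[-1, 1]`) and `targetShape`.
#' @export
#' @examples
#' normalizedGrid(c(2, 1, 1))$coords
normalizedGrid <- function(targetShape) {
  targetShape <- as.integer(targetShape)
  stopifnot(length(targetShape) == 3L, all(targetShape >= 1L))
  ax <- function(n) if (n == 1L) 0 else -1 + 2 * (0:(n - 1)) / (n - 1)
  D <- targetShape[1]; H <- targetShape[2]; W <- targetShape[3]
  z <- rep(ax(D), times = H * W)
  y <- rep(rep(ax(H), each = D), times = W)
  x <- rep(ax(W), each = D * H)
  list(coords = cbind(x = x, y = y, z = z), targetShape = targetShape)
}

#' Trilinear semantic anchors
#'
#' Samples every channel of a soft label volume at the grid's normalized
#' coordinates with the same centre-aligned convention as
#' [normalizedGrid()]. Because interpolation weights are convex, each
#' anchor row remains a probability vector.
#'
#' @param lr A [ProbabilityVolume-class] (or channel-first 4D array).
#' @param grid A grid from [normalizedGrid()], or an `N x 3` coordinate
#'   matrix.
#' @return `N x C` matrix of interpolated class probabilities.
#' @export
trilinearSample <- function(lr, grid) {
  v <- if (is(lr, "ProbabilityVolume")) lr@values else lr
  coords <- if (is.list(grid)) grid$coords else grid
  stopifnot(ncol(coords) == 3L, all(abs(coords) <= 1 + 1e-12))
  .trilinear_sample(v, dim(v), coords)
}

#' Explicit through-plane interpolation
#'
#' Linear interpolation along the slice axis only, to depth
#' `sZ * D`; in-plane content is untouched and channel sums remain 1. The
#' topology-preserving explicit branch of the super-resolver.
#'
#' @param lr A [ProbabilityVolume-class].
#' @param sZ Integer scale >= 1.
#' @return A [ProbabilityVolume-class] of depth `sZ * D`.
#' @export
explicitUpsample <- function(lr, sZ) {
  sZ <- as.integer(sZ)
  stopifnot(sZ >= 1L)
  if (sZ == 1L) return(lr)
  v <- lr@values
  Dlr <- dim(v)[2]
  Dhr <- sZ * Dlr
  # centre-aligned: target j (0-based) -> source position j*(Dlr-1)/(Dhr-1)
  t <- if (Dhr > 1) (0:(Dhr - 1)) * (Dlr - 1) / (Dhr - 1) else 0
  lo <- pmin(floor(t), Dlr - 1); hi <- pmin(lo + 1, Dlr - 1)
  f <- t - lo
  out <- array(0, c(dim(v)[1], Dhr, dim(v)[3], dim(v)[4]))
  for (j in seq_len(Dhr)) {
    a <- v[, lo[j] + 1, , , drop = FALSE]
    b <- v[, hi[j] + 1, , , drop = FALSE]
    out[, j, , ] <- (1 - f[j]) * a + f[j] * b
  }
  sp <- lr@spacing; sp[1] <- sp[1] / sZ
  ProbabilityVolume(out, spacing = sp)
}

# Evaluate the coordinate MLP over [coords, anchors] in chunks; returns the
# N x C' feature matrix (and caches when keep = TRUE, for training).
inrFeatureMatrix <- function(model, coords, anchors, keep = FALSE) {
  N <- nrow(coords)
  cs <- model@config$chunkSize
  inp <- cbind(coords, anchors)
  if (!keep && N > cs) {
    out <- matrix(0, N, model@config$cPrime)
    for (start in seq(1L, N, by = cs)) {
      end <- min(start + cs - 1L, N)
      out[start:end, ] <- mlpForward(model@mlpParams,
                                     inp[start:end, , drop = FALSE],
                                     keep = FALSE)$out
    }
    return(list(out = out, caches = NULL))
  }
  mlpForward(model@mlpParams, inp, keep = keep)
}

#' Implicit feature field
#'
#' Applies the coordinate-conditioned MLP pointwise to the concatenation
#' `[x, y, z, anchors]` and reshapes the result depth-fastest into a
#' channel-first 4D field `(C', D_hr, H, W)`.
#'
#' @param model An [ASVModel-class].
#' @param grid A grid from [normalizedGrid()].
#' @param anchors `N x C` anchor matrix from [trilinearSample()].
#' @return 4D array `(cPrime, D_hr, H, W)`.
#' @export
inrFeatures <- function(model, grid, anchors) {
  stopifnot(nrow(grid$coords) == nrow(anchors))
  fm <- inrFeatureMatrix(model, grid$coords, anchors)$out
  array(t(fm), c(ncol(fm), grid$targetShape))
}

# Full forward pass at scale sZ from a one-hot LR array; returns the
# probability array plus caches for training.
asvForward <- function(model, lrProbs, sZ, keep = FALSE) {
  dlr <- dim(lrProbs@values)
  target <- c(dlr[2] * sZ, dlr[3], dlr[4])
  grid <- normalizedGrid(target)
  anchors <- trilinearSample(lrProbs, grid)
  fm <- inrFeatureMatrix(model, grid$coords, anchors, keep = keep)
  feats <- array(t(fm$out), c(model@config$cPrime, target))
  xup <- explicitUpsample(lrProbs, sZ)
  M <- array(0, c(dlr[1] + model@config$cPrime, target))
  M[seq_len(dlr[1]), , , ] <- xup@values
  M[dlr[1] + seq_len(model@config$cPrime), , , ] <- feats
  fpsi <- nnForward(model@psiLayers, model@psiParams, M, keep = keep)
  P <- channelSoftmax(fpsi$out)
  list(P = P, psiCaches = fpsi$caches, mlpCaches = fm$caches,
       target = target, xupSpacing = xup@spacing)
}

#' Super-resolve a label volume along the slice axis
#'
#' One-hot encodes the input, evaluates the implicit + explicit branches at
#' an `sZ`-times denser slice grid, fuses them, and argmaxes the resulting
#' class probabilities. Output depth is exactly `sZ * D`; slice spacing is
#' divided by `sZ`; in-plane geometry is unchanged.
#'
#' @param model A trained [ASVModel-class].
#' @param vol A [LabelVolume-class] low-resolution input.
#' @param sZ Integer scale; must be in the model's trained scale set.
#' @return A [LabelVolume-class] of depth `sZ * D`.
#' @export
superresolve <- function(model, vol, sZ) {
  if (!model@trained) stop("model is untrained; run trainASV first")
  sZ <- as.integer(sZ)
  if (!(sZ %in% model@config$scales))
    stop("scale ", sZ, " not in the trained scale set {",
         paste(model@config$scales, collapse = ","), "}")
  lr <- toOneHot(vol, model@config$nClasses)
  fw <- asvForward(model, lr, sZ)
  sp <- vol@spacing; sp[1] <- sp[1] / sZ
  argmaxLabels(ProbabilityVolume(fw$P, spacing = sp), vol@classNames)
}

asvTrainState <- function(model) {
  list(mlp = model@mlpParams, psi = model@psiParams,
       mlpM = adamInit(model@mlpParams), mlpV = adamInit(model@mlpParams),
       psiM = adamInit(model@psiParams), psiV = adamInit(model@psiParams),
       t = 0L)
}

# One optimisation step: LR one-hot input, HR one-hot target, scale sZ.
# lrMlp scales the representation-path learning rate (differential lr).
# `warmup` descends a cross-entropy surrogate (see dslStep); the logged
# loss is always the combined objective.
asvStep <- function(model, state, lrProbs, yArr, sZ, lr, lrMlp,
                    lambda1, lambda2, eps, warmup = FALSE) {
  model@mlpParams <- state$mlp
  model@psiParams <- state$psi
  fw <- asvForward(model, lrProbs, sZ, keep = TRUE)
  lg <- combinedLossGrad(fw$P, yArr, lambda1, lambda2, eps)
  gLogits <- if (warmup) (fw$P - yArr) / prod(dim(yArr)[-1]) else
    softmaxBackward(fw$P, lg$grad)
  bp <- nnBackward(model@psiLayers, state$psi, fw$psiCaches, gLogits)
  state$t <- state$t + 1L
  rp <- adamStep(state$psi, bp$grads, state$psiM, state$psiV, state$t, lr)
  state$psi <- rp$p; state$psiM <- rp$m; state$psiV <- rp$v
  if (lrMlp > 0) {
    nC <- model@config$nClasses
    gF <- bp$gx[nC + seq_len(model@config$cPrime), , , , drop = FALSE]
    gFm <- t(matrix(gF, nrow = model@config$cPrime))
    bm <- mlpBackward(state$mlp, fw$mlpCaches, gFm)
    rm <- adamStep(state$mlp, bm$grads, state$mlpM, state$mlpV, state$t,
                   lrMlp)
    state$mlp <- rm$p; state$mlpM <- rm$m; state$mlpV <- rm$v
  }
  state$loss <- lg$total
  state
}

#' Train the super-resolver by multi-scale degradation reconstruction
#'
#' Each step draws a scale `s` from the configured scale set, decimates a
#' clean high-resolution volume along z by `s` ([downsampleZ()]), and
#' supervises the full pipeline against the high-resolution one-hot target
#' with the combined L1 + Dice loss. Volume depths must be divisible by
#' every trained scale.
#'
#' @param model An [ASVModel-class].
#' @param volumes List of clean high-resolution [LabelVolume-class] cases.
#' @param scales Scales to train (defaults to the model's configured set).
#' @inheritParams pretrainDSL
#' @return The trained [ASVModel-class].
#' @export
trainASV <- function(model, volumes, scales = model@config$scales,
                     epochs = 12L, lr = 1e-4, lambda1 = 0.5, lambda2 = 0.5,
                     eps = 1e-5, warmupEpochs = max(1L, round(epochs / 3)),
                     seed = NULL, verbose = FALSE) {
  if (length(volumes) < 1) stop("need at least one training case")
  if (!is.null(seed)) set.seed(seed)
  nC <- model@config$nClasses
  state <- asvTrainState(model)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(volumes))
    losses <- numeric(length(ord))
    for (j in seq_along(ord)) {
      hr <- volumes[[ord[j]]]
      s <- if (length(scales) == 1L) scales else sample(scales, 1)
      if (dim(hr@voxels)[1] %% s != 0L)
        stop("depth ", dim(hr@voxels)[1], " not divisible by scale ", s)
      lrv <- downsampleZ(hr, s)
      lrProbs <- toOneHot(lrv, nC)
      yArr <- toOneHot(hr, nC)@values
      state <- asvStep(model, state, lrProbs, yArr, s, lr, lr,
                       lambda1, lambda2, eps, warmup = ep <= warmupEpochs)
      if (!is.finite(state$loss))
        stop("NaN/Inf loss at epoch ", ep, ", case ", ord[j])
      losses[j] <- state$loss
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  model@mlpParams <- state$mlp
  model@psiParams <- state$psi
  model@trained <- TRUE
  model@config$scales <- sort(unique(as.integer(scales)))
  model@history <- c(model@history, history)
  model
}

#' Finetune the super-resolver with differential learning rates
#'
#' All parameters remain trainable, but the pretrained representation path
#' (the coordinate MLP) learns at `lr * lrMultiplier` while the fusion
#' decoder learns at the full rate — adapting the output morphology to the
#' target domain without overwriting the learned continuous-shape prior.
#' Training pairs are explicit (low-resolution, high-resolution) volumes
#' from the target domain.
#'
#' @param model A pretrained [ASVModel-class] (warning otherwise).
#' @param lrVolumes,hrVolumes Parallel lists of [LabelVolume-class] pairs;
#'   each HR depth must be an exact multiple of its LR depth, with the
#'   factor in the model's scale set.
#' @param lrMultiplier Representation-path learning-rate factor in `[0, 1]`.
#' @inheritParams pretrainDSL
#' @return The finetuned [ASVModel-class].
#' @export
finetuneASV <- function(model, lrVolumes, hrVolumes, lrMultiplier = 0.1,
                        epochs = 5L, lr = 1e-4, lambda1 = 0.5,
                        lambda2 = 0.5, eps = 1e-5, seed = NULL,
                        verbose = FALSE) {
  if (!model@trained) warning("finetuning an unpretrained model")
  stopifnot(length(lrVolumes) == length(hrVolumes))
  if (!is.null(seed)) set.seed(seed)
  nC <- model@config$nClasses
  state <- asvTrainState(model)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(lrVolumes))
    losses <- numeric(length(ord))
    for (j in seq_along(ord)) {
      lrv <- lrVolumes[[ord[j]]]; hrv <- hrVolumes[[ord[j]]]
      s <- dim(hrv@voxels)[1] %/% dim(lrv@voxels)[1]
      stopifnot(dim(hrv@voxels)[1] == s * dim(lrv@voxels)[1])
      state <- asvStep(model, state, toOneHot(lrv, nC),
                       toOneHot(hrv, nC)@values, s, lr,
                       lr * lrMultiplier, lambda1, lambda2, eps)
      losses[j] <- state$loss
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("finetune epoch %d: loss %.4f", ep,
                                 history[ep]))
  }
  model@mlpParams <- state$mlp
  model@psiParams <- state$psi
  model@history <- c(model@history, history)
  model
}
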