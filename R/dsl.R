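# Deep structure-consistency learning (DSL): an anisotropic 3D convolutional
# autoencoder that projects motion-corrupted label volumes onto a learned
# anatomical manifold. The encoder compresses in-plane only (two (1,2,2)
# max-poolings, factor 4) while preserving the slice axis, producing a
# spatially structured latent volume map (C_latent, D, H/4, W/4). Training
# follows the cross-modality protocol: full training on degraded/clean
# synthetic pairs ("CT" phase), then target-domain finetuning with the
# decoder frozen so the learned structural smoothness is retained.

#' DSLModel: shape-prior autoencoder for motion correction
#'
#' @slot encoderLayers,decoderLayers Layer specifications.
#' @slot encoderParams,decoderParams Parameter lists.
#' @slot config Named list: `inChannels`, `latentChannels`, `convChannels`,
#'   `nPoolStages`.
#' @slot trained Logical.
#' @slot history Numeric per-epoch mean training loss.
#' @export
setClass("DSLModel",
  representation(encoderLayers = "list", decoderLayers = "list",
                 encoderParams = "list", decoderParams = "list",
                 config = "list", trained = "logical", history = "numeric"))

setMethod("show", "DSLModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DSLModel: %d -> latent %d channels, in-plane /%d, %s\n",
    cfg$inChannels, cfg$latentChannels, 2^cfg$nPoolStages,
    if (object@trained) sprintf("trained (%d epochs)",
                                length(object@history)) else "untrained"))
})

#' Build the shape-prior autoencoder
#'
#' The encoder interleaves convolutions with `nPoolStages` in-plane (1,2,2)
#' max-poolings down to `latentChannels` feature channels; the decoder
#' mirrors it with (1,2,2) nearest upsampling and ends in per-class logits.
#' The slice axis is never pooled, so the latent volume map has shape
#' `(latentChannels, D, H/4, W/4)` for the default two pooling stages.
#'
#' @param inChannels Number of label classes including background.
#' @param latentChannels Latent channel count (default 64).
#' @param convChannels Widths of the two pre-latent conv stages.
#' @param seed Optional seed for parameter initialization.
#' @return An untrained [DSLModel-class].
#' @export
#' @examples
#' m <- buildDSLModel(8, seed = 1)
#' m
buildDSLModel <- function(inChannels = 8L, latentChannels = 64L,
                          convChannels = c(12L, 16L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c1 <- convChannels[1]; c2 <- convChannels[2]
  enc <- list(
    convLayer(inChannels, c1, c(1, 3, 3)),
    poolLayer(2L),
    convLayer(c1, c2, c(3, 3, 3)),
    poolLayer(2L),
    convLayer(c2, latentChannels, c(3, 1, 1))
  )
  dec <- list(
    convLayer(latentChannels, c2, c(3, 1, 1)),
    upLayer(2L),
    convLayer(c2, c1, c(3, 3, 3)),
    upLayer(2L),
    convLayer(c1, inChannels, c(1, 3, 3), act = "linear")
  )
  new("DSLModel", encoderLayers = enc, decoderLayers = dec,
      encoderParams = nnInit(enc), decoderParams = nnInit(dec),
      config = list(inChannels = as.integer(inChannels),
                    latentChannels = as.integer(latentChannels),
                    convChannels = as.integer(convChannels),
                    nPoolStages = 2L),
      trained = FALSE, history = numeric())
}

checkDivisible <- function(d, by = 4L) {
  if (d[3] %% by != 0L || d[4] %% by != 0L)
    stop("in-plane dimensions must be divisible by ", by,
         " (use dslCorrect, which pads automatically)")
}

#' Encode a soft label volume into the latent volume map
#'
#' @param model A [DSLModel-class].
#' @param probs A [ProbabilityVolume-class] whose in-plane dims divide 4.
#' @return 4D array `(latentChannels, D, H/4, W/4)`.
#' @export
dslEncode <- function(model, probs) {
  x <- if (is(probs, "ProbabilityVolume")) probs@values else probs
  checkDivisible(dim(x))
  nnForward(model@encoderLayers, model@encoderParams, x, keep = FALSE)$out
}

#' Decode a latent volume map into class probabilities
#'
#' @param model A [DSLModel-class].
#' @param latent 4D array from [dslEncode()].
#' @param spacing Spacing for the returned volume.
#' @return A [ProbabilityVolume-class] (softmax over channels).
#' @export
dslDecode <- function(model, latent, spacing = c(1, 1, 1)) {
  logits <- nnForward(model@decoderLayers, model@decoderParams, latent,
                      keep = FALSE)$out
  ProbabilityVolume(channelSoftmax(logits), spacing = spacing)
}

# One optimisation step on a (degraded, clean) one-hot pair; returns updated
# state. `freezeDecoder` stops decoder updates (gradients still flow through
# it to the encoder). With `warmup` the step descends a cross-entropy
# surrogate: the L1 + Dice objective has vanishing gradients wherever the
# softmax saturates, so from a random initialization it stalls in a
# constant-prediction plateau; a brief cross-entropy phase moves the model
# into the regime where the dual objective is well conditioned. The logged
# loss is always the combined objective.
dslStep <- function(state, x, y, lr, lambda1, lambda2, eps,
                    freezeDecoder = FALSE, warmup = FALSE) {
  fe <- nnForward(state$encLayers, state$encParams, x)
  fd <- nnForward(state$decLayers, state$decParams, fe$out)
  P <- channelSoftmax(fd$out)
  lg <- combinedLossGrad(P, y, lambda1, lambda2, eps)
  gLogits <- if (warmup) (P - y) / prod(dim(y)[-1]) else
    softmaxBackward(P, lg$grad)
  bd <- nnBackward(state$decLayers, state$decParams, fd$caches, gLogits)
  be <- nnBackward(state$encLayers, state$encParams, fe$caches, bd$gx,
                   skipInputGrad = TRUE)
  state$t <- state$t + 1L
  re <- adamStep(state$encParams, be$grads, state$encM, state$encV,
                 state$t, lr)
  state$encParams <- re$p; state$encM <- re$m; state$encV <- re$v
  if (!freezeDecoder) {
    rd <- adamStep(state$decParams, bd$grads, state$decM, state$decV,
                   state$t, lr)
    state$decParams <- rd$p; state$decM <- rd$m; state$decV <- rd$v
  }
  state$loss <- lg$total
  state
}

dslTrainState <- function(model) {
  list(encLayers = model@encoderLayers, decLayers = model@decoderLayers,
       encParams = model@encoderParams, decParams = model@decoderParams,
       encM = adamInit(model@encoderParams),
       encV = adamInit(model@encoderParams),
       decM = adamInit(model@decoderParams),
       decV = adamInit(model@decoderParams), t = 0L)
}

asTrainingPair <- function(x, y, nClasses) {
  list(x = toOneHot(x, nClasses)@values, y = toOneHot(y, nClasses)@values)
}

#' Pretrain the shape prior on synthetic degraded/clean pairs
#'
#' The manifold-learning phase: each epoch draws a fresh stochastic
#' degradation of every clean volume (augmentation semantics) and minimises
#' the combined L1 + Dice reconstruction loss against the clean target with
#' Adam. Degraded inputs are built at the clean volume's depth
#' (misalignment, noise, through-plane decimation and stair-step
#' re-expansion; see [degradeToDepth()]).
#'
#' @param model An untrained or partially trained [DSLModel-class].
#' @param volumes List of clean [LabelVolume-class] training cases.
#' @param degradationConfig A [DegradationConfig-class] for augmentation.
#' @param epochs Number of passes over the training set.
#' @param lr Adam learning rate.
#' @param lambda1,lambda2,eps Loss parameters (see [combinedLoss()]).
#' @param warmupEpochs Initial epochs optimised with a cross-entropy
#'   surrogate before switching to the L1 + Dice objective (the dual loss
#'   is poorly conditioned from a random initialization; see the methods
#'   vignette). Defaults to a third of `epochs`.
#' @param seed Optional RNG seed for augmentation and shuffling.
#' @param verbose Print per-epoch losses.
#' @return The trained [DSLModel-class] with `@history` filled (always the
#'   combined-loss value, including during warm-up).
#' @export
pretrainDSL <- function(model, volumes, degradationConfig,
                        epochs = 20L, lr = 1e-4, lambda1 = 0.5,
                        lambda2 = 0.5, eps = 1e-5,
                        warmupEpochs = max(1L, round(epochs / 3)),
                        seed = NULL, verbose = FALSE) {
  if (length(volumes) < 1) stop("need at least one training case")
  if (!is.null(seed)) set.seed(seed)
  nC <- model@config$inChannels
  state <- dslTrainState(model)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(volumes))
    losses <- numeric(length(ord))
    for (j in seq_along(ord)) {
      clean <- volumes[[ord[j]]]
      deg <- degradeToDepth(clean, degradationConfig)$vol
      pair <- asTrainingPair(deg, clean, nC)
      state <- dslStep(state, pair$x, pair$y, lr, lambda1, lambda2, eps,
                       warmup = ep <= warmupEpochs)
      if (!is.finite(state$loss))
        stop("NaN/Inf loss at epoch ", ep, ", case ", ord[j])
      losses[j] <- state$loss
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  model@encoderParams <- state$encParams
  model@decoderParams <- state$decParams
  model@trained <- TRUE
  model@history <- c(model@history, history)
  model
}

#' Finetune the encoder on target-domain pairs with the decoder frozen
#'
#' The cross-modality transfer phase: only the encoder adapts to the new
#' domain's spatial characteristics, while the decoder — the keeper of the
#' structural smoothness learned during pretraining — is frozen
#' (bit-identical before and after). Inputs are used as-is; no synthetic
#' degradation is applied.
#'
#' @param model A pretrained [DSLModel-class] (a warning is issued
#'   otherwise).
#' @param inputs List of observed [LabelVolume-class] inputs.
#' @param targets List of corrected [LabelVolume-class] targets, parallel to
#'   `inputs`.
#' @inheritParams pretrainDSL
#' @return The finetuned [DSLModel-class].
#' @export
finetuneDSL <- function(model, inputs, targets, epochs = 10L, lr = 1e-4,
                        lambda1 = 0.5, lambda2 = 0.5, eps = 1e-5,
                        seed = NULL, verbose = FALSE) {
  if (!model@trained) warning("finetuning an unpretrained model")
  if (length(inputs) < 1) stop("empty finetuning set")
  stopifnot(length(inputs) == length(targets))
  if (!is.null(seed)) set.seed(seed)
  nC <- model@config$inChannels
  state <- dslTrainState(model)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(inputs))
    losses <- numeric(length(ord))
    for (j in seq_along(ord)) {
      pair <- asTrainingPair(inputs[[ord[j]]], targets[[ord[j]]], nC)
      state <- dslStep(state, pair$x, pair$y, lr, lambda1, lambda2, eps,
                       freezeDecoder = TRUE)
      losses[j] <- state$loss
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("finetune epoch %d: loss %.4f", ep,
                                 history[ep]))
  }
  model@encoderParams <- state$encParams
  model@history <- c(model@history, history)
  model
}

#' Motion-correct a label volume
#'
#' Projects a (possibly motion-corrupted) label volume through the learned
#' shape manifold: one-hot encode, encode, decode, argmax. In-plane
#' dimensions that do not divide 4 are symmetrically zero-padded and the
#' output is cropped back; spacing metadata is preserved.
#'
#' @param model A trained [DSLModel-class].
#' @param vol A [LabelVolume-class].
#' @return The corrected [LabelVolume-class], same shape as the input.
#' @export
dslCorrect <- function(model, vol) {
  if (!model@trained) stop("model is untrained; run pretrainDSL first")
  v <- vol@voxels
  d <- dim(v)
  padH <- (4 - d[2] %% 4) %% 4
  padW <- (4 - d[3] %% 4) %% 4
  if (padH || padW) {
    padded <- array(0L, c(d[1], d[2] + padH, d[3] + padW))
    h0 <- padH %/% 2; w0 <- padW %/% 2
    padded[, h0 + seq_len(d[2]), w0 + seq_len(d[3])] <- v
    v <- padded
  }
  x <- toOneHot(LabelVolume(v, vol@spacing, vol@classNames),
                model@config$inChannels)
  z <- dslEncode(model, x)
  p <- dslDecode(model, z, spacing = vol@spacing)
  out <- argmaxLabels(p, vol@classNames)@voxels
  if (padH || padW) {
    h0 <- padH %/% 2; w0 <- padW %/% 2
    out <- out[, h0 + seq_len(d[2]), w0 + seq_len(d[3]), drop = FALSE]
  }
  LabelVolume(out, spacing = vol@spacing, classNames = vol@classNames)
}

#' Serialize / restore a model
#'
#' Models are written as an RDS payload plus a JSON manifest describing the
#' configuration and training state.
#'
#' @param model A [DSLModel-class] or [ASVModel-class].
#' @param path Output `.rds` path; the manifest is written alongside with
#'   extension `.json`.
#' @return Invisibly, `path`.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  manifest <- list(class = class(model)[1], trained = model@trained,
                   epochs = length(model@history),
                   config = model@config)
  jsonlite::write_json(manifest, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
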