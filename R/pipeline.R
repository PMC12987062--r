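# End-to-end experimental skeletons: the demo pipeline (generate -> degrade
# -> pretrain -> finetune -> correct -> super-resolve -> evaluate), the
# paired ablation of super-resolution with/without motion correction, and
# the severity/spacing study of the curvature metric.

#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end studies with desk-scale defaults.
#' A fixed `seed` makes every derived RNG stream reproducible.
#'
#' @param phantom A [phantomParams()] list.
#' @param severity Degradation severity for the test arm.
#' @param nTrain,nHeldout Training / held-out phantom counts.
#' @param nFinetune Target-domain finetuning pairs.
#' @param dslEpochs,asvEpochs,finetuneEpochs Training lengths.
#' @param lr Adam learning rate for all stages.
#' @param srScale Evaluation super-resolution scale.
#' @param asvScales Scale set the super-resolver is trained on; every
#'   phantom depth must divide by each.
#' @param seed Master seed.
#' @param workDir Optional directory for artifacts (CSV summaries,
#'   manifests); nothing is written when `NULL`.
#' @return Named list (class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(phantom = phantomParams(grid = c(36, 64, 64),
                                                   spacing = c(2, 1, 1)),
                           severity = "medium", nTrain = 10L,
                           nHeldout = 4L, nFinetune = 4L, dslEpochs = 30L,
                           asvEpochs = 30L, finetuneEpochs = 4L, lr = 1e-3,
                           srScale = 2L, asvScales = c(2L, 3L, 4L),
                           seed = 1L, workDir = NULL) {
  structure(list(phantom = phantom, severity = severity,
                 nTrain = as.integer(nTrain),
                 nHeldout = as.integer(nHeldout),
                 nFinetune = as.integer(nFinetune),
                 dslEpochs = as.integer(dslEpochs),
                 asvEpochs = as.integer(asvEpochs),
                 finetuneEpochs = as.integer(finetuneEpochs), lr = lr,
                 srScale = as.integer(srScale),
                 asvScales = as.integer(asvScales), seed = as.integer(seed),
                 workDir = workDir),
            class = "pipelineConfig")
}

generateCohort <- function(n, params, seeds) {
  lapply(seq_len(n), function(i) generatePhantom(params, seed = seeds[i]))
}

#' Run the end-to-end demonstration pipeline
#'
#' Generates phantom cohorts, pretrains the motion-correction autoencoder
#' on freshly degraded pairs, finetunes it decoder-frozen on a small
#' target-domain set, corrects held-out degraded cases, trains the
#' super-resolver multi-scale on the clean cohort, super-resolves the
#' corrected cases, and evaluates every arm. Returns the trained models,
#' the per-case reports and a summary table; writes CSV/JSON artifacts when
#' `cfg$workDir` is set.
#'
#' @param cfg A [pipelineConfig()] list.
#' @param verbose Print stage progress.
#' @return List with `summary` (data.frame), `reports`, `dsl`, `asv`,
#'   `heldout` (the evaluation volumes).
#' @export
runDemo <- function(cfg = pipelineConfig(), verbose = FALSE) {
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      cfg$nTrain + cfg$nHeldout + cfg$nFinetune + 4L)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d + %d + %d phantoms",
      cfg$nTrain, cfg$nHeldout, cfg$nFinetune)
  train <- generateCohort(cfg$nTrain, cfg$phantom, seeds)
  heldout <- generateCohort(cfg$nHeldout, cfg$phantom,
                            seeds[cfg$nTrain + seq_len(cfg$nHeldout)])
  ftClean <- generateCohort(
    cfg$nFinetune, cfg$phantom,
    seeds[cfg$nTrain + cfg$nHeldout + seq_len(cfg$nFinetune)])
  sev <- severityPreset(cfg$severity)

  say("pretraining DSL (%d epochs)", cfg$dslEpochs)
  dsl <- buildDSLModel(8L, seed = seeds[cfg$nTrain + cfg$nHeldout +
                                          cfg$nFinetune + 1L])
  dsl <- pretrainDSL(dsl, train, sev, epochs = cfg$dslEpochs, lr = cfg$lr,
                     seed = seeds[cfg$nTrain + cfg$nHeldout +
                                    cfg$nFinetune + 2L], verbose = verbose)

  say("finetuning DSL decoder-frozen (%d epochs)", cfg$finetuneEpochs)
  easy <- severityPreset("easy")
  ftInputs <- lapply(seq_along(ftClean), function(i)
    degradeToDepth(ftClean[[i]], easy,
                   seed = seeds[cfg$nTrain + cfg$nHeldout +
                                  cfg$nFinetune + 3L] + i)$vol)
  dsl <- finetuneDSL(dsl, ftInputs, ftClean, epochs = cfg$finetuneEpochs,
                     lr = cfg$lr, seed = cfg$seed + 1L, verbose = verbose)

  say("training ASV (%d epochs)", cfg$asvEpochs)
  asv <- buildASVModel(8L, scales = cfg$asvScales, seed = cfg$seed + 2L)
  asv <- trainASV(asv, train, epochs = cfg$asvEpochs, lr = cfg$lr,
                  seed = cfg$seed + 3L, verbose = verbose)

  say("evaluating %d held-out cases", cfg$nHeldout)
  reports <- list()
  rows <- list()
  for (i in seq_along(heldout)) {
    clean <- heldout[[i]]
    dg <- degradeToDepth(clean, sev, seed = cfg$seed + 10L + i)
    degraded <- dg$vol
    corrected <- dslCorrect(dsl, degraded)
    lrv <- downsampleZ(corrected, sev@zFactor, sev@zPhase)
    sr <- superresolve(asv, lrv, cfg$srScale)
    srEval <- if (dim(sr@voxels)[1] == dim(clean@voxels)[1]) sr else
      LabelVolume(zRepeat(sr, 1L,
                          targetDepth = dim(clean@voxels)[1])@voxels,
                  clean@spacing, clean@classNames)
    repDeg <- evaluateCase(degraded, clean, caseId = sprintf("case%02d", i),
                           severity = cfg$severity)
    repCor <- evaluateCase(corrected, clean, pre = degraded,
                           caseId = sprintf("case%02d", i),
                           severity = cfg$severity)
    repSR <- evaluateCase(srEval, clean, pre = degraded,
                          caseId = sprintf("case%02d", i),
                          severity = cfg$severity)
    reports[[i]] <- list(degraded = repDeg, corrected = repCor, sr = repSR)
    pick <- function(r, col) r@table[r@table$class == "mean", col]
    rows[[i]] <- data.frame(
      case = sprintf("case%02d", i),
      diceDegraded = pick(repDeg, "dice"),
      diceCorrected = pick(repCor, "dice"),
      diceSR = pick(repSR, "dice"),
      hd95Corrected = pick(repCor, "hd95"),
      assdCorrected = pick(repCor, "assd"),
      kappaPre = pick(repCor, "kappaPre"),
      kappaPost = pick(repCor, "kappaPost"),
      rKappa = pick(repCor, "rKappa"))
  }
  summary <- do.call(rbind, rows)
  if (!is.null(cfg$workDir)) {
    dir.create(cfg$workDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(cfg$workDir, "demo_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, severity = cfg$severity,
           grid = cfg$phantom$grid, spacing = cfg$phantom$spacing,
           meanDiceDegraded = mean(summary$diceDegraded),
           meanDiceCorrected = mean(summary$diceCorrected),
           meanDiceSR = mean(summary$diceSR)),
      file.path(cfg$workDir, "demo_summary.json"), auto_unbox = TRUE,
      pretty = TRUE)
  }
  list(summary = summary, reports = reports, dsl = dsl, asv = asv,
       heldout = heldout)
}

#' Paired ablation: super-resolution with vs without motion correction
#'
#' On identical degraded test phantoms (paired design: the same degradation
#' draws in both arms), compares direct super-resolution of the misaligned
#' low-resolution stack against motion correction followed by
#' super-resolution, both evaluated against the clean high-resolution
#' reference.
#'
#' @param dsl A trained [DSLModel-class].
#' @param asv A trained [ASVModel-class].
#' @param cleanVolumes List of clean [LabelVolume-class] test cases.
#' @param severity Severity preset name for the degradations.
#' @param sZ Super-resolution scale.
#' @param seed Seed for the paired degradation draws.
#' @return data.frame with one row per arm (`srOnly`, `mcSr`): mean Dice,
#'   HD95, ASSD across cases.
#' @export
runMCSRAblation <- function(dsl, asv, cleanVolumes, severity = "medium",
                            sZ = 2L, seed = 1L) {
  if (!dsl@trained || !asv@trained) stop("need trained DSL and ASV models")
  sev <- severityPreset(severity)
  arms <- list(srOnly = list(), mcSr = list())
  for (i in seq_along(cleanVolumes)) {
    clean <- cleanVolumes[[i]]
    D <- dim(clean@voxels)[1]
    dg <- degradeToDepth(clean, sev, seed = seed + i)  # paired input
    degraded <- dg$vol
    lrDeg <- downsampleZ(degraded, sev@zFactor, sev@zPhase)
    srOnly <- superresolve(asv, lrDeg, sZ)
    corrected <- dslCorrect(dsl, degraded)
    lrCor <- downsampleZ(corrected, sev@zFactor, sev@zPhase)
    mcSr <- superresolve(asv, lrCor, sZ)
    for (arm in c("srOnly", "mcSr")) {
      vol <- if (arm == "srOnly") srOnly else mcSr
      if (dim(vol@voxels)[1] != D)
        vol <- LabelVolume(zRepeat(vol, 1L, targetDepth = D)@voxels,
                           clean@spacing, clean@classNames)
      vol@spacing <- clean@spacing
      arms[[arm]][[i]] <- evaluateCase(vol, clean,
                                       caseId = sprintf("case%02d", i),
                                       severity = severity)
    }
  }
  pick <- function(r, col) r@table[r@table$class == "mean", col]
  do.call(rbind, lapply(names(arms), function(arm) {
    reps <- arms[[arm]]
    data.frame(arm = arm,
               dice = mean(vapply(reps, pick, numeric(1), "dice")),
               hd95 = mean(vapply(reps, pick, numeric(1), "hd95")),
               assd = mean(vapply(reps, pick, numeric(1), "assd")),
               n = length(reps))
  }))
}

#' Severity and spacing study of the curvature metric
#'
#' For each severity level, repeatedly degrades clean phantoms, corrects
#' them with the trained model, and reports per-class mean curvature
#' intensity before/after correction and the relative variation rate.
#' Additionally renders the same phantom geometries at several spacings and
#' reports the per-class relative spread of curvature intensity across
#' resolutions.
#'
#' @param dsl A trained [DSLModel-class].
#' @param params A [phantomParams()] list for the clean phantoms.
#' @param nSeeds Degradation draws per severity level.
#' @param spacings List of `(sz, sy, sx)` spacing configurations (with
#'   grids scaled to keep the physical field of view, supplied as a
#'   parallel `grids` list).
#' @param grids List of `(D, H, W)` grids parallel to `spacings`.
#' @param seed Master seed.
#' @return List with `severityTable` (severity x class means of kappaPre,
#'   kappaPost, rKappa) and `spacingTable` (per class: kappa at each
#'   spacing and the relative spread).
#' @export
runSeverityStudy <- function(dsl, params, nSeeds = 20L,
                             spacings = list(c(2, 1, 1), c(2, 2, 2),
                                             c(1, 1, 1)),
                             grids = NULL, seed = 1L) {
  if (!dsl@trained) stop("need a trained DSL model")
  set.seed(seed)
  baseSeeds <- sample.int(.Machine$integer.max - 1L, nSeeds)
  classNames <- whsClassNames()[-1]
  sevRows <- list()
  for (level in c("easy", "medium", "hard")) {
    sev <- severityPreset(level)
    kPre <- kPost <- matrix(NA_real_, nSeeds, 7)
    for (s in seq_len(nSeeds)) {
      clean <- generatePhantom(params, seed = baseSeeds[s])
      degraded <- degradeToDepth(clean, sev, seed = baseSeeds[s] + 1L)$vol
      corrected <- dslCorrect(dsl, degraded)
      for (cls in 1:7) {
        dm <- degraded@voxels == cls
        cm <- corrected@voxels == cls
        if (sum(dm) > 0) kPre[s, cls] <-
            meanCurvatureIntensity(dm, degraded@spacing)
        if (sum(cm) > 0) kPost[s, cls] <-
            meanCurvatureIntensity(cm, corrected@spacing)
      }
    }
    rk <- abs(kPost - kPre) / kPre
    sevRows[[level]] <- data.frame(
      severity = level, class = classNames,
      kappaPre = colMeans(kPre, na.rm = TRUE),
      kappaPost = colMeans(kPost, na.rm = TRUE),
      rKappa = colMeans(rk, na.rm = TRUE))
  }
  severityTable <- do.call(rbind, sevRows)
  rownames(severityTable) <- NULL

  # spacing robustness on clean phantoms: same geometry, several grids
  if (is.null(grids)) {
    fov <- params$grid * params$spacing
    grids <- lapply(spacings, function(sp) as.integer(round(fov / sp)))
  }
  nPh <- min(5L, nSeeds)
  kap <- array(NA_real_, c(nPh, length(spacings), 7))
  for (p in seq_len(nPh)) {
    set.seed(baseSeeds[p])
    geom <- samplePhantomGeometry(params)
    for (g in seq_along(spacings)) {
      vol <- rasterizePhantom(geom, grids[[g]], spacings[[g]])
      for (cls in 1:7) {
        m <- vol@voxels == cls
        if (sum(m) > 0) kap[p, g, cls] <-
            meanCurvatureIntensity(m, spacings[[g]])
      }
    }
  }
  kmean <- apply(kap, c(2, 3), mean, na.rm = TRUE)  # spacing x class
  spread <- apply(kmean, 2, function(x)
    (max(x, na.rm = TRUE) - min(x, na.rm = TRUE)) / mean(x, na.rm = TRUE))
  spacingTable <- data.frame(
    class = classNames,
    t(kmean),
    relSpread = spread)
  names(spacingTable)[2:(1 + length(spacings))] <-
    vapply(spacings, function(sp) paste0("kappa_",
                                         paste(sp, collapse = "x")), "")
  rownames(spacingTable) <- NULL
  list(severityTable = severityTable, spacingTable = spacingTable)
}
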