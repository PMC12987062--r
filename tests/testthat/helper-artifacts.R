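# Lazily trained shared artifacts for the training-dependent studies: one
# phantom cohort, one pretrained motion-correction model and one trained
# super-resolver, reused across test files to keep the suite within a
# single-CPU budget. Sizes and severities are the package's documented
# desk-scale study conditions.

.artifactCache <- new.env(parent = emptyenv())

studyPhantomParams <- function() {
  phantomParams(grid = c(36, 64, 64), spacing = c(2, 1, 1))
}

studyArtifacts <- function() {
  if (!is.null(.artifactCache$art)) return(.artifactCache$art)
  p <- studyPhantomParams()
  set.seed(20260921)
  seeds <- sample.int(.Machine$integer.max - 1L, 40)
  train <- lapply(seeds[1:30], function(s) generatePhantom(p, seed = s))
  heldout <- lapply(seeds[31:40], function(s) generatePhantom(p, seed = s))
  sev <- severityPreset("medium")
  dsl <- buildDSLModel(8, seed = 1)
  dsl <- pretrainDSL(dsl, train, sev, epochs = 18L, lr = 1e-3,
                     warmupEpochs = 4L, seed = 99)
  asv <- buildASVModel(8, seed = 2)
  asv <- trainASV(asv, train[1:10], epochs = 38L, lr = 1e-3,
                  warmupEpochs = 10L, seed = 7)
  .artifactCache$art <- list(params = p, train = train, heldout = heldout,
                             severity = sev, dsl = dsl, asv = asv)
  .artifactCache$art
}
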