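# Numerical correctness of the training engine: analytic gradients of every
# layer type against central differences, and the loss against an
# independent scalar implementation.

numericGrad <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

test_that("conv / pool / upsample gradients match central differences", {
  set.seed(101)
  layers <- list(
    whrecon:::convLayer(3, 4, c(3, 3, 3)),
    whrecon:::poolLayer(2),
    whrecon:::convLayer(4, 2, c(1, 3, 3)),
    whrecon:::upLayer(2),
    whrecon:::convLayer(2, 3, c(3, 1, 1), act = "linear")
  )
  params <- whrecon:::nnInit(layers)
  x <- array(rnorm(3 * 4 * 8 * 8), c(3, 4, 8, 8))
  target <- array(rnorm(3 * 4 * 8 * 8), c(3, 4, 8, 8))
  lossOf <- function(p) {
    out <- whrecon:::nnForward(layers, p, x, keep = FALSE)$out
    sum((out - target)^2)
  }
  fw <- whrecon:::nnForward(layers, params, x)
  gy <- 2 * (fw$out - target)
  bk <- whrecon:::nnBackward(layers, params, fw$caches, gy)
  for (li in c(1, 3, 5)) {
    for (probe in 1:4) {
      i <- sample(length(params[[li]]$W), 1)
      fWi <- function(v) {
        p <- params; p[[li]]$W[i] <- v
        lossOf(p)
      }
      num <- (fWi(params[[li]]$W[i] + 1e-6) -
                fWi(params[[li]]$W[i] - 1e-6)) / 2e-6
      expect_equal(bk$grads[[li]]$W[i], num, tolerance = 1e-4)
    }
    j <- sample(length(params[[li]]$b), 1)
    fb <- function(v) { p <- params; p[[li]]$b[j] <- v; lossOf(p) }
    num <- (fb(params[[li]]$b[j] + 1e-6) -
              fb(params[[li]]$b[j] - 1e-6)) / 2e-6
    expect_equal(bk$grads[[li]]$b[j], num, tolerance = 1e-4)
  }
  # input gradient
  fx <- function(xx) {
    sum((whrecon:::nnForward(layers, params, xx, keep = FALSE)$out -
           target)^2)
  }
  for (probe in 1:4) {
    i <- sample(length(x), 1)
    expect_equal(bk$gx[i], numericGrad(fx, x, i), tolerance = 1e-4)
  }
})

test_that("MLP gradients match central differences", {
  set.seed(102)
  params <- whrecon:::mlpInit(c(5, 7, 3))
  x <- matrix(rnorm(20 * 5), 20, 5)
  target <- matrix(rnorm(20 * 3), 20, 3)
  lossOf <- function(p) {
    sum((whrecon:::mlpForward(p, x, keep = FALSE)$out - target)^2)
  }
  fw <- whrecon:::mlpForward(params, x)
  bk <- whrecon:::mlpBackward(params, fw$caches, 2 * (fw$out - target))
  for (li in 1:2) {
    for (probe in 1:4) {
      i <- sample(length(params[[li]]$W), 1)
      fWi <- function(v) { p <- params; p[[li]]$W[i] <- v; lossOf(p) }
      num <- (fWi(params[[li]]$W[i] + 1e-6) -
                fWi(params[[li]]$W[i] - 1e-6)) / 2e-6
      expect_equal(bk$grads[[li]]$W[i], num, tolerance = 1e-4)
    }
  }
})

test_that("softmax + combined loss gradient matches central differences", {
  set.seed(103)
  logits <- array(rnorm(4 * 2 * 3 * 3), c(4, 2, 3, 3))
  y <- whrecon:::channelSoftmax(array(rnorm(length(logits)), dim(logits)))
  y <- round(y)  # roughly one-hot-ish; re-normalize
  y <- array(apply(matrix(y, 4), 2, function(col) {
    if (sum(col) == 0) col[1] <- 1
    col / sum(col)
  }), dim(logits))
  lossOf <- function(lg) {
    P <- whrecon:::channelSoftmax(lg)
    whrecon:::combinedLossGrad(P, y)$total
  }
  P <- whrecon:::channelSoftmax(logits)
  lg <- whrecon:::combinedLossGrad(P, y)
  gLogits <- whrecon:::softmaxBackward(P, lg$grad)
  for (probe in 1:6) {
    i <- sample(length(logits), 1)
    expect_equal(gLogits[i], numericGrad(lossOf, logits, i),
                 tolerance = 1e-5)
  }
})

test_that("combined loss matches an independent scalar implementation", {
  # plain for-loop evaluation of the dual objective, no shared code
  scalarLoss <- function(P, Y, l1w, l2w, eps) {
    C <- dim(P)[1]; nvox <- prod(dim(P)[-1])
    l1 <- 0
    for (i in seq_len(length(P))) l1 <- l1 + abs(P[i] - Y[i])
    l1 <- l1 / nvox
    num <- 0; den <- eps
    for (i in seq_len(length(P))) {
      num <- num + P[i] * Y[i]
      den <- den + P[i]^2 + Y[i]^2
    }
    l1w * l1 + l2w * (1 - 2 * num / den)
  }
  set.seed(104)
  for (rep in 1:5) {
    P <- whrecon:::channelSoftmax(array(rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2)))
    Y <- toOneHot(randomLabelVolume(c(2, 2, 2), nClasses = 3), 3)@values
    got <- combinedLoss(P, Y, 0.5, 0.5, 1e-5)$total
    expect_equal(got, scalarLoss(P, Y, 0.5, 0.5, 1e-5), tolerance = 1e-6)
  }
  # identity gives exactly zero L1 and ~zero Dice loss
  Y <- toOneHot(randomLabelVolume(c(3, 3, 3)), 8)@values
  l <- combinedLoss(Y, Y)
  expect_identical(l$l1, 0)
  expect_lt(l$dice, 1e-4)
  # fully disjoint one-hot pair pushes the Dice loss to ~1
  a <- array(0, c(2, 1, 1, 2)); a[1, , , ] <- 1
  b <- array(0, c(2, 1, 1, 2)); b[2, , , ] <- 1
  expect_gt(combinedLoss(a, b)$dice, 1 - 1e-4)
})
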