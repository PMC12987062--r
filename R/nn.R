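# A compact CPU training engine for small channel-first (C, D, H, W) conv
# networks: sequential conv / in-plane maxpool / in-plane nearest-upsample
# layers with ReLU, dense (pointwise MLP) stacks, Adam, softmax over the
# channel axis, and the combined L1 + soft-Dice objective with analytic
# gradients. Convolutions run as im2col + BLAS GEMM in compiled code.

# ---- layer specs -----------------------------------------------------------
convLayer <- function(cin, cout, k, act = "relu") {
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k), act = act)
}
poolLayer <- function(f = 2L) list(type = "pool", f = as.integer(f))
upLayer <- function(f = 2L) list(type = "up", f = as.integer(f))

# He-initialised parameters for a layer stack; draws from the ambient RNG.
nnInit <- function(layers) {
  lapply(layers, function(l) {
    if (l$type != "conv") return(list())
    K <- l$cin * prod(l$k)
    list(W = matrix(rnorm(l$cout * K, sd = sqrt(2 / K)), l$cout, K),
         b = numeric(l$cout))
  })
}

nnForward <- function(layers, params, x, keep = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      y <- .conv3d_forward(x, dim(x), params[[i]]$W, params[[i]]$b, l$k)
      if (l$act == "relu") {
        # leaky rectifier (slope 0.01): a hard cut-off lets whole channels
        # die on sparse one-hot inputs, collapsing the net to a constant
        neg <- y < 0
        y[neg] <- 0.01 * y[neg]
        if (keep) caches[[i]] <- list(x = x, neg = neg)
      } else if (keep) caches[[i]] <- list(x = x)
      x <- y
    } else if (l$type == "pool") {
      r <- .maxpool_hw(x, dim(x), l$f)
      if (keep) caches[[i]] <- list(idx = r$idx, xdim = dim(x))
      x <- r$y
    } else {
      x <- .upsample_hw(x, dim(x), l$f)
    }
  }
  list(out = x, caches = caches)
}

nnBackward <- function(layers, params, caches, gy, skipInputGrad = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      cache <- caches[[i]]
      if (l$act == "relu") gy[cache$neg] <- 0.01 * gy[cache$neg]
      r <- .conv3d_backward(cache$x, dim(cache$x), params[[i]]$W, gy, l$k,
                            needGx = !(skipInputGrad && i == 1L))
      grads[[i]] <- list(W = r$gW, b = as.numeric(r$gb))
      gy <- r$gx
    } else if (l$type == "pool") {
      gy <- .maxpool_hw_backward(gy, caches[[i]]$idx, caches[[i]]$xdim)
      grads[[i]] <- list()
    } else {
      gy <- .upsample_hw_backward(gy, dim(gy), l$f)
      grads[[i]] <- list()
    }
  }
  list(grads = grads, gx = gy)
}

# ---- dense (pointwise MLP) stack ------------------------------------------
mlpInit <- function(widths) {
  # widths: c(in, hidden..., out); ReLU between, linear output
  n <- length(widths) - 1L
  lapply(seq_len(n), function(i) {
    list(W = matrix(rnorm(widths[i] * widths[i + 1],
                          sd = sqrt(2 / widths[i])),
                    widths[i], widths[i + 1]),
         b = numeric(widths[i + 1]))
  })
}

mlpForward <- function(params, x, keep = TRUE) {
  # x: N x in matrix
  n <- length(params)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    y <- x %*% params[[i]]$W
    y <- y + rep(params[[i]]$b, each = nrow(y))
    if (i < n) {
      neg <- y < 0
      y[neg] <- 0.01 * y[neg]
      if (keep) caches[[i]] <- list(x = x, neg = neg)
    } else if (keep) caches[[i]] <- list(x = x)
    x <- y
  }
  list(out = x, caches = caches)
}

mlpBackward <- function(params, caches, gy) {
  n <- length(params)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    if (i < n) gy[caches[[i]]$neg] <- 0.01 * gy[caches[[i]]$neg]
    grads[[i]] <- list(W = crossprod(caches[[i]]$x, gy),
                       b = colSums(gy))
    gy <- tcrossprod(gy, params[[i]]$W)
  }
  list(grads = grads, gx = gy)
}

# ---- Adam ------------------------------------------------------------------
adamInit <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

adamStep <- function(params, grads, m, v, t, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      if (is.null(names(p))) {
        for (i in seq_along(p)) {
          r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
          out$p[[i]] <- r$p; out$m[[i]] <- r$m; out$v[[i]] <- r$v
        }
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk(params, grads, m, v)
}

# ---- softmax over the channel axis ----------------------------------------
channelSoftmax <- function(logits) {
  C <- dim(logits)[1]
  m <- matrix(logits, nrow = C)
  cmax <- m[1, ]
  for (r in seq_len(C)[-1]) cmax <- pmax(cmax, m[r, ])
  e <- exp(m - rep(cmax, each = C))
  p <- e / rep(colSums(e), each = C)
  array(p, dim(logits))
}

# grad of loss wrt logits given P = softmax(logits) and gP = dL/dP
softmaxBackward <- function(P, gP) {
  C <- dim(P)[1]
  pm <- matrix(P, nrow = C)
  gm <- matrix(gP, nrow = C)
  dot <- colSums(pm * gm)
  array(pm * (gm - rep(dot, each = C)), dim(P))
}

#' Combined L1 + soft-Dice reconstruction loss
#'
#' The dual objective used for both reconstruction stages:
#' `lambda1 * L_L1 + lambda2 * L_Dice`, where `L_L1` is the mean over voxels
#' of the channel-wise L1 distance and `L_Dice` is the multi-class soft Dice
#' loss with a squared denominator,
#' `1 - 2 * sum(P * Y) / (sum(P^2) + sum(Y^2) + eps)`, sums running over
#' classes and voxels.
#'
#' @param pred A [ProbabilityVolume-class] or a channel-first 4D array of
#'   predicted class probabilities.
#' @param target A one-hot [ProbabilityVolume-class] or array of the same
#'   shape.
#' @param lambda1,lambda2 Positive weights of the L1 and Dice terms
#'   (defaults 0.5 and 0.5).
#' @param eps Stability constant of the Dice denominator.
#' @return Named list `total`, `l1`, `dice`.
#' @export
#' @examples
#' p <- array(c(0.6, 0.4), c(2, 1, 1, 1))
#' y <- array(c(1, 0), c(2, 1, 1, 1))
#' combinedLoss(p, y)  # total ~ 0.5053
combinedLoss <- function(pred, target, lambda1 = 0.5, lambda2 = 0.5,
                         eps = 1e-5) {
  if (is(pred, "ProbabilityVolume")) pred <- pred@values
  if (is(target, "ProbabilityVolume")) target <- target@values
  stopifnot(identical(dim(pred), dim(target)))
  if (lambda1 <= 0 || lambda2 <= 0) stop("lambda weights must be positive")
  nvox <- prod(dim(pred)[-1])
  l1 <- sum(abs(pred - target)) / nvox
  num <- 2 * sum(pred * target)
  den <- sum(pred^2) + sum(target^2) + eps
  dice <- 1 - num / den
  list(total = lambda1 * l1 + lambda2 * dice, l1 = l1, dice = dice)
}

# Loss and gradient wrt P (both 4D arrays).
combinedLossGrad <- function(pred, target, lambda1 = 0.5, lambda2 = 0.5,
                             eps = 1e-5) {
  nvox <- prod(dim(pred)[-1])
  diff <- pred - target
  l1 <- sum(abs(diff)) / nvox
  A <- sum(pred * target)
  B <- sum(pred^2) + sum(target^2) + eps
  dice <- 1 - 2 * A / B
  g <- lambda1 * sign(diff) / nvox +
    lambda2 * (-2 * target * B + 4 * A * pred) / B^2
  list(total = lambda1 * l1 + lambda2 * dice, l1 = l1, dice = dice,
       grad = g)
}
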