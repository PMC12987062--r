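# Shared fixtures and independent brute-force oracles used across tests.

randomLabelVolume <- function(dims = c(6, 8, 8), nClasses = 8,
                              spacing = c(2, 1, 1)) {
  LabelVolume(array(sample(0:(nClasses - 1), prod(dims), replace = TRUE),
                    dims),
              spacing = spacing)
}

tinyPhantomParams <- function() {
  phantomParams(grid = c(24, 48, 48), spacing = c(2, 1.25, 1.25))
}

# Brute-force trilinear oracle: 8-corner weighted sum with the same
# centre-aligned convention (index t = (coord + 1) / 2 * (n - 1)).
oracleTrilinear <- function(field, coords) {
  dims <- dim(field)
  C <- dims[1]
  out <- matrix(0, nrow(coords), C)
  toIdx <- function(t, n) {
    if (n == 1) return(0)
    min(max((t + 1) / 2 * (n - 1), 0), n - 1)
  }
  for (i in seq_len(nrow(coords))) {
    tz <- toIdx(coords[i, 3], dims[2])
    ty <- toIdx(coords[i, 2], dims[3])
    tx <- toIdx(coords[i, 1], dims[4])
    z0 <- floor(tz); y0 <- floor(ty); x0 <- floor(tx)
    for (c in seq_len(C)) {
      acc <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        z <- min(z0 + dz, dims[2] - 1)
        y <- min(y0 + dy, dims[3] - 1)
        x <- min(x0 + dx, dims[4] - 1)
        wz <- if (dz == 0) 1 - (tz - z0) else tz - z0
        wy <- if (dy == 0) 1 - (ty - y0) else ty - y0
        wx <- if (dx == 0) 1 - (tx - x0) else tx - x0
        acc <- acc + wz * wy * wx * field[c, z + 1, y + 1, x + 1]
      }
      out[i, c] <- acc
    }
  }
  out
}

# Brute-force exposed-face count: for every foreground voxel, count its six
# neighbours that are background or outside, weighting by physical face area.
oracleSurfaceArea <- function(mask, spacing) {
  d <- dim(mask)
  areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
             spacing[1] * spacing[2])  # faces normal to z, y, x
  total <- 0
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  axisOf <- c(1, 1, 2, 2, 3, 3)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    for (o in 1:6) {
      nb <- idx[r, ] + offs[o, ]
      outside <- any(nb < 1) || any(nb > d)
      if (outside || !mask[nb[1], nb[2], nb[3]])
        total <- total + areas[axisOf[o]]
    }
  }
  total
}

# Brute-force boundary extraction + all-pairs directed surface distances.
oracleBoundary <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
      nb <- v + o
      if (any(nb < 1) || any(nb > d) || !mask[nb[1], nb[2], nb[3]]) {
        keep[r] <- TRUE; break
      }
    }
  }
  idx[keep, , drop = FALSE]
}

oracleSurfaceDistances <- function(aMask, bMask, spacing) {
  ba <- oracleBoundary(aMask); bb <- oracleBoundary(bMask)
  mm <- function(i) sweep(i - 1, 2, spacing, "*")
  pa <- mm(ba); pb <- mm(bb)
  d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  dmat <- sqrt(pmax(d2, 0))
  c(apply(dmat, 1, min), apply(dmat, 2, min))
}

# Non-degrading configuration (exact identity).
neutralConfig <- function() degradationConfig()

diceMean <- function(a, b) diceCoefficient(a, b)$mean
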