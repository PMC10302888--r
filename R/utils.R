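## Internal numeric helpers shared across modules.

# smallest 2/3/5-smooth size >= n (FFT-friendly; avoids prime-length DFTs)
fastLen <- function(n) stats::nextn(n, c(2L, 3L, 5L))

# relative L2 distance, guarded for a zero reference
relL2 <- function(a, b) {
  den <- sqrt(sum(b^2))
  if (den == 0) sqrt(sum(a^2)) else sqrt(sum((a - b)^2)) / den
}

softThreshold <- function(x, k) sign(x) * pmax(abs(x) - k, 0)

# 6-connected component labelling of a 3D logical array.
# Iterative flood fill with an integer stack; volumes here are small
# (<= ~64^3) so plain R is adequate.
labelComponents3d <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1L)
  mask <- array(mask, dim = d)
  labels <- array(0L, dim = d)
  nxt <- 0L
  idx <- which(mask)
  off <- c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  for (start in idx) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    labels[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- arrayInd(cur, d)
      for (k in seq_along(off)) {
        # guard axis wrap-around at array edges
        nb <- ci
        ax <- c(1L, 1L, 2L, 2L, 3L, 3L)[k]
        dir <- c(-1L, 1L, -1L, 1L, -1L, 1L)[k]
        nb[ax] <- nb[ax] + dir
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        lin <- cur + off[k]
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          stack <- c(stack, lin)
        }
      }
    }
  }
  labels
}

# Otsu's threshold on a numeric array (maximizes between-class variance
# over a 256-bin histogram of the data range).
otsuThreshold <- function(x, nBins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    findInterval(x, seq(rng[1], rng[2], length.out = nBins + 1L),
                 rightmost.closed = TRUE), 1L), nBins), nbins = nBins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = nBins + 1L)[-1] -
    diff(rng) / (2 * nBins)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nBins]
  sb2 <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# sub-voxel peak position along one axis by quadratic (3-point) interpolation
quadraticPeakOffset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (den >= 0) return(0)  # not a strict local max; keep grid position
  off <- 0.5 * (ym1 - yp1) / den
  max(min(off, 0.5), -0.5)
}

# Lorentzian line shape normalized to 1 at its center
lorentzianLine <- function(nu, centerCm1, hwhmCm1) {
  hwhmCm1^2 / ((nu - centerCm1)^2 + hwhmCm1^2)
}
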