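# Independent brute-force oracles, deliberately coded by direct definition
# (explicit DFT sums, double loops, per-pixel scans) rather than through the
# package's vectorized paths.

# Welch MSC by direct periodogram averaging: explicit DFT matrix per
# subsegment, plain loops for the spectral averages.
oracle_welch_msc <- function(x, y, fs, n_sub = 8, ov = 0.5, nfft = 256) {
  w <- length(x)
  L <- floor(w / (1 + (n_sub - 1) * (1 - ov)))
  step <- max(1, round(L * (1 - ov)))
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  dft <- exp(-2i * pi * outer(0:(nfft - 1), 0:(nfft - 1)) / nfft)
  Pxx <- Pyy <- numeric(nfft)
  Pxy <- complex(nfft)
  for (k in 0:(n_sub - 1)) {
    i0 <- 1 + k * step
    xs <- x[i0:(i0 + L - 1)]; ys <- y[i0:(i0 + L - 1)]
    xs <- (xs - mean(xs)) * ham; ys <- (ys - mean(ys)) * ham
    X <- dft %*% c(xs, rep(0, nfft - L))
    Y <- dft %*% c(ys, rep(0, nfft - L))
    Pxx <- Pxx + Mod(X)^2 / n_sub
    Pyy <- Pyy + Mod(Y)^2 / n_sub
    Pxy <- Pxy + Conj(X) * Y / n_sub
  }
  msc <- Mod(Pxy)^2 / (Pxx * Pyy)
  half <- 1:(nfft / 2 + 1)
  list(freqs = (half - 1) * fs / nfft, values = as.numeric(msc[half]))
}

# Biased normalized cross-correlation maximum by double loop.
oracle_max_cc <- function(x, y, max_lag) {
  N <- length(x)
  best <- -Inf; best_lag <- 0L
  for (n in -max_lag:max_lag) {
    acc <- 0
    for (m in 1:N) {
      mm <- m + n
      if (mm >= 1 && mm <= N) acc <- acc + x[m] * y[mm]
    }
    r <- acc / sqrt(sum(x^2) * sum(y^2))
    if (r > best) { best <- r; best_lag <- n }
  }
  structure(best, lag = best_lag)
}

# Non-maximum suppression by per-pixel scan.
oracle_nms <- function(M, D) {
  n <- nrow(M); m <- ncol(M)
  out <- M
  for (i in 1:n) for (j in 1:m) {
    s <- (round(D[i, j] / (pi / 4)) %% 4)
    d <- switch(as.character(s),
                "0" = c(1, 0), "1" = c(1, 1), "2" = c(0, 1), "3" = c(1, -1))
    for (sgn in c(1, -1)) {
      ii <- i + sgn * d[1]; jj <- j + sgn * d[2]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m && M[i, j] < M[ii, jj]) {
        out[i, j] <- 0
        break
      }
    }
  }
  out
}

# Hysteresis edge linking by explicit flood fill from strong pixels.
oracle_hysteresis <- function(S, high, low_ratio) {
  mx <- max(S)
  if (mx == 0) return(matrix(0L, nrow(S), ncol(S)))
  nrm <- S / mx
  strong <- which(nrm >= high, arr.ind = TRUE)
  weak <- nrm >= low_ratio * high
  marked <- matrix(FALSE, nrow(S), ncol(S))
  stack <- split(strong, row(strong))
  while (length(stack)) {
    p <- stack[[1]]; stack <- stack[-1]
    i <- p[1]; j <- p[2]
    if (i < 1 || i > nrow(S) || j < 1 || j > ncol(S)) next
    if (marked[i, j] || !weak[i, j]) next
    marked[i, j] <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di || dj) stack <- c(stack, list(c(i + di, j + dj)))
    }
  }
  out <- matrix(0L, nrow(S), ncol(S))
  out[marked] <- 1L
  out
}

# Interval Jaccard index over frequency extent.
band_jaccard <- function(a, b) {
  lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
  if (hi <= lo) return(0)
  (hi - lo) / (max(a[2], b[2]) - min(a[1], b[1]))
}
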