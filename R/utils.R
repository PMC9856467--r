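# Internal helpers shared across modules.

# Sliding-window start indices (1-based) for a signal of n samples.
# Trailing partial windows are discarded.
window_starts <- function(n, fs, window_s, overlap_s) {
  w <- round(window_s * fs)
  hop <- round((window_s - overlap_s) * fs)
  if (hop < 1L) stop("overlap_s must be smaller than window_s")
  if (n < w) stop("signal shorter than one window")
  seq.int(1L, n - w + 1L, by = hop)
}

# Window-center times in seconds for the grid above; t0 is the absolute time
# of the first sample.
window_times <- function(starts, fs, window_s, t0 = 0) {
  t0 + (starts - 1L) / fs + window_s / 2
}

# Population standard deviation (1/N normalization).
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Analytic signal via FFT: x + i * Hilbert(x).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Canonicalize a set of channel pairs into an integer matrix with columns
# i < j (1-based channel indices).
as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) as.integer(p[1:2])))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns (i, j)")
  storage.mode(pairs) <- "integer"
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  if (any(pairs[, 1L] == pairs[, 2L])) stop("a pair must name two distinct channels")
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

pair_key <- function(pairs) paste(pairs[, 1L], pairs[, 2L], sep = "-")
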