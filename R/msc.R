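#' Spectral configuration for MSC maps
#'
#' Controls the sliding-window grid and the Welch estimator used inside each
#' window. The map grid splits the signal into `window_s`-long segments
#' (default 400 ms, overlap 200 ms, so the minimum resolvable frequency of a
#' segment is `1/window_s` = 2.5 Hz). Within each segment, coherence is
#' estimated by Welch's overlapped averaged periodogram: `welch_n_sub`
#' Hamming-tapered subsegments with `welch_overlap_frac` overlap (a single
#' full-segment periodogram would make coherence identically 1), zero-padded
#' to `nfft` FFT points.
#'
#' @param window_s segment length in seconds (default 0.4).
#' @param overlap_s segment overlap in seconds (default 0.2).
#' @param welch_n_sub number of Welch subsegments per segment (default 8).
#' @param welch_overlap_frac subsegment overlap fraction (default 0.5).
#' @param nfft FFT length for the zero-padded subsegments (default 256).
#' @param f_max keep only frequencies `<= f_max` Hz (default `fs/2`).
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 0.4, overlap_s = 0.2, welch_n_sub = 8L,
                            welch_overlap_frac = 0.5, nfft = 256L,
                            f_max = NULL) {
  if (!(overlap_s >= 0 && overlap_s < window_s))
    stop("need 0 <= overlap_s < window_s")
  if (welch_n_sub < 2L) stop("welch_n_sub must be >= 2 (else coherence is identically 1)")
  if (!(welch_overlap_frac >= 0 && welch_overlap_frac < 1))
    stop("welch_overlap_frac must be in [0, 1)")
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 welch_n_sub = as.integer(welch_n_sub),
                 welch_overlap_frac = welch_overlap_frac,
                 taper = "hamming", nfft = as.integer(nfft), f_max = f_max),
            class = "spectral_config")
}

# Subsegment layout inside one window of w samples: length and start offsets.
welch_layout <- function(w, cfg) {
  span <- 1 + (cfg$welch_n_sub - 1) * (1 - cfg$welch_overlap_frac)
  L <- floor(w / span)
  if (L < 4L) stop("segment too short for ", cfg$welch_n_sub, " Welch subsegments")
  step <- max(1L, round(L * (1 - cfg$welch_overlap_frac)))
  offsets <- (seq_len(cfg$welch_n_sub) - 1L) * step
  if (max(offsets) + L > w) stop("Welch layout exceeds segment length")
  nfft <- max(cfg$nfft, next_pow2(L))
  list(L = L, offsets = offsets, nfft = nfft)
}

# Hamming-tapered, mean-detrended, zero-padded FFTs of all subsegments of all
# segments of x. Columns are grouped by segment (welch_n_sub consecutive
# columns per segment).
segment_ffts <- function(x, seg_starts, lay) {
  all_starts <- rep(seg_starts, each = length(lay$offsets)) +
    rep(lay$offsets, times = length(seg_starts))
  idx <- outer(seq_len(lay$L) - 1L, all_starts, "+")
  M <- matrix(x[idx], nrow = lay$L)
  M <- sweep(M, 2L, colMeans(M))
  k <- seq_len(lay$L) - 1L
  taper <- 0.54 - 0.46 * cos(2 * pi * k / (lay$L - 1))
  M <- M * taper
  M <- rbind(M, matrix(0, lay$nfft - lay$L, ncol(M)))
  stats::mvfft(M)
}

# Segment-grouped averaging matrix: (n_seg*n_sub) x n_seg with 1/n_sub blocks.
group_matrix <- function(n_seg, n_sub) {
  G <- matrix(0, n_seg * n_sub, n_seg)
  G[cbind(seq_len(n_seg * n_sub), rep(seq_len(n_seg), each = n_sub))] <- 1 / n_sub
  G
}

msc_from_ffts <- function(Fx, Fy, n_sub, nfft, fs, f_max) {
  n_seg <- ncol(Fx) / n_sub
  G <- group_matrix(n_seg, n_sub)
  Pxx <- (Mod(Fx)^2) %*% G
  Pyy <- (Mod(Fy)^2) %*% G
  Pxy <- (Conj(Fx) * Fy) %*% G
  vals <- Mod(Pxy)^2 / (Pxx * Pyy)
  vals[!is.finite(vals)] <- 0
  vals <- pmin(pmax(vals, 0), 1)
  freqs <- (0:(nfft / 2)) * fs / nfft
  keep <- freqs <= f_max + 1e-9
  list(freqs = freqs[keep], values = vals[seq_len(nfft / 2 + 1)[keep], , drop = FALSE])
}

#' Magnitude-squared coherence of one segment pair (Welch estimator)
#'
#' Estimates `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))` on one pair of
#' equal-length segments, with the auto- and cross-spectra averaged over
#' Hamming-tapered, mean-detrended, overlapping subsegments (Welch's method).
#' Values lie in `[0, 1]`; 1 at every bin when `y` is a scaled copy of `x`.
#'
#' @param x_seg,y_seg equal-length numeric segments (e.g. 400 samples).
#' @param fs sampling rate, Hz.
#' @param cfg a [spectral_config()].
#' @return A list with `freqs` (Hz) and `values` (coherence per bin).
#' @export
welch_msc <- function(x_seg, y_seg, fs, cfg = spectral_config()) {
  if (length(x_seg) != length(y_seg)) stop("segments must have equal length")
  if (stats::sd(x_seg) == 0 || stats::sd(y_seg) == 0)
    stop("zero-variance segment: coherence undefined")
  lay <- welch_layout(length(x_seg), cfg)
  Fx <- segment_ffts(x_seg, 1L, lay)
  Fy <- segment_ffts(y_seg, 1L, lay)
  f_max <- if (is.null(cfg$f_max)) fs / 2 else cfg$f_max
  out <- msc_from_ffts(Fx, Fy, cfg$welch_n_sub, lay$nfft, fs, f_max)
  list(freqs = out$freqs, values = as.numeric(out$values))
}

msc_map_obj <- function(values, freqs, times, pair) {
  structure(list(values = values, freqs = freqs, times = times,
                 pair = as.integer(pair)),
            class = "msc_map")
}

#' @export
print.msc_map <- function(x, ...) {
  cat(sprintf("<msc_map> pair (%d,%d): %d freq bins x %d segments, t in [%.2f, %.2f] s\n",
              x$pair[1], x$pair[2], nrow(x$values), ncol(x$values),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Build a time-frequency MSC map for one channel pair
#'
#' Slides a `window_s` window (hop `window_s - overlap_s`) along the pair of
#' signals, estimates Welch coherence in every window ([welch_msc()]), and
#' splices the spectra into a matrix with frequency on the rows and time on
#' the columns. Column time stamps are window centers; the trailing partial
#' window is discarded.
#'
#' @param x,y equal-length channel signals.
#' @param fs sampling rate, Hz.
#' @param cfg a [spectral_config()].
#' @param t0 absolute time of the first sample (seconds), for sliced inputs.
#' @param pair channel index pair recorded in the result.
#' @return An object of class `msc_map` with fields `values`, `freqs`,
#'   `times`, `pair`.
#' @export
build_msc_map <- function(x, y, fs, cfg = spectral_config(), t0 = 0,
                          pair = c(1L, 2L)) {
  if (length(x) != length(y)) stop("channels must have equal length")
  starts <- window_starts(length(x), fs, cfg$window_s, cfg$overlap_s)
  lay <- welch_layout(round(cfg$window_s * fs), cfg)
  Fx <- segment_ffts(x, starts, lay)
  Fy <- segment_ffts(y, starts, lay)
  f_max <- if (is.null(cfg$f_max)) fs / 2 else cfg$f_max
  out <- msc_from_ffts(Fx, Fy, cfg$welch_n_sub, lay$nfft, fs, f_max)
  msc_map_obj(out$values, out$freqs,
              window_times(starts, fs, cfg$window_s, t0), pair)
}

#' MSC maps for every channel pair of a recording
#'
#' Computes one `msc_map` per unordered channel pair (`i < j`), `C(n,2)` maps
#' for `n` channels. Channel FFTs are computed once and shared across pairs.
#'
#' @param rec an [recording()] with at least 2 channels.
#' @param cfg a [spectral_config()].
#' @param pairs optional pair matrix/list restricting which pairs to compute.
#' @return A named list of `msc_map` objects, keyed `"i-j"`.
#' @export
all_pairs_maps <- function(rec, cfg = spectral_config(), pairs = NULL) {
  stopifnot(inherits(rec, "lfp_recording"))
  nc <- n_channels(rec)
  if (nc < 2L) stop("need at least 2 channels")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(nc, 2L))
  }
  pairs <- as_pair_matrix(pairs)
  starts <- window_starts(n_samples(rec), rec$fs, cfg$window_s, cfg$overlap_s)
  lay <- welch_layout(round(cfg$window_s * rec$fs), cfg)
  times <- window_times(starts, rec$fs, cfg$window_s, rec$start_s)
  f_max <- if (is.null(cfg$f_max)) rec$fs / 2 else cfg$f_max
  chans <- sort(unique(as.vector(pairs)))
  F <- vector("list", nc)
  for (ch in chans) F[[ch]] <- segment_ffts(rec$data[, ch], starts, lay)
  maps <- vector("list", nrow(pairs))
  names(maps) <- pair_key(pairs)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    out <- msc_from_ffts(F[[i]], F[[j]], cfg$welch_n_sub, lay$nfft, rec$fs, f_max)
    maps[[k]] <- msc_map_obj(out$values, out$freqs, times, c(i, j))
  }
  maps
}
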