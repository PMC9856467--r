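#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass (two poles per band edge) applied forward
#' and backward (`signal::filtfilt`), so the net phase response is zero and
#' waveform timing is preserved — essential before cross-correlating
#' channels, where filter-induced lags would bias the lag search.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param band `c(f_lo, f_hi)` Hz with `0 < f_lo < f_hi < fs/2`.
#' @return The filtered signal, same length.
#' @export
bandpass_zero_phase <- function(x, fs, band) {
  band <- as.numeric(band)
  if (!(length(band) == 2 && 0 < band[1] && band[1] < band[2] && band[2] < fs / 2))
    stop("band must satisfy 0 < f_lo < f_hi < fs/2")
  bt <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bt, x))
}

#' Maximal normalized cross-correlation of two windows
#'
#' Computes the biased cross-correlation
#' `R_xy(n) = (1/N) * sum_m x(m) y(m+n)` for lags `|n| <= max_lag` (samples
#' outside the window contribute zero), normalizes by
#' `sqrt(R_xx(0) * R_yy(0))`, and returns the maximum over lags (signed
#' values; the maximizing lag is attached as attribute `"lag"`).
#' Identical windows give 1 at lag 0; the value is invariant to amplitude
#' scaling. A zero-energy window yields 0 (no synchrony evidence).
#'
#' @param x_win,y_win equal-length numeric windows.
#' @param max_lag maximal |lag| in samples, `0 <= max_lag < N`.
#' @return The maximal normalized cross-correlation, with attribute `lag`.
#' @export
max_cc <- function(x_win, y_win, max_lag = 50L) {
  N <- length(x_win)
  if (length(y_win) != N) stop("windows must have equal length")
  if (!(max_lag >= 0 && max_lag < N)) stop("need 0 <= max_lag < N")
  ex <- sum(x_win^2); ey <- sum(y_win^2)
  if (ex == 0 || ey == 0) return(structure(0, lag = 0L))
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(n) {
    if (n >= 0) sum(x_win[1:(N - n)] * y_win[(1 + n):N])
    else sum(x_win[(1 - n):N] * y_win[1:(N + n)])
  }, numeric(1))
  r <- r / sqrt(ex * ey)
  k <- which.max(r)
  structure(r[k], lag = lags[k])
}

#' Sliding-window maximal cross-correlation curves
#'
#' For each channel pair: band-pass both channels once
#' ([bandpass_zero_phase()]; `band = NULL` skips filtering), then compute
#' [max_cc()] in every sliding window on the same 400 ms / 200 ms grid as the
#' MSC maps. The per-window correlations are computed for all windows at once
#' through FFT cross-correlation.
#'
#' @param rec an [recording()].
#' @param pairs pair matrix/list of channel indices.
#' @param band `c(f_lo, f_hi)` Hz, or `NULL` for the full band.
#' @param window_s,overlap_s window grid (defaults 0.4 / 0.2 s).
#' @param max_lag_ms lag search bound, milliseconds (default 50).
#' @return An object of class `cc_features`: `times` (window centers, s),
#'   `per_pair_cc` (pairs x windows matrix), `pairs`, `band`, `fs`,
#'   `duration_s`; `avg`/`std` are filled by [avg_std()].
#' @export
cc_curves <- function(rec, pairs, band = NULL, window_s = 0.4,
                      overlap_s = 0.2, max_lag_ms = 50) {
  stopifnot(inherits(rec, "lfp_recording"))
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0L) stop("no pairs given")
  if (max(pairs) > n_channels(rec)) stop("pairs reference missing channels")
  fs <- rec$fs
  max_lag <- round(max_lag_ms * fs / 1000)
  w <- round(window_s * fs)
  if (max_lag >= w) stop("max_lag_ms must be shorter than the window")
  starts <- window_starts(n_samples(rec), fs, window_s, overlap_s)
  times <- window_times(starts, fs, window_s, rec$start_s)
  nwin <- length(starts)
  nfft <- next_pow2(w + max_lag)

  chans <- sort(unique(as.vector(pairs)))
  filt <- vector("list", n_channels(rec))
  for (ch in chans) {
    filt[[ch]] <- if (is.null(band)) rec$data[, ch]
                  else bandpass_zero_phase(rec$data[, ch], fs, band)
  }

  cc <- matrix(0, nrow(pairs), nwin)
  rownames(cc) <- pair_key(pairs)
  block <- 2048L
  lag_idx <- c(nfft - (max_lag:1) + 1L, 1:(max_lag + 1L))  # lags -L..0..L
  for (b0 in seq.int(1L, nwin, by = block)) {
    b1 <- min(nwin, b0 + block - 1L)
    bs <- starts[b0:b1]
    idx <- outer(seq_len(w) - 1L, bs, "+")
    Fch <- vector("list", n_channels(rec))
    E <- vector("list", n_channels(rec))
    for (ch in chans) {
      Wm <- matrix(filt[[ch]][idx], nrow = w)
      E[[ch]] <- colSums(Wm^2)
      Fch[[ch]] <- stats::mvfft(rbind(Wm, matrix(0, nfft - w, ncol(Wm))))
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      R <- Re(stats::mvfft(Conj(Fch[[i]]) * Fch[[j]], inverse = TRUE)) / nfft
      R <- R[lag_idx, , drop = FALSE]
      denom <- sqrt(E[[i]] * E[[j]])
      val <- apply(R, 2L, max) / denom
      val[!is.finite(val)] <- 0
      cc[k, b0:b1] <- val
    }
  }
  structure(list(times = times, per_pair_cc = cc, pairs = pairs, band = band,
                 fs = fs, duration_s = rec$duration_s, window_s = window_s,
                 overlap_s = overlap_s, avg = NULL, std = NULL,
                 selected = NULL, background = NULL),
            class = "cc_features")
}

#' @export
print.cc_features <- function(x, ...) {
  cat(sprintf("<cc_features> %d pairs x %d windows (%.1f s), band %s\n",
              nrow(x$per_pair_cc), ncol(x$per_pair_cc), x$duration_s,
              if (is.null(x$band)) "full" else paste(x$band, collapse = "-")))
  invisible(x)
}

#' AVG and STD detection features
#'
#' Fills the two detection features: `avg[t]`, the mean of the selected
#' pairs' maximal cross-correlations in window `t` (the overall correlation
#' enhancement), and `std[t]`, the population standard deviation over the
#' union of selected and background pairs (normally 20 values) — background
#' pairs do not synchronize at onset, so a genuine multi-site event spreads
#' the 20 values apart while common-mode noise does not.
#'
#' @param features a `cc_features` from [cc_curves()] whose `per_pair_cc`
#'   contains rows for every selected and background pair.
#' @param selected,background pair matrices (see [select_pairs()]).
#' @return The `cc_features` with `avg`, `std`, `selected`, `background` set.
#' @export
avg_std <- function(features, selected, background) {
  stopifnot(inherits(features, "cc_features"))
  selected <- as_pair_matrix(selected)
  background <- as_pair_matrix(background)
  if (nrow(selected) == 0L) stop("selected pair set is empty")
  keys <- rownames(features$per_pair_cc)
  sk <- pair_key(selected); bk <- pair_key(background)
  missing <- setdiff(c(sk, bk), keys)
  if (length(missing))
    stop("per_pair_cc lacks rows for pairs: ", paste(missing, collapse = ", "))
  sel_m <- features$per_pair_cc[sk, , drop = FALSE]
  all_m <- features$per_pair_cc[c(sk, bk), , drop = FALSE]
  features$avg <- colMeans(sel_m)
  features$std <- apply(all_m, 2L, pop_sd)
  features$selected <- selected
  features$background <- background
  features
}

#' Write / read feature curves as CSV
#'
#' Columns: `time_s`, `avg`, `std`, then one column per pair (`cc_i-j`).
#' @param features a `cc_features`.
#' @param path CSV path.
#' @return `path` invisibly; `read_features` returns a reduced `cc_features`.
#' @export
write_features <- function(features, path) {
  tab <- data.frame(time_s = features$times,
                    avg = if (is.null(features$avg)) NA else features$avg,
                    std = if (is.null(features$std)) NA else features$std)
  cc <- t(features$per_pair_cc)
  colnames(cc) <- paste0("cc_", rownames(features$per_pair_cc))
  utils::write.csv(cbind(tab, cc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  cc_cols <- grep("^cc_", names(tab), value = TRUE)
  per_pair <- t(as.matrix(tab[, cc_cols, drop = FALSE]))
  rownames(per_pair) <- sub("^cc_", "", cc_cols)
  pairs <- as_pair_matrix(do.call(rbind, strsplit(rownames(per_pair), "-")))
  dt <- stats::median(diff(tab$time_s))
  structure(list(times = tab$time_s, per_pair_cc = per_pair, pairs = pairs,
                 band = NULL, fs = NA_real_,
                 duration_s = max(tab$time_s) + dt / 2,
                 window_s = NA_real_, overlap_s = NA_real_,
                 avg = if (all(is.na(tab$avg))) NULL else tab$avg,
                 std = if (all(is.na(tab$std))) NULL else tab$std,
                 selected = NULL, background = NULL),
            class = "cc_features")
}
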