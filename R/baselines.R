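#' Instantaneous phase of a signal
#'
#' Phase of the analytic signal `x + i*H(x)` (Hilbert transform by FFT),
#' radians in `(-pi, pi]`. Amplitude-invariant; a constant signal has no
#' defined phase and is an error.
#'
#' @param x numeric signal, length >= 8.
#' @return Numeric vector of per-sample phases.
#' @export
instantaneous_phase <- function(x) {
  if (length(x) < 8L) stop("signal too short for a phase estimate")
  if (stats::sd(x) == 0) stop("constant signal: phase undefined")
  Arg(analytic_signal(x))
}

#' Mean phase coherence of two windows
#'
#' Modulus of the mean phasor of the instantaneous phase difference,
#' `R = |mean(exp(i*(phi_x - phi_y)))|`, in `[0, 1]`: 1 when the two signals
#' keep a fixed phase relation throughout the window, near `1/sqrt(N)` for
#' independent noise.
#'
#' @param x_win,y_win equal-length numeric windows.
#' @return Scalar in `[0, 1]`.
#' @export
mpc <- function(x_win, y_win) {
  if (length(x_win) != length(y_win)) stop("windows must have equal length")
  dphi <- instantaneous_phase(x_win) - instantaneous_phase(y_win)
  Mod(mean(exp(1i * dphi)))
}

#' Single-channel comparison features
#'
#' Standard per-window features used as seizure-detection baselines:
#' \describe{
#'   \item{AMP}{mean absolute amplitude.}
#'   \item{LL}{line length, sum of absolute successive differences.}
#'   \item{VAR}{population variance.}
#'   \item{MSP}{maximum slope, max absolute successive difference times `fs`.}
#'   \item{TP}{total power, mean squared value.}
#'   \item{PSR}{power spectral ratio: periodogram power inside `band` over
#'     total power.}
#'   \item{ApEn}{approximate entropy with embedding `m` and tolerance
#'     `r * sd(x)` (defaults m = 2, r = 0.2).}
#' }
#'
#' @param x_win numeric window (length >= 2; >= m+1 for ApEn).
#' @param fs sampling rate, Hz.
#' @param name one of `"AMP"`, `"LL"`, `"VAR"`, `"MSP"`, `"TP"`, `"PSR"`,
#'   `"ApEn"`.
#' @param band `c(f_lo, f_hi)` Hz, required for PSR.
#' @param m,r ApEn embedding dimension and tolerance factor.
#' @return A scalar feature value.
#' @export
single_channel_feature <- function(x_win, fs, name, band = NULL, m = 2L,
                                   r = 0.2) {
  if (length(x_win) < 2L) stop("window too short")
  switch(toupper(name),
    AMP = mean(abs(x_win)),
    LL = sum(abs(diff(x_win))),
    VAR = mean((x_win - mean(x_win))^2),
    MSP = max(abs(diff(x_win))) * fs,
    TP = mean(x_win^2),
    PSR = {
      if (is.null(band)) stop("PSR needs a frequency band")
      n <- length(x_win)
      p <- Mod(stats::fft(x_win - mean(x_win)))^2
      f <- (seq_len(n) - 1L) * fs / n
      half <- f <= fs / 2
      tot <- sum(p[half])
      if (tot == 0) 0 else sum(p[half & f >= band[1] & f <= band[2]]) / tot
    },
    APEN = {
      if (length(x_win) < m + 1L) stop("window too short for ApEn")
      if (stats::sd(x_win) == 0) 0
      else pracma::approx_entropy(x_win, edim = m, r = r * stats::sd(x_win))
    },
    stop("unknown feature: ", name))
}

#' Sliding-window baseline feature curve
#'
#' Computes a comparison feature on the same 400 ms / 200 ms window grid as
#' the detection features, so it can be pushed through the identical
#' threshold machinery ([init_thresholds()], [detect_events()],
#' [evaluate_detections()]). Multi-channel features (`"MPC"`, `"CC"`) take a
#' channel pair; single-channel features take one channel. `"CC"` is the
#' plain maximal cross-correlation without band or pair selection.
#'
#' @param rec an [recording()].
#' @param feature feature name: `"MPC"`, `"CC"`, or a
#'   [single_channel_feature()] name.
#' @param channels one channel index, or `c(i, j)` for MPC/CC.
#' @param window_s,overlap_s window grid (defaults 0.4 / 0.2 s).
#' @param band optional band for PSR (Hz).
#' @param max_lag_ms lag bound for CC, milliseconds.
#' @return A list of class `baseline_curve`: `feature`, `times`, `values`.
#' @export
baseline_curve <- function(rec, feature, channels, window_s = 0.4,
                           overlap_s = 0.2, band = NULL, max_lag_ms = 50) {
  stopifnot(inherits(rec, "lfp_recording"))
  feature <- toupper(feature)
  starts <- window_starts(n_samples(rec), rec$fs, window_s, overlap_s)
  times <- window_times(starts, rec$fs, window_s, rec$start_s)
  w <- round(window_s * rec$fs)
  if (feature == "CC") {
    if (length(channels) != 2L) stop("CC needs a channel pair")
    fcurv <- cc_curves(rec, rbind(channels), band = NULL,
                       window_s = window_s, overlap_s = overlap_s,
                       max_lag_ms = max_lag_ms)
    vals <- as.numeric(fcurv$per_pair_cc[1L, ])
  } else if (feature == "MPC") {
    if (length(channels) != 2L) stop("MPC needs a channel pair")
    x <- rec$data[, channels[1]]; y <- rec$data[, channels[2]]
    vals <- vapply(starts, function(s) {
      xi <- x[s:(s + w - 1L)]; yi <- y[s:(s + w - 1L)]
      if (stats::sd(xi) == 0 || stats::sd(yi) == 0) 0 else mpc(xi, yi)
    }, numeric(1))
  } else {
    if (length(channels) != 1L) stop(feature, " is a single-channel feature")
    x <- rec$data[, channels]
    vals <- vapply(starts, function(s)
      single_channel_feature(x[s:(s + w - 1L)], rec$fs, feature, band = band),
      numeric(1))
  }
  structure(list(feature = feature, times = times, values = vals),
            class = "baseline_curve")
}

#' Adapt a baseline curve to the detector interface
#'
#' Wraps a single-feature curve as a `cc_features` object whose AVG and STD
#' curves both equal the feature values, so the unchanged
#' [init_thresholds()] / [detect_events()] / [evaluate_detections()] chain
#' applies a single `u + 3*sd` threshold to the feature.
#'
#' @param curve a [baseline_curve()].
#' @param duration_s recording duration, seconds.
#' @return A `cc_features` object.
#' @export
as_feature_series <- function(curve, duration_s) {
  stopifnot(inherits(curve, "baseline_curve"))
  per <- matrix(curve$values, nrow = 1L,
                dimnames = list("1-2", NULL))
  structure(list(times = curve$times, per_pair_cc = per,
                 pairs = as_pair_matrix(rbind(c(1L, 2L))), band = NULL,
                 fs = NA_real_, duration_s = duration_s,
                 window_s = NA_real_, overlap_s = NA_real_,
                 avg = curve$values, std = curve$values,
                 selected = NULL, background = NULL),
            class = "cc_features")
}
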