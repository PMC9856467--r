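#' Configuration for the synthetic multichannel LFP generator
#'
#' Describes a recording in which every channel carries independent
#' 1/f^alpha background noise and, during each labeled seizure epoch, the
#' channels named in `coupled_pairs` additionally receive one shared
#' band-limited source (white noise band-passed to `coupling_band`) with a
#' per-channel gain and a small per-channel lag. This reproduces the
#' statistical structure the detection method assumes: a multi-site,
#' band-specific synchronization increase at seizure onset.
#'
#' Defaults describe the standard validation recording used throughout the
#' package: 12 channels at 1 kHz for 30 minutes, fifteen 10 s seizures every
#' 120 s (the first five serve as the threshold-training set), coupling
#' confined to the three pairs of a three-channel clique in the 150-250 Hz
#' band with a strong gain.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz.
#' @param duration_s total duration, seconds.
#' @param seizures data frame with columns `onset_s`, `duration_s`; epochs
#'   must lie inside the recording and not overlap.
#' @param coupled_pairs channel-index pairs (1-based) that synchronize; every
#'   channel appearing here receives the shared source.
#' @param coupling_band `c(f_lo, f_hi)` in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param coupling_gain source standard deviation as a multiple of the
#'   background standard deviation; `>= 0` (0 disables coupling).
#' @param lag_ms maximal per-channel lag of the shared source, milliseconds;
#'   lags are drawn once per channel, uniformly on `[0, lag_ms]`, and applied
#'   as exact fractional-sample delays.
#' @param background_exponent spectral slope alpha of the 1/f^alpha background.
#' @param background_sd background noise standard deviation (microvolts).
#' @param mains_amplitude amplitude of an optional common 50 Hz mains
#'   component (microvolts); 0 disables it.
#' @param channel_gain_range range of per-channel source gain multipliers.
#' @param quantize_16bit if `TRUE`, round samples to integer microvolts and
#'   clip to the signed 16-bit range.
#' @param seed integer seed; identical configurations with identical seeds
#'   generate bit-identical recordings.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 12L, fs = 1000, duration_s = 1800,
                         seizures = data.frame(
                           onset_s = 60 + 120 * (0:14), duration_s = 10),
                         coupled_pairs = rbind(c(1, 2), c(1, 3), c(2, 3)),
                         coupling_band = c(150, 250), coupling_gain = 4,
                         lag_ms = 5, background_exponent = 1,
                         background_sd = 50, mains_amplitude = 0,
                         channel_gain_range = c(0.8, 1.2),
                         quantize_16bit = FALSE, seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              duration_s = duration_s,
              seizures = as.data.frame(seizures),
              coupled_pairs = as_pair_matrix(coupled_pairs),
              coupling_band = as.numeric(coupling_band),
              coupling_gain = coupling_gain, lag_ms = lag_ms,
              background_exponent = background_exponent,
              background_sd = background_sd,
              mains_amplitude = mains_amplitude,
              channel_gain_range = as.numeric(channel_gain_range),
              quantize_16bit = isTRUE(quantize_16bit), seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_channels < 1L) stop("n_channels must be >= 1")
  if (cfg$fs <= 0 || cfg$duration_s <= 0) stop("fs and duration_s must be positive")
  b <- cfg$coupling_band
  if (!(length(b) == 2 && 0 < b[1] && b[1] < b[2] && b[2] < cfg$fs / 2))
    stop("coupling_band must satisfy 0 < f_lo < f_hi < fs/2")
  if (cfg$coupling_gain < 0) stop("coupling_gain must be >= 0")
  sz <- cfg$seizures
  if (nrow(sz)) {
    if (!all(c("onset_s", "duration_s") %in% names(sz)))
      stop("seizures needs columns onset_s, duration_s")
    off <- sz$onset_s + sz$duration_s
    if (any(sz$onset_s < 0) || any(off > cfg$duration_s))
      stop("seizure epochs must lie within [0, duration_s]")
    o <- order(sz$onset_s)
    if (any(sz$onset_s[o][-1] < off[o][-nrow(sz)]))
      stop("seizure epochs overlap")
  }
  if (nrow(cfg$coupled_pairs) &&
      max(cfg$coupled_pairs) > cfg$n_channels)
    stop("coupled_pairs reference channels beyond n_channels")
  invisible(cfg)
}

# 1/f^alpha Gaussian noise of length n, unit standard deviation.
one_over_f_noise <- function(n, fs, alpha) {
  white <- stats::rnorm(n)
  if (alpha == 0) return(white)
  X <- stats::fft(white)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]    # two-sided frequency magnitude
  h <- c(0, 1 / f[-1]^(alpha / 2))       # kill DC
  x <- Re(stats::fft(X * h, inverse = TRUE)) / n
  x / stats::sd(x)
}

# White Gaussian noise strictly band-limited to [f_lo, f_hi] by FFT masking,
# so the shared seizure source has sharp spectral edges.
band_limited_noise <- function(n, fs, band) {
  X <- stats::fft(stats::rnorm(n))
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  X[!(f >= band[1] & f <= band[2])] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Exact fractional-sample delay via FFT phase ramp (circular on a padded copy).
frac_delay <- function(x, delay_samples) {
  n0 <- length(x)
  pad <- 64L
  xp <- c(x, numeric(pad))
  n <- length(xp)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  ph <- exp(-2i * pi * k * delay_samples / n)
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1])
  y <- Re(stats::fft(stats::fft(xp) * ph, inverse = TRUE)) / n
  y[seq_len(n0)]
}

#' Generate a synthetic multichannel LFP recording
#'
#' Draws the recording described by a [synth_config()]: independent
#' 1/f^alpha background per channel, one shared band-limited source per
#' seizure epoch added (with per-channel gains and fractional-sample lags) to
#' every channel that appears in `coupled_pairs`, and optional common 50 Hz
#' mains contamination. The returned annotations match the configured epochs.
#'
#' @param cfg a [synth_config()].
#' @return A list with elements `recording` (an [recording()]) and
#'   `annotations` (a [annotations()] data frame).
#' @examples
#' sim <- synth_lfp(synth_config(n_channels = 4, duration_s = 30,
#'   seizures = data.frame(onset_s = 10, duration_s = 5), seed = 7))
#' sim$recording
#' @export
synth_lfp <- function(cfg) {
  validate_synth_config(cfg)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n <- round(cfg$duration_s * cfg$fs)
  data <- matrix(0, nrow = n, ncol = cfg$n_channels)
  for (ch in seq_len(cfg$n_channels)) {
    data[, ch] <- cfg$background_sd *
      one_over_f_noise(n, cfg$fs, cfg$background_exponent)
  }

  coupled_channels <- sort(unique(as.vector(cfg$coupled_pairs)))
  if (length(coupled_channels) && cfg$coupling_gain > 0 && nrow(cfg$seizures)) {
    gains <- stats::runif(length(coupled_channels),
                          cfg$channel_gain_range[1], cfg$channel_gain_range[2])
    lags_ms <- stats::runif(length(coupled_channels), 0, cfg$lag_ms)
    src_sd <- cfg$coupling_gain * cfg$background_sd
    for (k in seq_len(nrow(cfg$seizures))) {
      i0 <- round(cfg$seizures$onset_s[k] * cfg$fs) + 1L
      len <- round(cfg$seizures$duration_s[k] * cfg$fs)
      i1 <- min(n, i0 + len - 1L)
      src <- band_limited_noise(i1 - i0 + 1L, cfg$fs, cfg$coupling_band)
      src <- src / stats::sd(src) * src_sd
      for (ci in seq_along(coupled_channels)) {
        ch <- coupled_channels[ci]
        delayed <- frac_delay(src, lags_ms[ci] * cfg$fs / 1000)
        data[i0:i1, ch] <- data[i0:i1, ch] + gains[ci] * delayed
      }
    }
  }

  if (cfg$mains_amplitude > 0) {
    t <- (seq_len(n) - 1L) / cfg$fs
    mains <- cfg$mains_amplitude * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    data <- data + mains
  }
  if (cfg$quantize_16bit) {
    data <- pmin(pmax(round(data), -32768), 32767)
  }
  ann <- if (nrow(cfg$seizures)) {
    annotations(cfg$seizures$onset_s,
                cfg$seizures$onset_s + cfg$seizures$duration_s)
  } else {
    annotations(numeric(0), numeric(0))
  }
  list(recording = recording(data, cfg$fs), annotations = ann)
}

#' Synthetic step-change MSC map
#'
#' Builds an MSC-map-like time-frequency matrix whose coherence steps from
#' `lo` to `hi` at a known time column, inside a known frequency-row band.
#' The band edges roll off smoothly over `roll_rows` rows (coherence decays
#' gradually across frequency in real maps), so the dominant gradient is the
#' temporal step. Used to exercise edge detection with ground truth.
#'
#' @param n_freq,n_time map dimensions (rows = frequency bins, cols = time).
#' @param change_col column index of the coherence step.
#' @param band_rows integer range `c(r_lo, r_hi)` of fully elevated rows.
#' @param lo,hi coherence levels before/after the step.
#' @param roll_rows width of the raised-cosine roll-off at each band edge.
#' @param noise_sd additive uniform-noise amplitude on every pixel.
#' @param fs nominal sampling rate used to assign frequencies (Hz).
#' @return An object of class `msc_map` (see [build_msc_map()]).
#' @export
synth_step_map <- function(n_freq = 96, n_time = 80, change_col = 40,
                           band_rows = c(34, 62), lo = 0.1, hi = 0.8,
                           roll_rows = 28, noise_sd = 0.02, fs = 1000) {
  profile <- numeric(n_freq)
  r <- seq_len(n_freq)
  profile[r >= band_rows[1] & r <= band_rows[2]] <- 1
  for (edge in 1:2) {
    ramp <- seq_len(roll_rows) / (roll_rows + 1)
    ramp <- (1 - cos(pi * ramp)) / 2
    if (edge == 1) {
      rows <- band_rows[1] - rev(seq_len(roll_rows))
      keep <- rows >= 1
      profile[rows[keep]] <- pmax(profile[rows[keep]], ramp[keep])
    } else {
      rows <- band_rows[2] + seq_len(roll_rows)
      keep <- rows <= n_freq
      profile[rows[keep]] <- pmax(profile[rows[keep]], rev(ramp)[keep])
    }
  }
  vals <- matrix(lo, n_freq, n_time)
  post <- change_col:n_time
  vals[, post] <- lo + outer(profile, rep(hi - lo, length(post)))
  vals <- vals + matrix(stats::runif(n_freq * n_time, -noise_sd, noise_sd),
                        n_freq, n_time)
  vals <- pmin(pmax(vals, 0), 1)
  msc_map_obj(vals,
              freqs = seq(0, fs / 2, length.out = n_freq),
              times = 0.2 * seq_len(n_time),
              pair = c(1L, 2L))
}
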