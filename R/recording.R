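#' Multichannel LFP/iEEG recording container
#'
#' An `lfp_recording` holds a samples-by-channels numeric matrix together with
#' its sampling rate and channel labels. All channels share one sampling rate
#' and length; amplitudes are on the microvolt scale typical of intracranial
#' recordings.
#'
#' @param data numeric matrix, one column per channel (rows are samples), or a
#'   data frame coercible to one.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names; defaults to
#'   the matrix column names or `ch1..chn`.
#' @return An object of class `lfp_recording` with elements `data`, `fs`,
#'   `channel_labels` and `duration_s`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), ncol = 2), fs = 1000)
#' rec$duration_s
#' @export
recording <- function(data, fs, channel_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_labels)) {
    channel_labels <- colnames(data)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(data))
    stop("channel_labels must match the number of channels")
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique")
  colnames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         duration_s = nrow(data) / fs, start_s = 0),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$data), nrow(x$data), x$fs, x$duration_s))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

n_channels <- function(rec) ncol(rec$data)
n_samples <- function(rec) nrow(rec$data)

#' Extract a time slice of a recording
#'
#' Returns the samples with time in `[from_s, to_s)`. The slice remembers its
#' absolute start time (`start_s`) so downstream time axes (MSC maps, feature
#' curves) stay on the original clock.
#'
#' @param rec an [recording()].
#' @param from_s,to_s slice boundaries in seconds from the recording start.
#' @return An `lfp_recording` covering the requested span.
#' @export
crop_recording <- function(rec, from_s, to_s) {
  stopifnot(inherits(rec, "lfp_recording"))
  from_s <- max(0, from_s)
  to_s <- min(rec$duration_s, to_s)
  if (to_s <= from_s) stop("empty slice: to_s must exceed from_s")
  i0 <- floor(from_s * rec$fs) + 1L
  i1 <- min(n_samples(rec), ceiling(to_s * rec$fs))
  out <- recording(rec$data[i0:i1, , drop = FALSE], rec$fs, rec$channel_labels)
  out$start_s <- rec$start_s + (i0 - 1L) / rec$fs
  out
}

#' Read a multichannel recording
#'
#' Supported formats: `"csv"` (one header row of channel labels, one column
#' per channel; the sampling rate is supplied through `fs`), `"edf"`
#' (European Data Format, 16-bit records, read-only; all signals must share
#' one sampling rate) and `"rds"` (R's serialized container, written by
#' [write_recording()]).
#'
#' @param path file path.
#' @param format one of `"csv"`, `"edf"`, `"rds"`; default guesses from the
#'   file extension.
#' @param fs sampling rate in Hz, required for CSV input.
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf", "rds"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf", rds = "rds",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  switch(format,
    csv = {
      if (is.null(fs)) stop("fs must be supplied for CSV recordings")
      tab <- utils::read.csv(path, check.names = FALSE)
      if (nrow(tab) == 0L) stop("format error: CSV recording has no samples: ", path)
      if (anyNA(tab)) stop("format error: ragged or non-numeric channels in ", path)
      recording(as.matrix(tab), fs = fs, channel_labels = colnames(tab))
    },
    rds = {
      obj <- readRDS(path)
      if (!inherits(obj, "lfp_recording")) stop("format error: not a recording: ", path)
      recording(obj$data, obj$fs, obj$channel_labels)
    },
    edf = read_edf(path))
}

#' Write a recording to CSV or RDS
#'
#' CSV output stores one column per channel with a label header; the sampling
#' rate must travel out of band (the `fs` argument of [read_recording()]).
#' RDS output is self-describing.
#'
#' @param rec an [recording()].
#' @param path output path.
#' @param format `"csv"` or `"rds"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "rds")) {
  stopifnot(inherits(rec, "lfp_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), csv = "csv", rds = "rds",
                     stop("cannot guess format for ", path))
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(rec$data), path, row.names = FALSE)
  } else {
    saveRDS(rec, path)
  }
  invisible(path)
}

# Minimal EDF reader: fixed 256-byte header, per-signal header blocks, data
# records of 16-bit little-endian integers scaled to physical units. Requires
# all signals to share one sampling rate (true for the recordings this
# package targets).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  hdr(8)                       # version
  hdr(80); hdr(80)             # patient / recording id
  hdr(8); hdr(8)               # start date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                      # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1L) stop("format error: bad EDF signal count in ", path)
  field <- function(nc) vapply(seq_len(ns), function(i) hdr(nc), character(1))
  labels <- field(16)
  field(80); field(8)                      # transducer, physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                # prefiltering
  nsamp <- as.integer(field(8))
  field(32)                                # reserved
  if (length(unique(nsamp)) != 1L)
    stop("format error: EDF signals with differing sampling rates in ", path)
  seek(con, header_bytes)
  total <- n_records * sum(nsamp)
  raw16 <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                   endian = "little")
  if (length(raw16) < total) stop("format error: truncated EDF data in ", path)
  # records are channel-blocked: reshape to samples x channels
  arr <- array(raw16, dim = c(nsamp[1], ns, n_records))
  data <- matrix(0, nrow = nsamp[1] * n_records, ncol = ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns)) {
    dig <- as.vector(arr[, s, ])
    data[, s] <- phys_min[s] + (dig - dig_min[s]) * scale[s]
  }
  fs <- nsamp[1] / record_dur
  recording(data, fs = fs, channel_labels = make.unique(labels))
}

#' Read seizure annotations
#'
#' Annotations are delimited text with columns `onset_s`, `offset_s`, `label`
#' (times in seconds from recording start). Rows are validated
#' (`0 <= onset_s < offset_s`), sorted by onset, and must not overlap.
#'
#' @param path CSV file path.
#' @return A data frame of class `seizure_annotations`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotations: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "label")
  if (!all(need %in% names(tab)))
    stop("annotation file must have columns onset_s, offset_s, label")
  annotations(tab$onset_s, tab$offset_s, tab$label)
}

#' Construct validated seizure annotations
#'
#' @param onset_s,offset_s numeric vectors of epoch boundaries in seconds;
#'   intervals are half-open `[onset, offset)`.
#' @param label optional character labels.
#' @return A sorted, non-overlapping data frame of class `seizure_annotations`.
#' @export
annotations <- function(onset_s, offset_s, label = NULL) {
  onset_s <- as.numeric(onset_s); offset_s <- as.numeric(offset_s)
  if (length(onset_s) != length(offset_s))
    stop("onset_s and offset_s must have equal length")
  if (is.null(label)) label <- if (length(onset_s)) paste0("sz", seq_along(onset_s)) else character(0)
  bad <- which(!(onset_s >= 0 & onset_s < offset_s))
  if (length(bad))
    stop("invalid annotation at row ", bad[1], ": need 0 <= onset_s < offset_s")
  o <- order(onset_s)
  ann <- data.frame(onset_s = onset_s[o], offset_s = offset_s[o],
                    label = as.character(label)[o], stringsAsFactors = FALSE)
  if (nrow(ann) > 1L && any(ann$onset_s[-1] < ann$offset_s[-nrow(ann)]))
    stop("annotations overlap")
  class(ann) <- c("seizure_annotations", "data.frame")
  ann
}

#' Write seizure annotations to CSV
#' @param ann a `seizure_annotations` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[, c("onset_s", "offset_s", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Remove 50 Hz mains contamination
#'
#' Applies a second-order IIR band-stop (notch) filter centered at 50 Hz to
#' every channel, causally (single forward pass), mirroring an online
#' acquisition-side filter. The biquad is designed for unit gain away from the
#' notch with a -3 dB bandwidth of `bw_hz`.
#'
#' @param rec an [recording()] with `fs > 100` Hz.
#' @param f0_hz notch center frequency, default 50 Hz.
#' @param bw_hz -3 dB bandwidth in Hz, default 4.
#' @return A new `lfp_recording` of the same shape.
#' @export
notch_50hz <- function(rec, f0_hz = 50, bw_hz = 4) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (rec$fs <= 2 * f0_hz)
    stop("sampling rate too low: ", f0_hz, " Hz notch needs fs > ", 2 * f0_hz, " Hz")
  w0 <- 2 * pi * f0_hz / rec$fs
  q <- f0_hz / bw_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- rec
  out$data <- apply(rec$data, 2L, function(x) as.numeric(signal::filter(b, a, x)))
  colnames(out$data) <- rec$channel_labels
  out
}
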