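# Small fixtures generated in code at test time.

# Compact coupled recording: 4 channels, one coupled pair (1,2), one seizure.
small_sim <- function(seed = 5, gain = 4, duration_s = 40,
                      onset_s = 15, sz_dur = 10) {
  synth_lfp(synth_config(
    n_channels = 4, duration_s = duration_s,
    seizures = data.frame(onset_s = onset_s, duration_s = sz_dur),
    coupled_pairs = rbind(c(1, 2)), coupling_gain = gain, seed = seed))
}

# Minimal EDF writer used only to exercise the reader: one data record per
# second, 16-bit little-endian samples, physical range chosen so microvolt
# signals survive the digital round-trip.
write_test_edf <- function(rec, path, phys_range = c(-3276.8, 3276.7)) {
  ns <- ncol(rec$data)
  n_rec <- floor(nrow(rec$data) / rec$fs)
  nsamp <- as.integer(rec$fs)
  pad <- function(s, n) formatC(as.character(s), width = -n)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, n) writeBin(charToRaw(pad(s, n)), con)
  put("0", 8); put("test patient", 80); put("test recording", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(256 * (1 + ns), 8); put("", 44)
  put(n_rec, 8); put("1", 8); put(ns, 4)
  for (lab in rec$channel_labels) put(lab, 16)
  for (i in 1:ns) put("", 80)          # transducer
  for (i in 1:ns) put("uV", 8)
  for (i in 1:ns) put(phys_range[1], 8)
  for (i in 1:ns) put(phys_range[2], 8)
  for (i in 1:ns) put(-32768, 8)
  for (i in 1:ns) put(32767, 8)
  for (i in 1:ns) put("", 80)          # prefiltering
  for (i in 1:ns) put(nsamp, 8)
  for (i in 1:ns) put("", 32)
  scale <- (32767 - (-32768)) / (phys_range[2] - phys_range[1])
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * nsamp + 1):(r * nsamp)
    for (s in seq_len(ns)) {
      dig <- round((rec$data[rows, s] - phys_range[1]) * scale) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}
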