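# Independent minimal EDF writer used only to build synthetic fixtures for
# the reader tests (continuous EDF, one record duration, int16 samples).

edf_pad <- function(s, w) {
  s <- substr(as.character(s), 1, w)
  paste0(s, strrep(" ", w - nchar(s)))
}

write_edf_fixture <- function(path, channels, sampling_rate,
                              record_duration = 1) {
  ns <- length(channels)
  n <- length(channels[[1]])
  spr <- as.integer(sampling_rate * record_duration)
  n_records <- n %/% spr
  stopifnot(n_records * spr == n)

  # round the calibration range so it prints exactly in its 8-char field
  phys_max <- vapply(channels, function(x)
    ceiling(max(1e-6, max(abs(x))) * 100) / 100, numeric(1))
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("test patient", 80), edf_pad("test recording", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_records, 8), edf_pad(format(record_duration), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    c(vapply(seq_len(ns), function(i) edf_pad(paste0("sig", i), 16), "")),
    rep(edf_pad("", 80), ns),                       # transducer
    rep(edf_pad("uV", 8), ns),                      # physical dimension
    vapply(-phys_max, edf_pad, "", w = 8),          # physical min
    vapply(phys_max, edf_pad, "", w = 8),           # physical max
    rep(edf_pad(dig_min, 8), ns),
    rep(edf_pad(dig_max, 8), ns),
    rep(edf_pad("", 80), ns),                       # prefiltering
    rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  gain <- 2 * phys_max / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- channels[[s]][(r - 1) * spr + seq_len(spr)]
      dig <- as.integer(round((seg + phys_max[s]) / gain[s] + dig_min))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
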