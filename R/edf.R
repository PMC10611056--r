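# Minimal reader for continuous European Data Format (EDF) recordings:
# 256-byte fixed header, 256 bytes of per-signal header fields, then data
# records of little-endian 16-bit integers scaled to physical units by the
# per-signal calibration (physical min/max against digital min/max).
# Discontinuous (EDF+D) files and annotation channels are out of scope;
# an "EDF Annotations" signal, if present, is dropped.

edf_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

edf_num <- function(con, n) {
  v <- suppressWarnings(as.numeric(edf_ascii(con, n)))
  if (is.na(v)) stop("malformed EDF header: non-numeric field")
  v
}

#' @rdname read_signal_file
#' @details EDF channels keep their native per-channel sampling rates
#'   (samples per record / record duration); mixing rates across selected
#'   channels is allowed at read time since channels are decomposed
#'   independently.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_ascii(con, 8L)
  if (version != "0") stop("malformed EDF file ", path,
                           ": unsupported version '", version, "'")
  invisible(readBin(con, "raw", 80L + 80L + 8L + 8L))  # patient/recording/date/time
  header_bytes <- edf_num(con, 8L)
  invisible(readBin(con, "raw", 44L))                  # reserved
  n_records <- edf_num(con, 8L)
  record_duration <- edf_num(con, 8L)
  ns <- as.integer(edf_num(con, 4L))
  if (ns < 1L) stop("malformed EDF file ", path, ": no signals")

  field <- function(width, parse = edf_ascii)
    vapply(seq_len(ns), function(i) parse(con, width), numeric(1))
  labels <- vapply(seq_len(ns), function(i) edf_ascii(con, 16L), character(1))
  invisible(readBin(con, "raw", ns * 80L))             # transducer
  units <- vapply(seq_len(ns), function(i) edf_ascii(con, 8L), character(1))
  phys_min <- field(8L, edf_num)
  phys_max <- field(8L, edf_num)
  dig_min <- field(8L, edf_num)
  dig_max <- field(8L, edf_num)
  invisible(readBin(con, "raw", ns * 80L))             # prefiltering
  spr <- as.integer(field(8L, edf_num))                # samples per record
  invisible(readBin(con, "raw", ns * 32L))             # reserved

  if (n_records < 0) stop("malformed EDF file ", path,
                          ": unknown record count")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- lapply(seq_len(ns), function(s) numeric(n_records * spr[s]))
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) != spr[s])
        stop("malformed EDF file ", path, ": truncated record ", r)
      data[[s]][(r - 1L) * spr[s] + seq_len(spr[s])] <-
        phys_min[s] + (dig - dig_min[s]) * gain[s]
    }
  }
  keep <- which(labels != "EDF Annotations")
  lapply(keep, function(s)
    signal_channel(data[[s]],
                   sampling_rate = spr[s] / record_duration,
                   label = labels[s]))
}
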