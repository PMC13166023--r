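# Write a minimal synthetic EDF file (for reader tests only): one data
# record per second, int16 little-endian, physical range +-200 uV mapped
# onto the full digital range.
write_synthetic_edf <- function(path, data, fs, channel_names,
                                phys_range = c(-200, 200)) {
  ns <- nrow(data)
  n_rec <- ncol(data) / fs
  stopifnot(n_rec == round(n_rec))
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (nm in channel_names) wr(nm, 16)
  for (i in seq_len(ns)) wr("AgAgCl", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(as.character(phys_range[1]), 8)
  for (i in seq_len(ns)) wr(as.character(phys_range[2]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- 65535 / diff(phys_range)
  for (r in seq_len(n_rec)) for (s in seq_len(ns)) {
    seg <- data[s, ((r - 1) * fs + 1):(r * fs)]
    dig <- as.integer(round((seg - phys_range[1]) * scale)) - 32768L
    writeBin(pmax(-32768L, pmin(32767L, dig)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
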