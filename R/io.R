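#' Write / read epoched EEG in the plain-matrix format
#'
#' One delimited text matrix per epoch (`epoch_0001.csv`, channels x
#' samples, full precision), a `manifest.json` with sampling rate, channel
#' names and file list, and a `labels.tsv` (`epoch_id`, `subject_id`,
#' `condition`).  The round trip is bit-exact.
#'
#' @param eeg An `epoched_eeg`.
#' @param dir Dataset directory (created if missing).
#' @export
write_epochs <- function(eeg, dir) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ne <- dim(eeg$data)[1]
  files <- sprintf("epoch_%04d.csv", seq_len(ne))
  for (i in seq_len(ne))
    write_num_matrix(eeg$data[i, , , drop = TRUE], file.path(dir, files[i]))
  jsonlite::write_json(list(format = "ssrime-epochs-v1", fs = eeg$fs,
                            channel_names = eeg$channel_names,
                            n_epochs = ne, files = files),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  lab <- data.frame(epoch_id = seq_len(ne),
                    subject_id = if (is.null(eeg$subject_id)) rep(1L, ne)
                                 else eeg$subject_id,
                    condition = as.character(eeg$labels))
  write.table(lab, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read epoched EEG
#'
#' @param path Dataset directory (`format = "matrix"`) or an EDF file
#'   (`format = "edf"`).
#' @param format Input format.
#' @param epoch_seconds For EDF input: duration used to cut the continuous
#'   recording into consecutive epochs.
#' @param labels For EDF input: optional labels file (`labels.tsv` layout)
#'   or character/factor vector, one label per epoch.
#' @param channels Optional channel names to select, in the requested order.
#' @return An `epoched_eeg`.
#' @export
read_epochs <- function(path, format = c("matrix", "edf"),
                        epoch_seconds = NULL, labels = NULL,
                        channels = NULL) {
  format <- match.arg(format)
  if (format == "matrix") read_epochs_matrix(path, channels)
  else read_epochs_edf(path, epoch_seconds, labels, channels)
}

read_epochs_matrix <- function(dir, channels = NULL) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  labf <- file.path(dir, "labels.tsv")
  if (!file.exists(labf)) stop("missing labels.tsv in ", dir)
  lab <- read.table(labf, sep = "\t", header = TRUE)
  if (!all(lab$epoch_id %in% seq_len(meta$n_epochs)))
    stop("labels file references unknown epoch_id: ",
         paste(setdiff(lab$epoch_id, seq_len(meta$n_epochs)), collapse = ", "))
  if (nrow(lab) != meta$n_epochs)
    stop("labels.tsv must have one row per epoch")
  lab <- lab[order(lab$epoch_id), ]
  first <- read_num_matrix(file.path(dir, meta$files[1]))
  data <- array(0, c(meta$n_epochs, nrow(first), ncol(first)))
  data[1, , ] <- first
  for (i in seq_len(meta$n_epochs)[-1])
    data[i, , ] <- read_num_matrix(file.path(dir, meta$files[i]))
  eeg <- structure(list(data = data, fs = as.numeric(meta$fs),
                        labels = factor(lab$condition),
                        subject_id = as.integer(lab$subject_id),
                        channel_names = meta$channel_names),
                   class = "epoched_eeg")
  if (!is.null(channels)) eeg <- select_channels(eeg, channels)
  eeg
}

select_channels <- function(eeg, channels) {
  idx <- match(channels, eeg$channel_names)
  if (anyNA(idx))
    stop("unknown channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  eeg$data <- eeg$data[, idx, , drop = FALSE]
  eeg$channel_names <- eeg$channel_names[idx]
  eeg
}

read_epochs_edf <- function(path, epoch_seconds, labels, channels) {
  rec <- read_edf(path, channels)
  if (is.null(epoch_seconds)) stop("epoch_seconds is required for EDF input")
  n <- round(rec$fs * epoch_seconds)
  ne <- floor(ncol(rec$data) / n)
  if (ne < 1) stop("recording shorter than one epoch")
  data <- array(0, c(ne, nrow(rec$data), n))
  for (i in seq_len(ne))
    data[i, , ] <- rec$data[, ((i - 1) * n + 1):(i * n)]
  lab <- if (is.null(labels)) factor(rep("unlabelled", ne))
  else if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    tb <- read.table(labels, sep = "\t", header = TRUE)
    if (!all(tb$epoch_id %in% seq_len(ne)))
      stop("labels file references unknown epoch_id: ",
           paste(setdiff(tb$epoch_id, seq_len(ne)), collapse = ", "))
    factor(tb$condition[order(tb$epoch_id)])
  } else factor(labels)
  if (length(lab) != ne) stop("need one label per epoch")
  structure(list(data = data, fs = rec$fs, labels = lab,
                 subject_id = rep(1L, ne), channel_names = rec$channel_names),
            class = "epoched_eeg")
}

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Minimal EDF reader
#'
#' Reads a European Data Format file (the standard EEG exchange format):
#' 256-byte fixed header, per-signal headers, and 16-bit little-endian data
#' records, mapped to physical units through the per-signal digital and
#' physical ranges.  Annotation channels are dropped; all retained channels
#' must share one sampling rate.
#'
#' @param path EDF file path.
#' @param channels Optional channel names to keep, in the requested order.
#' @return List with `data` (channels x samples matrix, physical units),
#'   `fs`, `channel_names`.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                       # version
  read_ascii(con, 80); read_ascii(con, 80) # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)   # start date / time
  read_ascii(con, 8)                       # header bytes
  read_ascii(con, 44)                      # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: bad signal count")
  lab <- vapply(seq_len(ns), function(i) read_ascii(con, 16), "")
  for (i in seq_len(ns)) read_ascii(con, 80)   # transducer
  for (i in seq_len(ns)) read_ascii(con, 8)    # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  for (i in seq_len(ns)) read_ascii(con, 80)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)), 0L)
  for (i in seq_len(ns)) read_ascii(con, 32)   # reserved
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)) || n_rec < 1 || rec_dur <= 0)
    stop("malformed EDF header")
  keep <- which(lab != "EDF Annotations")
  if (length(unique(spr[keep])) != 1)
    stop("channels differ in samples per record (fs mismatch)")
  data <- matrix(0, length(keep), n_rec * spr[keep[1]])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[s], size = 2, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr[s]) stop("truncated EDF data record")
      ki <- match(s, keep)
      if (!is.na(ki)) {
        g <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
        data[ki, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
          (raw - dmin[s]) * g + pmin[s]
      }
    }
  }
  out <- list(data = data, fs = spr[keep[1]] / rec_dur,
              channel_names = lab[keep])
  if (!is.null(channels)) {
    idx <- match(channels, out$channel_names)
    if (anyNA(idx))
      stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "))
    out$data <- out$data[idx, , drop = FALSE]
    out$channel_names <- channels
  }
  out
}

# zero-phase FIR filtering via FFT convolution with edge reflection
fir_filtfilt <- function(x, b) {
  nb <- length(b)
  pad <- min(length(x) - 1, 3 * nb)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
  # forward pass delays by the group delay, the time-reversed second pass
  # advances by the same amount: zero net phase
  y <- signal::fftfilt(b, xe)
  y <- rev(signal::fftfilt(b, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

#' Preprocess epoched EEG
#'
#' Zero-phase FIR band-pass (forward-backward), optional zero-phase FIR
#' notch, amplitude-threshold epoch rejection, and optional integer-factor
#' downsampling (safe after band-limiting).
#'
#' @param eeg An `epoched_eeg`.
#' @param band Pass band `c(lo, hi)` in Hz (default `c(1, 40)`); `hi` must
#'   be below Nyquist.
#' @param notch Line frequency to suppress in Hz (default 50; `NULL`
#'   disables).
#' @param reject_uV Peak-amplitude rejection threshold in microvolts
#'   (default 100; epochs with any `|sample|` above it are dropped; `NULL`
#'   disables).
#' @param fir_order FIR length minus one; default scales with `fs / lo` for
#'   adequate low-edge roll-off.
#' @param downsample Integer decimation factor applied after filtering
#'   (default 1 = none).
#' @return List with `eeg` (the processed `epoched_eeg`) and
#'   `rejected` (integer ids of dropped epochs).
#' @export
preprocess <- function(eeg, band = c(1, 40), notch = 50, reject_uV = 100,
                       fir_order = NULL, downsample = 1) {
  stopifnot(inherits(eeg, "epoched_eeg"), band[1] < band[2])
  if (band[2] >= eeg$fs / 2)
    stop("band upper edge must be below the Nyquist frequency")
  n <- dim(eeg$data)[3]
  if (is.null(fir_order)) {
    fir_order <- min(round(3 * eeg$fs / band[1]), floor(n / 3) * 2)
    if (fir_order %% 2 == 1) fir_order <- fir_order + 1
  }
  bp <- signal::fir1(fir_order, band / (eeg$fs / 2), type = "pass")
  nt <- if (!is.null(notch) && notch < eeg$fs / 2)
    signal::fir1(fir_order, c(notch - 2, notch + 2) / (eeg$fs / 2),
                 type = "stop")
  ne <- dim(eeg$data)[1]
  nc <- dim(eeg$data)[2]
  for (i in seq_len(ne)) for (j in seq_len(nc)) {
    y <- fir_filtfilt(eeg$data[i, j, ], bp)
    if (!is.null(nt)) y <- fir_filtfilt(y, nt)
    eeg$data[i, j, ] <- y
  }
  rejected <- integer(0)
  if (!is.null(reject_uV)) {
    peak <- apply(abs(eeg$data), 1, max)
    rejected <- which(peak > reject_uV)
    if (length(rejected)) eeg <- subset_epochs(eeg, -rejected)
  }
  if (downsample > 1) {
    keep <- seq(1, dim(eeg$data)[3], by = downsample)
    eeg$data <- eeg$data[, , keep, drop = FALSE]
    eeg$fs <- eeg$fs / downsample
  }
  list(eeg = eeg, rejected = rejected)
}

#' Full pipeline configuration
#'
#' Bundles preprocessing, decomposition, feature, synthetic-data and
#' evaluation settings with one master seed; serializable to JSON with
#' full round-trip fidelity via [save_config] / [load_config].
#'
#' @param preprocessing List with `band`, `notch`, `reject_uV`,
#'   `downsample`.
#' @param ceemdan A [ceemdan_params].
#' @param features An [ssrime_params].
#' @param synthetic A [synth_config].
#' @param evaluation List with `classifier`, `n_folds`, `n_repeats`.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocessing = list(band = c(1, 40), notch = 50,
                                                 reject_uV = 100,
                                                 downsample = 1L),
                            ceemdan = ceemdan_params(),
                            features = ssrime_params(),
                            synthetic = synth_config(),
                            evaluation = list(classifier = "svm",
                                              n_folds = 10L,
                                              n_repeats = 10L),
                            seed = 1) {
  pp <- list(band = as.numeric(preprocessing$band),
             notch = if (is.null(preprocessing$notch)) NULL
                     else as.numeric(preprocessing$notch),
             reject_uV = if (is.null(preprocessing$reject_uV)) NULL
                         else as.numeric(preprocessing$reject_uV),
             downsample = as.integer(
               if (is.null(preprocessing$downsample)) 1L
               else preprocessing$downsample))
  stopifnot(pp$band[1] < pp$band[2],
            is.null(pp$reject_uV) || pp$reject_uV > 0)
  ev <- list(classifier = as.character(evaluation$classifier),
             n_folds = as.integer(evaluation$n_folds),
             n_repeats = as.integer(evaluation$n_repeats))
  structure(list(preprocessing = pp,
                 ceemdan = if (inherits(ceemdan, "ceemdan_params")) ceemdan
                           else do.call(ceemdan_params, ceemdan),
                 features = if (inherits(features, "ssrime_params")) features
                            else do.call(ssrime_params, features),
                 synthetic = if (inherits(synthetic, "synth_config")) synthetic
                             else do.call(synth_config, synthetic),
                 evaluation = ev, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- rapply(unclass(config), identity, how = "list")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}
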