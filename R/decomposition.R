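#' Single-channel EEG epoch
#'
#' Light container for one channel of one epoch: a finite numeric series in
#' microvolts plus its sampling rate.  All decomposition functions accept
#' either a `signal_epoch` or a bare numeric vector with `fs` supplied.
#'
#' @param samples Numeric vector of samples (microvolts), all finite,
#'   length at least 4.
#' @param fs Sampling rate in Hz, positive.
#' @param channel_id,epoch_id Optional labels carried through the pipeline.
#' @return An object of class `signal_epoch`.
#' @examples
#' x <- signal_epoch(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), fs = 250)
#' @export
signal_epoch <- function(samples, fs, channel_id = NA_character_,
                         epoch_id = NA_character_) {
  samples <- as.numeric(samples)
  fs <- as.numeric(fs)
  stopifnot(length(fs) == 1, fs > 0)
  if (length(samples) < 4)
    stop("signal_epoch needs at least 4 samples for extrema-based sifting")
  if (!all(is.finite(samples)))
    stop("signal_epoch samples must all be finite")
  structure(list(samples = samples, fs = fs,
                 channel_id = as.character(channel_id),
                 epoch_id = as.character(epoch_id)),
            class = "signal_epoch")
}

as_samples <- function(x) {
  if (inherits(x, "signal_epoch")) x$samples else as.numeric(x)
}

epoch_fs <- function(x, fs = NULL) {
  if (inherits(x, "signal_epoch")) return(x$fs)
  if (is.null(fs)) stop("fs must be supplied when the input is a bare vector")
  fs
}

#' CEEMDAN / sifting parameters
#'
#' @param n_realizations Number of noise-perturbed ensemble members
#'   (default 100).
#' @param noise_scale Noise amplitude as a fraction of the standard deviation
#'   of the current residual (default 0.2).
#' @param max_imfs Cap on the number of extracted modes (default 8); the
#'   effective cap is also limited to `floor(log2(N)) - 1` for an N-sample
#'   signal.
#' @param sift_sd_threshold Cauchy-type sifting stop: iteration halts once
#'   `sum((h_prev - h_new)^2) / sum(h_prev^2)` drops below this value
#'   (default 0.2).
#' @param max_sift_iters Hard cap on sifting iterations per mode
#'   (default 100).
#' @param seed Integer seed for the ensemble noise; `NULL` uses the current
#'   RNG state.
#' @return A list of class `ceemdan_params`.
#' @export
ceemdan_params <- function(n_realizations = 100, noise_scale = 0.2,
                           max_imfs = 8, sift_sd_threshold = 0.2,
                           max_sift_iters = 100, seed = NULL) {
  p <- list(n_realizations = as.integer(n_realizations),
            noise_scale = as.numeric(noise_scale),
            max_imfs = as.integer(max_imfs),
            sift_sd_threshold = as.numeric(sift_sd_threshold),
            max_sift_iters = as.integer(max_sift_iters),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(p$n_realizations >= 1, p$noise_scale > 0, p$max_imfs >= 1,
            p$sift_sd_threshold > 0, p$max_sift_iters >= 1)
  class(p) <- "ceemdan_params"
  p
}

effective_max_imfs <- function(n, max_imfs) {
  max(1L, min(as.integer(max_imfs), as.integer(floor(log2(n))) - 1L))
}

new_imf_set <- function(imfs, residual, fs, method, params = NULL,
                        order_is_stabilized = FALSE) {
  structure(list(imfs = imfs, residual = as.numeric(residual),
                 source_length = length(residual), fs = fs,
                 method = method, params = params,
                 order_is_stabilized = order_is_stabilized),
            class = "imf_set")
}

#' Sift one candidate intrinsic mode function
#'
#' Iteratively subtracts the mean of the upper and lower cubic-spline
#' envelopes (extrema mirrored past both ends) until the Cauchy SD criterion
#' falls below `sd_threshold` or `max_iters` is reached.
#'
#' @param x A [signal_epoch] or numeric vector.
#' @param sd_threshold,max_iters Sifting stop controls, see [ceemdan_params].
#' @return Numeric candidate IMF with attributes `iters`, `converged`, and
#'   `imf_condition` (extrema and zero-crossing counts differ by at most one).
#' @details Signals an error of class `ssrime_trend_error` when the input has
#'   fewer than two interior maxima or minima (a monotone/trend input, to be
#'   treated as residual).
#' @export
sift <- function(x, sd_threshold = 0.2, max_iters = 100) {
  xs <- as_samples(x)
  res <- .sift_cpp(xs, sd_threshold, as.integer(max_iters))
  if (!res$ok)
    stop(structure(class = c("ssrime_trend_error", "error", "condition"),
                   list(message = "too few extrema: monotone/trend input, treat as residual",
                        call = sys.call())))
  structure(res$imf, iters = res$iters, converged = res$converged,
            imf_condition = res$imf_condition)
}

#' Empirical mode decomposition
#'
#' Classical EMD: repeatedly sift the residual until it is monotone (or the
#' mode cap is reached).  The element-wise sum of the modes plus the residual
#' reconstructs the input to machine precision.
#'
#' @inheritParams sift
#' @param params A [ceemdan_params] object (only the sifting fields and
#'   `max_imfs` are used).
#' @param fs Sampling rate, required when `x` is a bare numeric vector.
#' @return An object of class `imf_set` with fields `imfs` (K x N matrix),
#'   `residual`, `fs`, `source_length` and `method`.
#' @examples
#' t <- seq(0, 4, by = 1 / 500)
#' d <- emd(sin(2 * pi * 25 * t) + 2 * sin(2 * pi * 3 * t), fs = 500)
#' @export
emd <- function(x, fs = NULL, params = ceemdan_params()) {
  xs <- as_samples(x)
  fs <- epoch_fs(x, fs)
  k <- effective_max_imfs(length(xs), params$max_imfs)
  res <- .emd_cpp(xs, k, params$sift_sd_threshold, params$max_sift_iters)
  new_imf_set(res$imfs, res$residual, fs, "emd", params)
}

#' CEEMDAN decomposition
#'
#' Complete ensemble EMD with adaptive noise (Torres scheme): the k-th mode
#' is the ensemble average of the first EMD mode of the current residual
#' perturbed with the (k-1)-th EMD mode of each white-noise realization,
#' scaled to `noise_scale` times the residual's standard deviation.  The
#' residual is defined by successive subtraction, so reconstruction is exact
#' by construction.  Given `params$seed` the result is deterministic.
#'
#' @inheritParams emd
#' @return An `imf_set` as for [emd], with `method = "ceemdan"`.
#' @export
ceemdan <- function(x, fs = NULL, params = ceemdan_params()) {
  xs <- as_samples(x)
  fs <- epoch_fs(x, fs)
  n <- length(xs)
  k <- effective_max_imfs(n, params$max_imfs)
  draw <- function() matrix(rnorm(n * params$n_realizations), n,
                            params$n_realizations)
  noise <- if (is.null(params$seed)) draw() else with_seed(params$seed, draw())
  res <- .ceemdan_cpp(xs, noise, params$noise_scale, k,
                      params$sift_sd_threshold, params$max_sift_iters)
  if (nrow(res$imfs) == 0)
    warning("degenerate input (constant or too few extrema): returning K = 0")
  new_imf_set(res$imfs, res$residual, fs, "ceemdan", params)
}

#' Reconstruct a signal from its decomposition
#'
#' @param imfset An `imf_set`.
#' @return Numeric vector: element-wise sum of all modes plus the residual.
#' @export
reconstruct <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  if (nrow(imfset$imfs) > 0 &&
      ncol(imfset$imfs) != length(imfset$residual))
    stop("length mismatch between imfs and residual")
  if (nrow(imfset$imfs) == 0) return(imfset$residual)
  colSums(imfset$imfs) + imfset$residual
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %s: K = %d modes + residual, %d samples @ %g Hz%s\n",
              x$method, nrow(x$imfs), x$source_length, x$fs,
              if (isTRUE(x$order_is_stabilized)) " (stabilized order)" else ""))
  invisible(x)
}

# full-precision delimited numeric matrix, bit-exact on round trip
write_num_matrix <- function(m, path) {
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
}

read_num_matrix <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
}

#' Write / read a decomposition as plain text
#'
#' The matrix file holds (K + 1) rows by N columns (modes in order, residual
#' last); a JSON sidecar `<path>.json` records the sampling rate, method and
#' decomposition parameters.
#'
#' @param imfset An `imf_set`.
#' @param path Output file for the matrix.
#' @return `read_imfset` returns the reconstructed `imf_set`.
#' @export
write_imfset <- function(imfset, path) {
  stopifnot(inherits(imfset, "imf_set"))
  write_num_matrix(rbind(imfset$imfs, imfset$residual), path)
  meta <- list(fs = imfset$fs, method = imfset$method,
               n_imfs = nrow(imfset$imfs),
               order_is_stabilized = imfset$order_is_stabilized,
               params = unclass(imfset$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_imfset
#' @export
read_imfset <- function(path) {
  m <- read_num_matrix(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  k <- meta$n_imfs
  params <- if (!is.null(meta$params)) do.call(ceemdan_params, meta$params)
  new_imf_set(m[seq_len(k), , drop = FALSE], m[k + 1, ], as.numeric(meta$fs),
              meta$method, params,
              isTRUE(meta$order_is_stabilized))
}
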