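#' Canonical EEG frequency bands
#'
#' Half-open bands `[lo, hi)` in Hz: delta 1-4, theta 4-7.5, alpha 8-13,
#' beta 13-30, gamma above 30.  The half-open convention avoids double
#' counting at the 4 Hz delta/theta boundary.
#'
#' @param gamma_hi Upper edge used for the gamma band (default 45 Hz; band
#'   definitions leave it open above 30 Hz).
#' @return Named list of `c(lo, hi)` pairs.
#' @export
eeg_bands <- function(gamma_hi = 45) {
  list(delta = c(1, 4), theta = c(4, 7.5), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, gamma_hi))
}

#' SS-RIME feature parameters
#'
#' @param alpha Stabilization exponent of the dispersion penalty
#'   `S = exp(-alpha * sigma/|mu|)` (default 1; `alpha = 0` disables
#'   stabilization).
#' @param delta_band,theta_band Half-open physiological bands in Hz.
#' @param K Target number of mode features per channel; decompositions with
#'   fewer modes are zero-padded, with more are truncated (default 8).
#' @param epsilon Numerical stability constant added to the total energy
#'   (default 1e-12).
#' @param weight_mode `"spectral_energy"` (fraction of Hilbert spectral
#'   energy inside delta+theta) or `"time_proportion"` (fraction of interior
#'   samples whose instantaneous frequency lies inside delta+theta).
#' @param energy_mode `"raw_imf"` (integral of the squared mode) or
#'   `"analytic_amplitude"` (integral of the squared instantaneous
#'   amplitude).
#' @param include_stabilization,include_weighting,include_normalization
#'   Component toggles for ablation; with all three off and
#'   `reorder = FALSE` the descriptor degrades to raw mode energies.
#' @param reorder Reorder modes by descending median instantaneous frequency
#'   before assembly (default TRUE).
#' @param dispersion_as_variance Interpret the dispersion numerator as the
#'   variance instead of the standard deviation of instantaneous frequency
#'   (default FALSE: standard deviation, which keeps sigma/mu dimensionless).
#' @param edge_trim_frac Fraction of samples trimmed at each end of every
#'   mode before computing Hilbert statistics (default 0.05).
#' @return A list of class `ssrime_params`.
#' @export
ssrime_params <- function(alpha = 1, delta_band = c(1, 4),
                          theta_band = c(4, 7.5), K = 8, epsilon = 1e-12,
                          weight_mode = c("spectral_energy", "time_proportion"),
                          energy_mode = c("raw_imf", "analytic_amplitude"),
                          include_stabilization = TRUE,
                          include_weighting = TRUE,
                          include_normalization = TRUE,
                          reorder = TRUE,
                          dispersion_as_variance = FALSE,
                          edge_trim_frac = 0.05) {
  p <- list(alpha = as.numeric(alpha),
            delta_band = as.numeric(delta_band),
            theta_band = as.numeric(theta_band),
            K = as.integer(K), epsilon = as.numeric(epsilon),
            weight_mode = match.arg(weight_mode),
            energy_mode = match.arg(energy_mode),
            include_stabilization = isTRUE(include_stabilization),
            include_weighting = isTRUE(include_weighting),
            include_normalization = isTRUE(include_normalization),
            reorder = isTRUE(reorder),
            dispersion_as_variance = isTRUE(dispersion_as_variance),
            edge_trim_frac = as.numeric(edge_trim_frac))
  stopifnot(p$alpha >= 0, p$epsilon > 0, p$K >= 1,
            p$delta_band[1] < p$delta_band[2],
            p$theta_band[1] < p$theta_band[2],
            p$delta_band[2] <= p$theta_band[1])
  class(p) <- "ssrime_params"
  p
}

#' Frequency-dispersion stabilization factor
#'
#' `S = exp(-alpha * sigma / |mu|)` with `mu` the interior mean and `sigma`
#' the interior (population) standard deviation of the instantaneous
#' frequency.  `S` lies in (0, 1], equals 1 for a perfectly steady
#' oscillation, and shrinks for jittery, noise-contaminated modes.
#'
#' @param a An `analytic_imf`.
#' @param alpha Non-negative exponent; 0 disables the penalty.
#' @param dispersion_as_variance Use the variance in place of the standard
#'   deviation (alternative reading of the dispersion definition).
#' @return S in (0, 1]; 0 with attribute `degenerate = TRUE` when the mean
#'   frequency is numerically zero (|mu| below 1e-9 Hz).
#' @export
stabilization_factor <- function(a, alpha = 1,
                                 dispersion_as_variance = FALSE) {
  stopifnot(inherits(a, "analytic_imf"), alpha >= 0)
  if (!a$freq_defined)
    return(structure(0, degenerate = TRUE))
  f <- a$inst_freq[interior_index(a)]
  mu <- mean(f)
  if (abs(mu) < 1e-9)
    return(structure(0, degenerate = TRUE))
  s2 <- mean((f - mu)^2)
  disp <- if (dispersion_as_variance) s2 else sqrt(s2)
  exp(-alpha * disp / abs(mu))
}

#' Delta/theta band weight of an IMF
#'
#' Fraction of the mode's Hilbert spectral energy (or, in time-proportion
#' mode, of its interior samples) whose instantaneous frequency falls inside
#' the union of the delta and theta bands.
#'
#' @param a An `analytic_imf`.
#' @param params An [ssrime_params] (bands and `weight_mode` are used).
#' @return W in [0, 1]; 0 with attribute `zero_energy = TRUE` for an
#'   energy-free mode.
#' @export
band_weight <- function(a, params = ssrime_params()) {
  stopifnot(inherits(a, "analytic_imf"))
  idx <- interior_index(a)
  if (!a$freq_defined || sum(a$amplitude[idx]^2) == 0)
    return(structure(0, zero_energy = TRUE))
  f <- a$inst_freq[idx]
  in_band <- (f >= params$delta_band[1] & f < params$delta_band[2]) |
    (f >= params$theta_band[1] & f < params$theta_band[2])
  if (params$weight_mode == "spectral_energy") {
    e <- a$amplitude[idx]^2
    sum(e[in_band]) / sum(e)
  } else {
    mean(in_band)
  }
}

#' Energy of one IMF
#'
#' Discrete integral of the squared mode (`raw_imf`) or squared analytic
#' amplitude (`analytic_amplitude`) over the interior samples, times the
#' sampling interval.
#'
#' @param x Numeric mode series or an `analytic_imf` (required for
#'   `analytic_amplitude`).
#' @param fs Sampling rate when `x` is a bare series.
#' @param energy_mode See [ssrime_params].
#' @param edge_trim Interior trim in samples when `x` is a bare series.
#' @return Non-negative energy (microvolt^2 x seconds).
#' @export
imf_energy <- function(x, fs = NULL,
                       energy_mode = c("raw_imf", "analytic_amplitude"),
                       edge_trim = NULL) {
  energy_mode <- match.arg(energy_mode)
  if (inherits(x, "analytic_imf")) {
    idx <- interior_index(x)
    v <- if (energy_mode == "raw_imf") Re(x$amplitude[idx] * cos(x$phase[idx]))
         else x$amplitude[idx]
    # for an analytic_imf in raw mode, reconstitute the real series
    return(sum(v^2) / x$fs)
  }
  x <- as.numeric(x)
  stopifnot(!is.null(fs), fs > 0)
  if (is.null(edge_trim)) edge_trim <- ceiling(0.05 * length(x))
  idx <- (edge_trim + 1L):(length(x) - edge_trim)
  sum(x[idx]^2) / fs
}

#' Relative (normalized) mode energies
#'
#' `Ebar_k = E_k / (sum(E) + epsilon)`; the epsilon keeps an all-zero energy
#' vector valid (it maps to all zeros) and the sum within `epsilon/sum(E)` of
#' one otherwise.
#'
#' @param energies Non-negative numeric vector.
#' @param epsilon Stability constant (default 1e-12).
#' @return Vector of the same length summing to at most 1.
#' @export
relative_energies <- function(energies, epsilon = 1e-12) {
  stopifnot(all(energies >= 0), epsilon > 0)
  energies / (sum(energies) + epsilon)
}

new_feature_vector <- function(values, method, channel_id = NA, epoch_id = NA,
                               per_imf_metadata = NULL, padded = FALSE) {
  structure(list(values = as.numeric(values), method = method,
                 channel_id = channel_id, epoch_id = epoch_id,
                 per_imf_metadata = per_imf_metadata, padded = padded),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s, K = %d%s\n", x$method, length(x$values),
              if (isTRUE(x$padded)) " (padded)" else ""))
  print(signif(x$values, 4))
  invisible(x)
}

# analytic transforms + per-mode statistics shared by ssrime/rime
mode_statistics <- function(imfset, params) {
  k <- nrow(imfset$imfs)
  if (k == 0)
    return(data.frame(median_freq = numeric(0), S = numeric(0),
                      W = numeric(0), E = numeric(0)))
  trim <- ceiling(params$edge_trim_frac * imfset$source_length)
  out <- lapply(seq_len(k), function(i) {
    m <- imfset$imfs[i, ]
    a <- analytic(m, imfset$fs, edge_trim = trim)
    mf <- tryCatch(median_frequency(a), ssrime_undefined_freq = function(e) NA_real_)
    e <- if (params$energy_mode == "raw_imf")
      imf_energy(m, imfset$fs, "raw_imf", edge_trim = trim)
    else sum(a$amplitude[interior_index(a)]^2) / imfset$fs
    data.frame(median_freq = mf,
               S = as.numeric(stabilization_factor(a, params$alpha,
                                                   params$dispersion_as_variance)),
               W = as.numeric(band_weight(a, params)),
               E = e)
  })
  do.call(rbind, out)
}

#' SS-RIME descriptor of one decomposition
#'
#' Full per-channel pipeline: analytic transform of every mode, stable
#' reordering by descending median instantaneous frequency, then per mode
#' the product of the stabilization factor S, the delta/theta band weight W
#' and the relative energy Ebar (components switchable for ablation), padded
#' or truncated to `params$K` values.
#'
#' @param imfset An `imf_set` from [emd] or [ceemdan].
#' @param params An [ssrime_params].
#' @return A `feature_vector` with `method = "ssrime"` and per-mode metadata
#'   (median frequency, S, W, Ebar, E) in the emitted order.
#' @export
ssrime_vector <- function(imfset, params = ssrime_params()) {
  stopifnot(inherits(imfset, "imf_set"))
  st <- mode_statistics(imfset, params)
  k <- nrow(st)
  if (k == 0)
    return(new_feature_vector(numeric(params$K), "ssrime", padded = TRUE))
  ord <- if (params$reorder) {
    key <- ifelse(is.na(st$median_freq), -Inf, st$median_freq)
    order(-key)                       # stable: ties keep extraction order
  } else seq_len(k)
  st <- st[ord, , drop = FALSE]
  keep <- seq_len(min(k, params$K))
  st <- st[keep, , drop = FALSE]
  ebar <- relative_energies(st$E, params$epsilon)
  vals <- if (params$include_normalization) ebar else st$E
  if (params$include_stabilization) vals <- vals * st$S
  if (params$include_weighting) vals <- vals * st$W
  st$Ebar <- ebar
  pad <- params$K - length(vals)
  if (pad > 0) {
    vals <- c(vals, numeric(pad))
    st[nrow(st) + seq_len(pad), ] <- 0
  }
  new_feature_vector(vals, "ssrime", per_imf_metadata = st, padded = pad > 0)
}

#' Relative intrinsic mode energy (RIME) baseline
#'
#' Mode energies in extraction order: no reordering, no stabilization, no
#' band weighting.  With `normalize = TRUE` (default) the energies are
#' divided by their total, the usual relative-energy baseline; with
#' `normalize = FALSE` the raw energies are returned, the fully ablated
#' reading in which RIME also lacks cross-mode normalization and is
#' therefore sensitive to global amplitude.
#'
#' @inheritParams ssrime_vector
#' @param normalize Divide by the total energy (default TRUE).
#' @return A `feature_vector` with `method = "rime"`.
#' @export
rime_vector <- function(imfset, params = ssrime_params(), normalize = TRUE) {
  stopifnot(inherits(imfset, "imf_set"))
  p <- params
  p$include_stabilization <- FALSE
  p$include_weighting <- FALSE
  p$include_normalization <- isTRUE(normalize)
  p$reorder <- FALSE
  out <- ssrime_vector(imfset, p)
  out$method <- "rime"
  out
}

# -- discrete wavelet transform (db4, periodic extension) --------------------

db4_lo <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

dwt_step <- function(x, lo, hi) {
  n <- length(x)
  idx <- outer(seq(1, n, by = 2), 0:(length(lo) - 1), "+")
  idx <- (idx - 1) %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xm %*% lo), detail = as.numeric(xm %*% hi))
}

dwt_energies <- function(x, n_levels) {
  lo <- db4_lo
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  a <- x
  e <- numeric(n_levels + 1)
  for (l in seq_len(n_levels)) {
    s <- dwt_step(a, lo, hi)
    e[l] <- sum(s$detail^2)
    a <- s$approx
  }
  e[n_levels + 1] <- sum(a^2)
  e
}

#' Relative wavelet energy (RWE) baseline
#'
#' Db4 discrete wavelet decomposition (Mallat pyramid, periodic extension);
#' per-subband energies (details level 1..n plus the final approximation)
#' normalized to sum to one.  The input is truncated to the largest multiple
#' of `2^n_levels` samples.
#'
#' @param x A [signal_epoch] or numeric vector.
#' @param fs Sampling rate (carried for labelling only).
#' @param n_levels Decomposition depth (default 5); requires at least
#'   `2^n_levels` samples.
#' @param epsilon Stability constant for the normalization.
#' @return A `feature_vector` with `method = "rwe"` and `n_levels + 1`
#'   values ordered from the finest detail band to the approximation.
#' @export
rwe_vector <- function(x, fs = NULL, n_levels = 5, epsilon = 1e-12) {
  xs <- as_samples(x)
  if (length(xs) < 2^n_levels)
    stop(sprintf("signal too short for %d wavelet levels: need >= %d samples",
                 n_levels, 2^n_levels))
  n <- 2^n_levels * (length(xs) %/% 2^n_levels)
  e <- dwt_energies(xs[seq_len(n)], n_levels)
  new_feature_vector(relative_energies(e, epsilon), "rwe")
}

# -- Welch PSD ---------------------------------------------------------------

# Hann-window Welch estimate with 50% overlap; returns density over [0, fs/2]
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, max(64, round(fs)))
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  u <- sum(w^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- (x[s:(s + nperseg - 1)] - mean(x[s:(s + nperseg - 1)])) * w
    p <- Mod(fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  if (nperseg %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(freq = seq(0, by = fs / nperseg, length.out = nf), psd = psd)
}

#' PSD band-power baseline
#'
#' Welch power spectral density (Hann windows, 50 percent overlap) integrated over
#' the canonical EEG bands.
#'
#' @param x A [signal_epoch] or numeric vector.
#' @param fs Sampling rate in Hz.
#' @param bands Named list of `c(lo, hi)` band edges, see [eeg_bands].
#' @param relative Normalize the band powers to sum to one (default TRUE).
#' @param nperseg Welch segment length in samples (default about one second).
#' @return A `feature_vector` with `method = "psd"`, one value per band.
#' @export
psd_bandpower_vector <- function(x, fs = NULL, bands = eeg_bands(),
                                 relative = TRUE, nperseg = NULL) {
  xs <- as_samples(x)
  fs <- epoch_fs(x, fs)
  if (length(xs) < 64) stop("signal too short for a Welch estimate (need >= 64 samples)")
  est <- welch_psd(xs, fs, nperseg)
  df <- est$freq[2] - est$freq[1]
  p <- vapply(bands, function(b) {
    sel <- est$freq >= b[1] & est$freq < min(b[2], fs / 2)
    sum(est$psd[sel]) * df
  }, numeric(1))
  if (relative) p <- relative_energies(p)
  out <- new_feature_vector(p, "psd")
  out$band_names <- names(bands)
  out
}

# -- epoch-level feature extraction ------------------------------------------

#' Extract a feature matrix from epoched EEG
#'
#' Applies the selected per-channel descriptor to every epoch and channel
#' and concatenates the per-channel vectors in fixed channel order, giving
#' one row of `K * n_channels` features per epoch (column names
#' `<channel>.IMF<k>` or band labels for `psd`).
#'
#' Decomposition noise is seeded per (epoch, channel) from `seed`, so the
#' matrix is reproducible end to end.
#'
#' @param eeg An `epoched_eeg` (see [generate_dataset] / [read_epochs]).
#' @param method One of `"ssrime"`, `"rime"`, `"rwe"`, `"psd"`.
#' @param params An [ssrime_params] (used by `ssrime`/`rime`).
#' @param cparams A [ceemdan_params] for the decomposition; its `seed` field
#'   is ignored in favour of `seed`.
#' @param seed Integer base seed for the ensemble noise.
#' @param decompositions Optional list of pre-computed `imf_set`s indexed
#'   `[[epoch]][[channel]]` (as from [decompose_epochs]), to reuse one
#'   decomposition across several feature variants.
#' @param n_levels,bands Passed to the `rwe` / `psd` baselines.
#' @param rime_normalize Passed to [rime_vector] for `method = "rime"`.
#' @return Numeric matrix (epochs x features) of class `ssrime_features`
#'   with attributes `labels`, `subject_id`, `channel_names`, `method`,
#'   `params`.
#' @export
extract_features <- function(eeg, method = c("ssrime", "rime", "rwe", "psd"),
                             params = ssrime_params(),
                             cparams = ceemdan_params(), seed = 1,
                             decompositions = NULL, n_levels = 5,
                             bands = eeg_bands(), rime_normalize = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(eeg, "epoched_eeg"))
  ne <- dim(eeg$data)[1]
  nc <- dim(eeg$data)[2]
  if (method %in% c("ssrime", "rime") && is.null(decompositions))
    decompositions <- decompose_epochs(eeg, cparams, seed)
  rows <- lapply(seq_len(ne), function(i) {
    unlist(lapply(seq_len(nc), function(j) {
      switch(method,
        ssrime = ssrime_vector(decompositions[[i]][[j]], params)$values,
        rime = {
          v <- rime_vector(decompositions[[i]][[j]], params,
                           normalize = rime_normalize)$values
          length(v) <- params$K
          v[is.na(v)] <- 0
          v
        },
        rwe = rwe_vector(eeg$data[i, j, ], eeg$fs, n_levels)$values,
        psd = psd_bandpower_vector(eeg$data[i, j, ], eeg$fs, bands)$values)
    }))
  })
  m <- do.call(rbind, rows)
  per <- ncol(m) / nc
  feat_lab <- if (method == "psd") names(bands)[seq_len(per)]
    else if (method == "rwe") c(paste0("D", seq_len(per - 1)), "A")
    else paste0("IMF", seq_len(per))
  colnames(m) <- as.vector(outer(feat_lab, eeg$channel_names,
                                 function(f, c) paste(c, f, sep = ".")))
  structure(m, labels = eeg$labels, subject_id = eeg$subject_id,
            channel_names = eeg$channel_names, method = method,
            params = if (method %in% c("ssrime", "rime")) unclass(params),
            class = c("ssrime_features", "matrix", "array"))
}

#' Decompose every epoch and channel once
#'
#' @inheritParams extract_features
#' @return Nested list of `imf_set`s indexed `[[epoch]][[channel]]`.
#' @export
decompose_epochs <- function(eeg, cparams = ceemdan_params(), seed = 1) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  ne <- dim(eeg$data)[1]
  nc <- dim(eeg$data)[2]
  lapply(seq_len(ne), function(i) {
    lapply(seq_len(nc), function(j) {
      cp <- cparams
      cp$seed <- derive_seed(seed, (i - 1) * nc + j)
      ceemdan(eeg$data[i, j, ], eeg$fs, cp)
    })
  })
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated matrix with a header row of channel/feature labels and
#' leading `epoch_id`, `subject_id`, `label` columns; a JSON sidecar stores
#' the method and parameters.  The round trip is bit-exact.
#'
#' @param features An `ssrime_features` matrix.
#' @param path Output TSV path.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "ssrime_features"))
  n <- nrow(features)
  lab <- attr(features, "labels")
  subj <- attr(features, "subject_id")
  df <- data.frame(epoch_id = seq_len(n),
                   subject_id = if (is.null(subj)) rep(NA, n) else subj,
                   label = as.character(lab))
  vals <- apply(features, 2, function(col) sprintf("%.17g", col))
  if (n == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, colnames(features)))
  write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(method = attr(features, "method"),
                            channel_names = attr(features, "channel_names"),
                            params = attr(features, "params")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  structure(m, labels = factor(df$label),
            subject_id = if (all(df$subject_id == "NA")) NULL
                         else as.integer(df$subject_id),
            channel_names = meta$channel_names, method = meta$method,
            params = meta$params,
            class = c("ssrime_features", "matrix", "array"))
}
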