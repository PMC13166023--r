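#' Configuration of the synthetic workload-EEG generator
#'
#' Describes a multichannel N-back-style dataset: narrowband delta, theta,
#' alpha and beta oscillators with random phase, mild frequency jitter and
#' slow burst envelopes, superimposed on 1/f^beta background noise.  Working
#' memory load is emulated by scaling frontal theta amplitude up and
#' posterior alpha amplitude down across conditions; a per-subject
#' multiplicative amplitude factor emulates inter-subject gain variability.
#'
#' @param n_channels Number of channels (default 8; a 64-channel layout is
#'   supported by passing `n_channels = 64`).
#' @param fs Sampling rate in Hz (default 1000).
#' @param epoch_seconds Epoch duration in seconds (default 3);
#'   `fs * epoch_seconds` must be at least 512.
#' @param n_epochs_per_condition Epochs generated per condition.
#' @param conditions Ordered condition labels.
#' @param theta_gain,alpha_gain Per-condition multipliers applied to the
#'   frontal theta and posterior alpha oscillators; one value per condition.
#' @param delta_amp,theta_amp,alpha_amp,beta_amp Base oscillator amplitudes
#'   in microvolts.
#' @param noise_amp Standard deviation of the 1/f background in microvolts.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1, typical of resting EEG).
#' @param subject_scale_sd Log-normal sigma of the per-subject global
#'   amplitude factor (default 0.2).
#' @param n_subjects Number of simulated subjects; epochs are assigned
#'   cyclically.
#' @param frontal_channels,posterior_channels Channel indices carrying the
#'   theta and alpha condition effects.
#' @param channel_names Channel labels; defaults to an 8-channel 10-20-style
#'   montage or `Ch1..ChN` otherwise.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8, fs = 1000, epoch_seconds = 3,
                         n_epochs_per_condition = 50,
                         conditions = c("0-back", "2-back", "3-back"),
                         theta_gain = c(1, 1.5, 2),
                         alpha_gain = c(1, 0.8, 0.65),
                         delta_amp = 6, theta_amp = 8, alpha_amp = 10,
                         beta_amp = 3, noise_amp = 8, noise_exponent = 1,
                         subject_scale_sd = 0.2, n_subjects = 10,
                         frontal_channels = NULL, posterior_channels = NULL,
                         channel_names = NULL, seed = 1) {
  n_channels <- as.integer(n_channels)
  if (is.null(channel_names))
    channel_names <- if (n_channels == 8)
      c("Fz", "FCz", "Cz", "C3", "C4", "Pz", "O1", "O2")
    else paste0("Ch", seq_len(n_channels))
  if (is.null(frontal_channels))
    frontal_channels <- seq_len(min(3L, n_channels))
  if (is.null(posterior_channels))
    posterior_channels <- seq.int(max(1L, n_channels - 2L), n_channels)
  cfg <- list(n_channels = n_channels, fs = as.numeric(fs),
              epoch_seconds = as.numeric(epoch_seconds),
              n_epochs_per_condition = as.integer(n_epochs_per_condition),
              conditions = as.character(conditions),
              theta_gain = as.numeric(theta_gain),
              alpha_gain = as.numeric(alpha_gain),
              delta_amp = as.numeric(delta_amp),
              theta_amp = as.numeric(theta_amp),
              alpha_amp = as.numeric(alpha_amp),
              beta_amp = as.numeric(beta_amp),
              noise_amp = as.numeric(noise_amp),
              noise_exponent = as.numeric(noise_exponent),
              subject_scale_sd = as.numeric(subject_scale_sd),
              n_subjects = as.integer(n_subjects),
              frontal_channels = as.integer(frontal_channels),
              posterior_channels = as.integer(posterior_channels),
              channel_names = as.character(channel_names),
              seed = as.integer(seed))
  stopifnot(cfg$n_channels >= 1, cfg$fs > 0,
            cfg$fs * cfg$epoch_seconds >= 512,
            length(cfg$theta_gain) == length(cfg$conditions),
            length(cfg$alpha_gain) == length(cfg$conditions),
            all(cfg$theta_gain > 0), all(cfg$alpha_gain > 0),
            cfg$delta_amp >= 0, cfg$noise_amp >= 0,
            cfg$subject_scale_sd >= 0, cfg$n_subjects >= 1,
            length(cfg$channel_names) == cfg$n_channels,
            all(cfg$frontal_channels >= 1 & cfg$frontal_channels <= cfg$n_channels),
            all(cfg$posterior_channels >= 1 & cfg$posterior_channels <= cfg$n_channels))
  class(cfg) <- "synth_config"
  cfg
}

# slow burst envelope: small baseline plus 2-4 Hann bursts of 0.5-1.5 s,
# normalized to unit RMS so the oscillator amplitude is interpretable
burst_envelope <- function(n, fs) {
  env <- rep(0.4, n)
  for (b in seq_len(sample(2:4, 1))) {
    len <- round(runif(1, 0.5, 1.5) * fs)
    len <- min(len, n)
    start <- sample.int(max(1, n - len + 1), 1)
    h <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
    env[start:(start + len - 1)] <- env[start:(start + len - 1)] + h
  }
  env / sqrt(mean(env^2))
}

# narrowband oscillator: random-phase sinusoid with +-0.5 Hz frequency
# jitter under a slow burst envelope; RMS-normalized then scaled
narrowband_osc <- function(n, fs, f0, amp) {
  f <- f0 + runif(1, -0.5, 0.5)
  ph <- runif(1, 0, 2 * pi)
  t <- seq(0, by = 1 / fs, length.out = n)
  s <- sin(2 * pi * f * t + ph) * burst_envelope(n, fs)
  amp * s / sqrt(2)          # amp is the nominal sinusoid amplitude
}

# 1/f^beta noise via spectral shaping of white noise, scaled to sd `amp`
pink_noise <- function(n, beta, amp) {
  if (amp == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  W <- W * f^(-beta / 2)
  x <- Re(fft(W, inverse = TRUE) / n)
  amp * (x - mean(x)) / sd(x)
}

#' Generate one synthetic EEG epoch
#'
#' Draws a channels x samples matrix for one condition using the current RNG
#' state; consumed by [generate_dataset], exported for targeted tests.
#'
#' @param condition Condition label, one of `config$conditions`.
#' @param subject_factor Multiplicative per-subject amplitude factor.
#' @param config A [synth_config].
#' @return Numeric matrix `n_channels x (fs * epoch_seconds)` in microvolts.
#' @export
generate_epoch <- function(condition, subject_factor, config) {
  ci <- match(condition, config$conditions)
  if (is.na(ci)) stop("unknown condition label: ", condition)
  n <- round(config$fs * config$epoch_seconds)
  out <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    th <- config$theta_amp *
      (if (ch %in% config$frontal_channels) config$theta_gain[ci] else 1)
    al <- config$alpha_amp *
      (if (ch %in% config$posterior_channels) config$alpha_gain[ci] else 1)
    x <- narrowband_osc(n, config$fs, 2, config$delta_amp) +
      narrowband_osc(n, config$fs, 6, th) +
      narrowband_osc(n, config$fs, 10, al) +
      narrowband_osc(n, config$fs, 20, config$beta_amp) +
      pink_noise(n, config$noise_exponent, config$noise_amp)
    out[ch, ] <- subject_factor * x
  }
  out
}

#' Generate a labelled synthetic EEG dataset
#'
#' Deterministic per seed: per-subject amplitude factors are drawn first,
#' then epochs condition by condition with subjects assigned cyclically.
#'
#' @param config A [synth_config].
#' @return An object of class `epoched_eeg`: list with `data` (epochs x
#'   channels x samples array), `fs`, `labels` (factor), `subject_id`
#'   (integer), `channel_names`.
#' @examples
#' eeg <- generate_dataset(synth_config(fs = 250, n_epochs_per_condition = 2,
#'                                      n_subjects = 2))
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    sf <- exp(rnorm(config$n_subjects, 0, config$subject_scale_sd))
    n <- round(config$fs * config$epoch_seconds)
    ncond <- length(config$conditions)
    ne <- ncond * config$n_epochs_per_condition
    data <- array(0, c(ne, config$n_channels, n))
    labels <- character(ne)
    subject <- integer(ne)
    i <- 0
    for (ci in seq_len(ncond)) {
      for (ep in seq_len(config$n_epochs_per_condition)) {
        i <- i + 1
        subject[i] <- ((ep - 1) %% config$n_subjects) + 1L
        labels[i] <- config$conditions[ci]
        data[i, , ] <- generate_epoch(config$conditions[ci],
                                      sf[subject[i]], config)
      }
    }
    structure(list(data = data, fs = config$fs,
                   labels = factor(labels, levels = config$conditions),
                   subject_id = as.integer(subject),
                   channel_names = config$channel_names),
              class = "epoched_eeg")
  })
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  print(table(x$labels))
  invisible(x)
}
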