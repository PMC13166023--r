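# deterministic signal fixtures shared across test files

tone <- function(f, dur = 3, fs = 250, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

# 25 Hz + 3 Hz two-tone used throughout the decomposition tests
two_tone <- function(dur = 4, fs = 500, a1 = 1, a2 = 2, f1 = 25, f2 = 3) {
  tone(f1, dur, fs, a1) + tone(f2, dur, fs, a2)
}

# interior index set: drop `frac` of samples at each end
interior <- function(n, frac = 0.1) {
  k <- ceiling(frac * n)
  (k + 1):(n - k)
}

fast_cparams <- function(seed = 1, n_realizations = 20) {
  ceemdan_params(n_realizations = n_realizations, seed = seed)
}

# small synthetic dataset at desk scale (250 Hz keeps CEEMDAN cheap)
small_synth <- function(..., fs = 250, n_subjects = 5, seed = 1) {
  synth_config(..., fs = fs, n_subjects = n_subjects, seed = seed)
}

# Welch band power of one channel (absolute units)
band_power <- function(x, fs, band) {
  v <- psd_bandpower_vector(x, fs, bands = list(b = band), relative = FALSE)
  v$values
}

with_seed_helper <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# manual analytic_imf fixture with a prescribed instantaneous-frequency
# series (edge_trim 0 so the statistics see exactly these samples)
analytic_fixture <- function(inst_freq, fs = 250, amplitude = NULL) {
  n <- length(inst_freq)
  structure(list(amplitude = if (is.null(amplitude)) rep(1, n) else amplitude,
                 phase = cumsum(2 * pi * inst_freq / fs),
                 inst_freq = inst_freq, fs = fs, edge_trim = 0L,
                 freq_defined = TRUE),
            class = "analytic_imf")
}
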