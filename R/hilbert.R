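# FFT-based analytic signal: positive frequencies doubled, DC (and Nyquist
# for even N) kept, negative frequencies zeroed.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  d <- diff(p)
  adj <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], adj))
}

#' Analytic representation of an IMF
#'
#' Builds the Hilbert analytic signal of a (near-)monocomponent series and
#' derives instantaneous amplitude, unwrapped phase and instantaneous
#' frequency.  A fraction of samples at each end is marked as edge trim and
#' excluded from all downstream statistics, since Hilbert end effects corrupt
#' the first and last few cycles.
#'
#' @param x Numeric series (one IMF), length at least 8, all finite.
#' @param fs Sampling rate in Hz.
#' @param edge_trim Samples to exclude at each end for statistics; default
#'   5 percent of the length (rounded up).
#' @return Object of class `analytic_imf` with fields `amplitude`, `phase`
#'   (unwrapped radians), `inst_freq` (Hz), `fs`, `edge_trim`, and
#'   `freq_defined` (FALSE for an all-zero input, whose instantaneous
#'   frequency is undefined).
#' @examples
#' a <- analytic(cos(2 * pi * 10 * seq(0, 3, by = 1 / 250)), fs = 250)
#' median_frequency(a)
#' @export
analytic <- function(x, fs, edge_trim = NULL) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 8, all(is.finite(x)), fs > 0)
  if (is.null(edge_trim)) edge_trim <- ceiling(0.05 * length(x))
  z <- analytic_signal(x)
  amp <- Mod(z)
  defined <- any(amp > 0)
  phase <- if (defined) unwrap_phase(Arg(z)) else numeric(length(x))
  f <- if (defined) inst_frequency(phase, fs) else rep(NA_real_, length(x))
  structure(list(amplitude = amp, phase = phase, inst_freq = f, fs = fs,
                 edge_trim = as.integer(edge_trim), freq_defined = defined),
            class = "analytic_imf")
}

#' @export
print.analytic_imf <- function(x, ...) {
  cat(sprintf("<analytic_imf> %d samples @ %g Hz, edge_trim = %d%s\n",
              length(x$amplitude), x$fs, x$edge_trim,
              if (!x$freq_defined) " (inst. frequency undefined)" else ""))
  invisible(x)
}

#' Instantaneous frequency from unwrapped phase
#'
#' Central-difference derivative of the unwrapped phase divided by 2*pi
#' (one-sided differences at the ends).  Negative values are preserved: they
#' arise when an IMF is noise-contaminated or multicomponent, and they feed
#' the dispersion penalty as intended.
#'
#' @param phase Unwrapped phase in radians.
#' @param fs Sampling rate in Hz.
#' @param method Only `"central"` is implemented.
#' @return Hz series of the same length.
#' @export
inst_frequency <- function(phase, fs, method = "central") {
  method <- match.arg(method, "central")
  n <- length(phase)
  f <- numeric(n)
  if (n >= 3)
    f[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) * fs / (4 * pi)
  f[1] <- (phase[2] - phase[1]) * fs / (2 * pi)
  f[n] <- (phase[n] - phase[n - 1]) * fs / (2 * pi)
  f
}

interior_index <- function(a) {
  n <- length(a$amplitude)
  lo <- a$edge_trim + 1L
  hi <- n - a$edge_trim
  if (lo > hi) stop("edge trim leaves no interior samples")
  lo:hi
}

#' Median instantaneous frequency of an IMF
#'
#' Median of the instantaneous frequency over the interior (non-trimmed)
#' samples; this is the statistic used to rank modes into a stable
#' high-to-low frequency order.
#'
#' @param a An `analytic_imf`.
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(a) {
  stopifnot(inherits(a, "analytic_imf"))
  if (!a$freq_defined)
    stop(structure(class = c("ssrime_undefined_freq", "error", "condition"),
                   list(message = "cannot rank zero-energy IMF: instantaneous frequency undefined",
                        call = sys.call())))
  median(a$inst_freq[interior_index(a)])
}

#' Hilbert spectrum on a time-frequency grid
#'
#' Each interior sample deposits its squared instantaneous amplitude into the
#' cell containing its (instantaneous frequency, time) pair.  Samples whose
#' frequency (or time) falls outside the grid are accumulated in `overflow`,
#' so total energy is conserved exactly.
#'
#' @param analytics An `analytic_imf` or a list of them (aggregated grid).
#' @param freq_edges,time_edges Strictly increasing bin edges (Hz, seconds);
#'   bins are half-open `[lo, hi)`.
#' @return Object of class `hilbert_spectrum` with fields `energy`
#'   (frequency x time matrix), `freq_edges`, `time_edges`, `overflow`,
#'   `aggregated`.
#' @export
hilbert_spectrum <- function(analytics, freq_edges = seq(0, 45, by = 0.5),
                             time_edges = NULL) {
  if (inherits(analytics, "analytic_imf")) analytics <- list(analytics)
  stopifnot(length(analytics) == 0 ||
              all(vapply(analytics, inherits, TRUE, "analytic_imf")))
  if (any(diff(freq_edges) <= 0)) stop("freq_edges must be strictly increasing")
  if (is.null(time_edges)) {
    dur <- if (length(analytics))
      length(analytics[[1]]$amplitude) / analytics[[1]]$fs else 1
    time_edges <- seq(0, dur, by = 0.05)
    if (time_edges[length(time_edges)] < dur)
      time_edges <- c(time_edges, dur + 1e-9)
  }
  if (any(diff(time_edges) <= 0)) stop("time_edges must be strictly increasing")
  nf <- length(freq_edges) - 1L
  nt <- length(time_edges) - 1L
  grid <- matrix(0, nf, nt)
  overflow <- 0
  for (a in analytics) {
    idx <- interior_index(a)
    if (!a$freq_defined) next
    tt <- (idx - 1) / a$fs
    fb <- findInterval(a$inst_freq[idx], freq_edges, left.open = FALSE)
    tb <- findInterval(tt, time_edges, left.open = FALSE)
    e <- a$amplitude[idx]^2
    inside <- fb >= 1 & fb <= nf & tb >= 1 & tb <= nt &
      a$inst_freq[idx] < freq_edges[nf + 1] & tt < time_edges[nt + 1]
    overflow <- overflow + sum(e[!inside])
    if (any(inside)) {
      cells <- (tb[inside] - 1L) * nf + fb[inside]
      acc <- tapply(e[inside], cells, sum)
      grid[as.integer(names(acc))] <- grid[as.integer(names(acc))] + acc
    }
  }
  structure(list(energy = grid, freq_edges = freq_edges,
                 time_edges = time_edges, overflow = overflow,
                 aggregated = length(analytics) > 1),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d freq x %d time bins, energy = %.4g (+%.3g overflow)\n",
              nrow(x$energy), ncol(x$energy), sum(x$energy), x$overflow))
  invisible(x)
}

#' Write / read a Hilbert spectrum as plain text
#'
#' Dense numeric matrix (rows = frequency bins) with a JSON sidecar holding
#' the bin edges and overflow energy.
#' @param spec A `hilbert_spectrum`.
#' @param path Output file for the matrix.
#' @export
write_hilbert_spectrum <- function(spec, path) {
  write_num_matrix(spec$energy, path)
  jsonlite::write_json(list(freq_edges = spec$freq_edges,
                            time_edges = spec$time_edges,
                            overflow = spec$overflow,
                            aggregated = spec$aggregated),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hilbert_spectrum
#' @export
read_hilbert_spectrum <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(energy = read_num_matrix(path),
                 freq_edges = as.numeric(meta$freq_edges),
                 time_edges = as.numeric(meta$time_edges),
                 overflow = as.numeric(meta$overflow),
                 aggregated = isTRUE(meta$aggregated)),
            class = "hilbert_spectrum")
}

#' Hilbert spectral energy in a frequency band
#'
#' Sum of squared instantaneous amplitude over interior samples whose
#' instantaneous frequency lies in `[lo, hi)`.  Summing over disjoint bands
#' covering the whole real line reproduces the total interior energy exactly.
#'
#' @param a An `analytic_imf`.
#' @param band Numeric `c(lo, hi)` in Hz, `lo < hi`.
#' @return Energy (microvolt^2 x samples).
#' @export
band_energy <- function(a, band) {
  stopifnot(inherits(a, "analytic_imf"), length(band) == 2)
  if (band[1] >= band[2]) stop("band must satisfy lo < hi")
  idx <- interior_index(a)
  if (!a$freq_defined) return(0)
  f <- a$inst_freq[idx]
  sum(a$amplitude[idx][f >= band[1] & f < band[2]]^2)
}
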