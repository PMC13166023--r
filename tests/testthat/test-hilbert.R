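test_that("analytic signal of a tone recovers amplitude and frequency", {
  for (f0 in c(2, 6, 10, 20)) {
    a <- analytic(cos(2 * pi * f0 * seq(0, 3 - 1 / 250, by = 1 / 250)), 250)
    ii <- interior(length(a$amplitude), 0.05)
    expect_lt(max(abs(a$amplitude[ii] - 1)), 0.01)
    fint <- a$inst_freq[ii]
    expect_lt(abs(mean(fint) - f0) / f0, 0.02)
    expect_lt(sd(fint) / mean(fint), 0.05)
  }
  expect_lt(abs(median_frequency(analytic(tone(10), 250)) - 10), 0.2)
})

test_that("a linear chirp's instantaneous frequency tracks the true law", {
  fs <- 250
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  f_true <- 5 + (10 - 5) / 4 * t
  x <- cos(2 * pi * (5 * t + (10 - 5) / (2 * 4) * t^2))
  a <- analytic(x, fs)
  ii <- interior(length(x), 0.05)
  expect_lt(sqrt(mean((a$inst_freq[ii] - f_true[ii])^2)), 0.3)
  expect_lt(abs(a$inst_freq[ii[1]] - f_true[ii[1]]), 0.5)
  expect_lt(abs(a$inst_freq[ii[length(ii)]] - f_true[ii[length(ii)]]), 0.5)
  # median of a linear ramp is its midpoint
  expect_lt(abs(median_frequency(a) - 7.5), 0.2)
  # mostly monotone increasing away from the ends
  expect_gt(mean(diff(a$inst_freq[ii]) > -0.01), 0.95)
})

test_that("zero input flags undefined instantaneous frequency", {
  a <- analytic(numeric(600), 250)
  expect_false(a$freq_defined)
  expect_true(all(a$amplitude == 0))
  expect_error(median_frequency(a), class = "ssrime_undefined_freq")
})

test_that("instantaneous frequency differentiation is local and signed", {
  fs <- 100
  ph <- 2 * pi * 10 * seq(0, 2 - 1 / fs, by = 1 / fs)
  expect_equal(inst_frequency(ph, fs), rep(10, length(ph)), tolerance = 1e-9)

  # a single corrupted phase sample only touches the difference stencil
  ph2 <- ph
  ph2[100] <- ph2[100] + 1
  f2 <- inst_frequency(ph2, fs)
  f1 <- inst_frequency(ph, fs)
  expect_identical(which(abs(f2 - f1) > 1e-12), c(99L, 101L))

  # reversed-phase segment yields preserved negative values
  ph3 <- c(seq(0, 10, length.out = 100), seq(10, 5, length.out = 50))
  expect_lt(min(inst_frequency(ph3, fs)), 0)

  # outlier robustness of the median statistic
  a <- analytic_fixture(c(4, 6, 100))
  expect_identical(median_frequency(a), 6)
})

test_that("the Hilbert spectrum concentrates tone energy and conserves total", {
  a <- analytic(tone(10), 250)
  spec <- hilbert_spectrum(a, freq_edges = seq(0, 45, by = 1))
  row10 <- which(spec$freq_edges == 9)     # bin [9, 10) + [10, 11) around f0
  e_near <- sum(spec$energy[row10 + 0:1, ])
  expect_gt(e_near / sum(spec$energy), 0.95)
  interior_total <- sum(a$amplitude[(a$edge_trim + 1):(length(a$amplitude) - a$edge_trim)]^2)
  expect_equal(sum(spec$energy) + spec$overflow, interior_total, tolerance = 1e-12)

  expect_identical(sum(hilbert_spectrum(list())$energy), 0)
  expect_error(hilbert_spectrum(a, freq_edges = c(1, 1, 2)), "increasing")
})

test_that("band energies are additive over disjoint bands and complete", {
  a <- analytic(tone(6), 250)
  total <- band_energy(a, c(-1e9, 1e9))
  expect_gt(band_energy(a, c(4, 7.5)) / total, 0.95)
  expect_lt(band_energy(a, c(13, 30)) / total, 0.05)
  parts <- band_energy(a, c(-1e9, 4)) + band_energy(a, c(4, 7.5)) +
    band_energy(a, c(7.5, 1e9))
  expect_identical(parts, total)
  expect_error(band_energy(a, c(7, 4)), "lo < hi")
  expect_identical(band_energy(analytic(numeric(600), 250), c(4, 7.5)), 0)
})

test_that("Hilbert spectra round-trip through the matrix + sidecar format", {
  spec <- hilbert_spectrum(analytic(tone(10), 250),
                           freq_edges = seq(0, 45, by = 0.5))
  path <- file.path(withr::local_tempdir(), "spec.csv")
  write_hilbert_spectrum(spec, path)
  spec2 <- read_hilbert_spectrum(path)
  expect_identical(spec2$energy, spec$energy)
  expect_identical(spec2$freq_edges, spec$freq_edges)
  expect_identical(spec2$overflow, spec$overflow)
})
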