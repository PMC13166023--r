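test_that("stabilization factor matches its closed form and monotonicity", {
  # interior mean 10 Hz, population sd 2 Hz
  a <- analytic_fixture(rep(c(8, 12), 50))
  expect_equal(stabilization_factor(a, alpha = 1), exp(-0.2),
               tolerance = 1e-13)
  # value frozen from an independent evaluation of exp(-1/5)
  expect_equal(stabilization_factor(a, alpha = 1), 0.818730753077982,
               tolerance = 1e-12)

  expect_identical(stabilization_factor(analytic_fixture(rep(10, 100))), 1)
  expect_identical(stabilization_factor(a, alpha = 0), 1)

  # strictly decreasing in alpha and in sigma/mu
  alphas <- c(0.25, 0.5, 1, 2, 4)
  s_alpha <- vapply(alphas, function(al) stabilization_factor(a, al), 0)
  expect_true(all(diff(s_alpha) < 0))
  sigmas <- c(0.5, 1, 2, 4)
  s_disp <- vapply(sigmas, function(sg)
    stabilization_factor(analytic_fixture(rep(c(10 - sg, 10 + sg), 50))), 0)
  expect_true(all(diff(s_disp) < 0))

  # degenerate mean frequency is maximally penalized
  s0 <- stabilization_factor(analytic_fixture(rep(c(-5, 5), 50)))
  expect_identical(as.numeric(s0), 0)
  expect_true(attr(s0, "degenerate"))

  # variance reading of the dispersion is selectable
  expect_equal(stabilization_factor(a, 1, dispersion_as_variance = TRUE),
               exp(-4 / 10), tolerance = 1e-13)
})

test_that("band weight isolates delta/theta content in both modes", {
  p_e <- ssrime_params(weight_mode = "spectral_energy")
  p_t <- ssrime_params(weight_mode = "time_proportion")
  a6 <- analytic(tone(6), 250)
  a20 <- analytic(tone(20), 250)
  for (p in list(p_e, p_t)) {
    expect_gte(band_weight(a6, p), 0.95)
    expect_lte(band_weight(a20, p), 0.05)
  }
  w0 <- band_weight(analytic(numeric(600), 250))
  expect_identical(as.numeric(w0), 0)
  expect_true(attr(w0, "zero_energy"))

  # spectral-energy weights add over disjoint sub-bands
  x <- tone(3) + tone(6)
  a <- analytic(x, 250)
  both <- band_energy(a, c(1, 4)) + band_energy(a, c(4, 7.5))
  expect_identical(both, band_energy(a, c(1, 7.5)))
})

test_that("mode energy matches the amplitude/raw relationship for a tone", {
  x <- tone(10, fs = 250)
  n_int <- length(x) - 2 * ceiling(0.05 * length(x))
  e_an <- imf_energy(analytic(x, 250), energy_mode = "analytic_amplitude")
  e_raw <- imf_energy(x, 250, "raw_imf")
  expect_equal(e_an, n_int / 250, tolerance = 0.01)
  expect_equal(e_raw / e_an, 0.5, tolerance = 0.02)
  expect_identical(imf_energy(numeric(600), 250), 0)
})

test_that("relative energies normalize as stated", {
  expect_equal(relative_energies(c(2, 2)), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(relative_energies(c(1, 3)), c(0.25, 0.75), tolerance = 1e-12)
  expect_identical(relative_energies(c(0, 0, 0)), c(0, 0, 0))
})

test_that("the SS-RIME descriptor reorders, weights and normalizes modes", {
  x <- tone(6, 3, 250) + tone(20, 3, 250)
  d <- ceemdan(x, 250, fast_cparams(seed = 11))
  p <- ssrime_params(K = 8)
  fv <- ssrime_vector(d, p)
  md <- fv$per_imf_metadata

  expect_length(fv$values, 8)
  expect_true(all(fv$values >= 0))
  # reordered: median frequencies non-increasing
  expect_true(all(diff(md$median_freq[md$median_freq != 0]) <= 1e-9))
  # SS-RIME_k <= Ebar_k element-wise since S, W <= 1
  expect_true(all(fv$values <= md$Ebar + 1e-15))

  # the theta-dominant mode dwarfs the beta mode after weighting
  k_theta <- which.min(abs(md$median_freq - 6))
  k_beta <- which.min(abs(md$median_freq - 20))
  expect_gt(fv$values[k_theta], 5 * fv$values[k_beta])

  # toggles off -> the RIME quantity after reordering
  p_off <- ssrime_params(K = 8, include_stabilization = FALSE,
                         include_weighting = FALSE)
  expect_equal(ssrime_vector(d, p_off)$values, md$Ebar, tolerance = 1e-12)

  # output is invariant to the storage order of the modes
  perm <- rev(seq_len(nrow(d$imfs)))
  d_perm <- d
  d_perm$imfs <- d$imfs[perm, , drop = FALSE]
  expect_equal(ssrime_vector(d_perm, p)$values, fv$values, tolerance = 1e-12)
})

test_that("all descriptor families are invariant to global amplitude", {
  x <- tone(6, 3, 250) + tone(20, 3, 250) + with_seed_helper(4, rnorm(750, 0, 0.5))
  p <- ssrime_params()
  base <- list(ssrime = ssrime_vector(ceemdan(x, 250, fast_cparams(5)), p)$values,
               rime = rime_vector(ceemdan(x, 250, fast_cparams(5)))$values,
               rwe = rwe_vector(x, 250)$values,
               psd = psd_bandpower_vector(x, 250)$values)
  for (c in c(0.1, 10)) {
    scaled <- list(ssrime = ssrime_vector(ceemdan(c * x, 250, fast_cparams(5)), p)$values,
                   rime = rime_vector(ceemdan(c * x, 250, fast_cparams(5)))$values,
                   rwe = rwe_vector(c * x, 250)$values,
                   psd = psd_bandpower_vector(c * x, 250)$values)
    for (m in names(base))
      expect_equal(scaled[[m]], base[[m]], tolerance = 1e-6, label = m)
  }
})

test_that("RIME is the unordered relative-energy special case", {
  d <- ceemdan(two_tone(3, 250), 250, fast_cparams(seed = 9))
  rv <- rime_vector(d)
  expect_equal(sum(rv$values), 1, tolerance = 1e-9)
  p_plain <- ssrime_params(include_stabilization = FALSE,
                           include_weighting = FALSE, reorder = FALSE)
  expect_identical(rv$values, ssrime_vector(d, p_plain)$values)

  single <- emd(tone(10, 2, 250), 250, ceemdan_params(max_imfs = 1))
  expect_equal(rime_vector(single)$values[1], 1, tolerance = 1e-9)

  # the fully ablated reading returns raw, unnormalized energies
  raw <- rime_vector(d, normalize = FALSE)$values
  expect_equal(raw / sum(raw), rv$values, tolerance = 1e-9)
  expect_gt(sum(raw), 1.5)   # microvolt^2-scale energies, not proportions
})

test_that("relative wavelet energy reflects subband bandwidth on white noise", {
  e <- rowMeans(vapply(1:20, function(s)
    rwe_vector(with_seed_helper(s, rnorm(1024)), 256)$values, numeric(6)))
  expected <- c(2^-(1:5), 2^-5)          # details 1..5 then approximation
  expect_true(all(abs(e - expected) / expected < 0.3))

  v <- rwe_vector(with_seed_helper(1, rnorm(512)), 256)
  expect_equal(sum(v$values), 1, tolerance = 1e-9)
  expect_identical(rwe_vector(numeric(512), 256)$values, numeric(6))
  expect_error(rwe_vector(rnorm(16), 256), "too short")
})

test_that("Welch band powers localize tones into canonical bands", {
  v6 <- psd_bandpower_vector(tone(6, 4, 250), 250)
  expect_gte(v6$values[2] / sum(v6$values), 0.9)    # theta
  v10 <- psd_bandpower_vector(tone(10, 4, 250), 250)
  expect_identical(which.max(v10$values), 3L)       # alpha
  expect_identical(psd_bandpower_vector(numeric(600), 250)$values,
                   numeric(5))
})

test_that("feature matrices round-trip through the delimited format", {
  eeg <- generate_dataset(small_synth(n_epochs_per_condition = 2,
                                      conditions = c("0-back", "2-back"),
                                      theta_gain = c(1, 2),
                                      alpha_gain = c(1, 0.8)))
  f <- extract_features(eeg, "psd")
  path <- file.path(withr::local_tempdir(), "features.tsv")
  write_features(f, path)
  f2 <- read_features(path)
  expect_identical(unclass(f2)[, ], unclass(f)[, ])
  expect_identical(attr(f2, "labels"), attr(f, "labels"))
  expect_identical(attr(f2, "method"), "psd")
})
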