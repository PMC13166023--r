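test_that("sifting a pure tone returns the tone; trends are rejected", {
  x <- tone(10)
  s <- sift(x)
  ii <- interior(length(x))
  expect_gt(cor(s[ii], x[ii]), 0.99)
  expect_true(attr(s, "imf_condition"))

  # DC offset is carried by the envelope mean, not the mode
  s2 <- sift(x + 5)
  expect_lt(abs(mean(s2)), 0.05)

  expect_error(sift(seq(0, 1, length.out = 100)), class = "ssrime_trend_error")
})

test_that("EMD separates a two-tone signal and reconstructs exactly", {
  x <- two_tone()
  d <- emd(x, fs = 500)
  expect_gte(nrow(d$imfs), 2)
  ii <- interior(length(x))
  expect_gt(cor(d$imfs[1, ii], tone(25, 4, 500)[ii]), 0.95)
  later <- vapply(2:nrow(d$imfs), function(k)
    abs(cor(d$imfs[k, ii], tone(3, 4, 500)[ii])), numeric(1))
  expect_gt(max(later), 0.95)
  expect_lt(max(abs(reconstruct(d) - x)), 1e-8 * max(abs(x)))

  # degenerate constant input: no modes, residual is the input
  d0 <- emd(rep(2, 600), fs = 250)
  expect_identical(nrow(d0$imfs), 0L)
  expect_identical(reconstruct(d0), rep(2, 600))
})

test_that("CEEMDAN is seed-deterministic, complete, and scale-equivariant", {
  x <- two_tone(dur = 3, fs = 250)
  p <- fast_cparams(seed = 42)
  d1 <- ceemdan(x, 250, p)
  d2 <- ceemdan(x, 250, p)
  expect_identical(d1$imfs, d2$imfs)
  expect_identical(d1$residual, d2$residual)
  expect_lt(max(abs(reconstruct(d1) - x)), 1e-8 * max(abs(x)))

  for (c in c(0.1, 10)) {
    dc <- ceemdan(c * x, 250, p)
    expect_equal(dim(dc$imfs), dim(d1$imfs))
    expect_lt(max(abs(dc$imfs - c * d1$imfs)) / max(abs(c * d1$imfs)), 1e-6)
  }
})

test_that("ensemble noise reduces mode mixing relative to plain EMD", {
  mix_index <- function(d, ii, fs) {
    mf <- vapply(seq_len(nrow(d$imfs)), function(k)
      median_frequency(analytic(d$imfs[k, ], fs)), numeric(1))
    hi <- which.min(abs(mf - 25))
    lo <- which.min(abs(mf - 3))
    if (hi == lo) return(1)
    abs(cor(d$imfs[hi, ii], d$imfs[lo, ii]))
  }
  fs <- 250
  res <- vapply(1:10, function(s) {
    x <- two_tone(3, fs) + with_seed_helper(s, rnorm(750, 0, 0.3))
    ii <- interior(length(x))
    c(emd = mix_index(emd(x, fs), ii, fs),
      ceemdan = mix_index(ceemdan(x, fs, fast_cparams(seed = s)), ii, fs))
  }, numeric(2))
  expect_lt(mean(res["ceemdan", ]), mean(res["emd", ]))
})

test_that("median instantaneous frequency decreases along the mode index", {
  ok <- vapply(1:20, function(s) {
    x <- with_seed_helper(s, {
      two_tone(3, 250,
               a1 = runif(1, 0.5, 2), a2 = runif(1, 0.5, 2),
               f1 = runif(1, 15, 35), f2 = runif(1, 2, 6))
    })
    d <- emd(x, 250)
    mf <- vapply(seq_len(nrow(d$imfs)), function(k)
      median_frequency(analytic(d$imfs[k, ], 250)), numeric(1))
    all(diff(mf) <= 1e-9)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("zeroing the fast mode removes the fast tone's spectral power", {
  x <- two_tone()
  d <- emd(x, fs = 500)
  d$imfs[1, ] <- 0
  y <- reconstruct(d)
  p25 <- function(v) band_power(v, 500, c(24, 26))
  expect_lt(p25(y), 0.05 * p25(x))
})

test_that("decompositions round-trip through the plain-text format", {
  d <- ceemdan(two_tone(3, 250), 250, fast_cparams(seed = 3))
  path <- file.path(withr::local_tempdir(), "dec.csv")
  write_imfset(d, path)
  d2 <- read_imfset(path)
  expect_identical(d2$imfs, unname(d$imfs))
  expect_identical(d2$residual, d$residual)
  expect_identical(d2$fs, d$fs)
  expect_identical(d2$method, d$method)
})
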