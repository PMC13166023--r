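test_that("Fisher score matches its defining ratio and guards degeneracy", {
  # class means 0 and 1, sample variances exactly 0.25 each -> score 2
  # (up to the 1e-12 variance guard in the denominator)
  x <- matrix(c(0.5, -0.5, 0), ncol = 1)     # mean 0, var 0.5 / 2
  x <- rbind(x, x + 1)
  y <- rep(c("a", "b"), each = 3)
  expect_equal(fisher_score(x, y)[[1]], 2, tolerance = 1e-10)

  # permuted labels: no discriminability
  z <- with_seed_helper(1, matrix(rnorm(400), ncol = 1))
  expect_lt(fisher_score(z, rep(c("a", "b"), 200))[[1]], 0.05)

  # zero variances, different means: finite via the variance guard
  const <- matrix(rep(c(0, 1), each = 3), ncol = 1)
  s <- fisher_score(const, rep(c("a", "b"), each = 3))
  expect_true(is.finite(s) && s > 1e6)

  expect_error(fisher_score(z, rep("a", 400)), "two classes")
})

test_that("cross-validation is calibrated, separable and deterministic", {
  # two Gaussian blobs 4 sd apart: perfectly separable
  blobs <- with_seed_helper(2, rbind(matrix(rnorm(100 * 2), ncol = 2),
                                     matrix(rnorm(100 * 2, mean = 4), ncol = 2)))
  yb <- factor(rep(c("lo", "hi"), each = 100))
  cvb <- cross_validate(blobs, yb, "svm", n_folds = 5, n_repeats = 2, seed = 3)
  expect_equal(cvb$accuracy_mean, 100)

  # pure-noise features: near chance for 400 epochs
  noise <- with_seed_helper(4, matrix(rnorm(400 * 10), ncol = 10))
  yn <- factor(rep(c("lo", "hi"), each = 200))
  cvn <- cross_validate(noise, yn, "svm", n_folds = 10, n_repeats = 1, seed = 5,
                        grid = data.frame(cost = 1, gamma = 0.1))
  half <- 2.576 * 50 / sqrt(400)       # 99% binomial half-width around 50%
  expect_gt(cvn$accuracy_mean, 50 - half)
  expect_lt(cvn$accuracy_mean, 50 + half)

  cvn2 <- cross_validate(noise, yn, "svm", n_folds = 10, n_repeats = 1, seed = 5,
                         grid = data.frame(cost = 1, gamma = 0.1))
  expect_identical(cvn$fold_scores, cvn2$fold_scores)

  expect_error(cross_validate(blobs[1:8, ], yb[1:8], n_folds = 10), "fewer")
})

test_that("every classifier in the harness runs on separable data", {
  blobs <- with_seed_helper(6, rbind(matrix(rnorm(40 * 2), ncol = 2),
                                     matrix(rnorm(40 * 2, mean = 5), ncol = 2)))
  y <- factor(rep(c("lo", "hi"), each = 40))
  for (clf in c("svm", "mlp", "rf", "knn")) {
    cv <- cross_validate(blobs, y, clf, n_folds = 4, n_repeats = 1, seed = 7)
    expect_gte(cv$accuracy_mean, 95)
    expect_gte(cv$f1_mean, 0.95)
  }
})

test_that("paired feature-set comparison behaves at the extremes", {
  s <- with_seed_helper(8, rnorm(20, 90, 2))
  expect_identical(compare_feature_sets(s, s)$p_raw, 1)
  expect_true(compare_feature_sets(s, s)$degenerate)

  cmp <- compare_feature_sets(s + 10, s)
  expect_lt(cmp$p_corrected, 0.001)
  expect_gt(cmp$cohen_d, 1.4)

  # Bonferroni is plain multiplication, capped at 1
  cmp3 <- compare_feature_sets(s + with_seed_helper(9, rnorm(20, 0.5, 1)), s,
                               n_comparisons = 3)
  expect_equal(cmp3$p_corrected, min(1, cmp3$p_raw * 3), tolerance = 1e-12)
})

test_that("delta maps vanish under the null and reduce correctly", {
  # null: same distribution in both conditions
  n_sub <- 20
  feats <- with_seed_helper(10, matrix(rnorm(n_sub * 100 * 8), ncol = 8))
  labels <- factor(rep(c("low", "high"), n_sub * 50))
  subj <- rep(seq_len(n_sub), each = 100)
  dm <- delta_map(feats, labels, subj, high = "high", low = "low",
                  channel_names = paste0("ch", 1:8), imf_select = 1)
  expect_lt(max(abs(dm)), 0.1)

  # single subject, one epoch per condition, channel-z convention:
  # the z-scored per-channel difference directly
  f2 <- matrix(c(1, 2, 3, 4, 8, 6, 4, 2), nrow = 2, byrow = TRUE)
  dm2 <- delta_map(f2, factor(c("low", "high")), c(1, 1), high = "high",
                   low = "low", channel_names = paste0("ch", 1:4),
                   imf_select = 1, z_mode = "channels")
  zn <- function(v) (v - mean(v)) / sd(v)
  expect_equal(unname(dm2), zn(c(8, 6, 4, 2)) - zn(c(1, 2, 3, 4)),
               tolerance = 1e-12)

  # a subject missing a condition is excluded with a warning
  f3 <- rbind(f2, f2)
  expect_warning(
    delta_map(f3, factor(c("low", "high", "low", "low")), c(1, 1, 2, 2),
              high = "high", low = "low",
              channel_names = paste0("ch", 1:4)),
    "lacks")
})

test_that("the ablation harness pairs folds and reports every variant", {
  cfg <- small_synth(n_channels = 4, n_epochs_per_condition = 10,
                     conditions = c("0-back", "2-back"),
                     theta_gain = c(1, 2.5), alpha_gain = c(1, 0.8),
                     frontal_channels = 1:2, posterior_channels = 3:4,
                     seed = 11)
  eeg <- generate_dataset(cfg)
  ab <- ablation_study(eeg, ssrime_params(K = 6),
                       fast_cparams(n_realizations = 5),
                       classifier = "svm", n_folds = 6, n_repeats = 1,
                       seed = 12, grid = data.frame(cost = 1, gamma = 0.05))
  expect_setequal(ab$table$variant,
                  c("full", "no_stabilization", "no_weighting",
                    "no_normalization", "rime", "rwe", "psd"))
  expect_true(all(ab$table$accuracy_mean >= 0 & ab$table$accuracy_mean <= 100))
  expect_length(ab$cv$full$fold_scores, 6)
  # paired design: identical features give a degenerate comparison
  self <- compare_feature_sets(ab$cv$full$fold_scores, ab$cv$full$fold_scores)
  expect_true(self$degenerate)
  expect_named(ab$comparisons, setdiff(ab$table$variant, "full"))
})
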