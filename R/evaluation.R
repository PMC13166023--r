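#' Fisher score of each feature for a two-class contrast
#'
#' `score_j = (m1_j - m0_j)^2 / (v1_j + v0_j + eps)` with per-class sample
#' means and variances; the epsilon guards degenerate zero-variance features.
#'
#' @param features Numeric matrix, epochs x features.
#' @param labels Two-level factor (or coercible), one per epoch, each level
#'   with at least 2 epochs.
#' @param epsilon Variance guard (default 1e-12).
#' @return Non-negative numeric vector, one score per column.
#' @export
fisher_score <- function(features, labels, epsilon = 1e-12) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("fisher_score requires exactly two classes (got ",
         nlevels(labels), ")")
  if (any(table(labels) < 2)) stop("each class needs at least 2 epochs")
  a <- features[labels == levels(labels)[1], , drop = FALSE]
  b <- features[labels == levels(labels)[2], , drop = FALSE]
  (colMeans(a) - colMeans(b))^2 /
    (apply(a, 2, var) + apply(b, 2, var) + epsilon)
}

stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < n_folds)
        stop("class '", lv, "' has fewer epochs than folds")
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
    fold
  })
}

zscore_apply <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  s[s == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, "/"),
       test = sweep(sweep(test, 2, mu), 2, s, "/"))
}

default_grids <- function(d) {
  list(svm = expand.grid(cost = c(1, 10), gamma = c(1 / d, 0.1 / d)),
       mlp = expand.grid(size = c(5, 10), decay = c(0.1, 0.01)),
       rf = expand.grid(ntree = 200),
       knn = expand.grid(k = c(3, 5, 7)))
}

fit_predict <- function(classifier, hp, xtr, ytr, xte, seed) {
  with_seed(seed, switch(classifier,
    svm = {
      m <- e1071::svm(xtr, ytr, kernel = "radial", cost = hp$cost,
                      gamma = hp$gamma, scale = FALSE)
      predict(m, xte)
    },
    mlp = {
      m <- nnet::nnet(xtr, nnet::class.ind(ytr), size = hp$size,
                      decay = hp$decay, maxit = 200, softmax = TRUE,
                      trace = FALSE, MaxNWts = 1e5)
      factor(levels(ytr)[max.col(predict(m, xte))], levels = levels(ytr))
    },
    rf = {
      m <- randomForest::randomForest(xtr, ytr, ntree = hp$ntree)
      predict(m, xte)
    },
    knn = class::knn(xtr, xte, ytr, k = hp$k),
    stop("unknown classifier: ", classifier)))
}

# inner CV grid search on the training partition
tune_hyperparameters <- function(classifier, grid, xtr, ytr, seed,
                                 inner_folds = 3) {
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  fold <- stratified_folds(ytr, inner_folds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(inner_folds), function(f) {
      z <- zscore_apply(xtr[fold != f, , drop = FALSE],
                        xtr[fold == f, , drop = FALSE])
      pred <- fit_predict(classifier, grid[g, , drop = FALSE], z$train,
                          ytr[fold != f], z$test, derive_seed(seed, g * 100 + f))
      mean(pred == ytr[fold == f])
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(acc), , drop = FALSE]
}

macro_f1 <- function(truth, pred) {
  mean(vapply(levels(truth), function(lv) {
    tp <- sum(pred == lv & truth == lv)
    fp <- sum(pred == lv & truth != lv)
    fn <- sum(pred != lv & truth == lv)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1)))
}

#' Stratified repeated k-fold cross-validated classification
#'
#' Epochs are pooled (across subjects) and assigned to label-stratified
#' folds, reshuffled each repeat; features are z-scored on each training
#' partition; hyperparameters are chosen by an inner 3-fold grid search on
#' the training partition (nested cross-validation).  Deterministic given
#' `seed`.
#'
#' @param features Numeric matrix, epochs x features.
#' @param labels Factor of condition labels, one per epoch.
#' @param classifier `"svm"` (RBF), `"mlp"`, `"rf"`, or `"knn"`.
#' @param n_folds,n_repeats Outer folds and repeats (defaults 10 and 10).
#' @param seed Integer seed controlling fold shuffles and classifier RNG.
#' @param grid Hyperparameter grid (a data frame); defaults to a small
#'   documented grid per classifier; a single-row grid disables tuning.
#' @return Object of class `cv_result`: accuracy mean/sd (percent), macro-F1
#'   mean, per-fold accuracy vector `fold_scores` (length
#'   `n_folds * n_repeats`, paired across feature sets run with the same
#'   seed), fold/repeat counts and seed.
#' @export
cross_validate <- function(features, labels, classifier = "svm",
                           n_folds = 10, n_repeats = 10, seed = 1,
                           grid = NULL) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  stopifnot(nrow(features) == length(labels))
  if (is.null(grid)) grid <- default_grids(ncol(features))[[classifier]]
  fold_acc <- numeric(0)
  fold_f1 <- numeric(0)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(labels, n_folds, derive_seed(seed, r))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      z <- zscore_apply(features[tr, , drop = FALSE],
                        features[!tr, , drop = FALSE])
      hp <- tune_hyperparameters(classifier, grid, z$train, labels[tr],
                                 derive_seed(seed, r * 1000 + f))
      pred <- fit_predict(classifier, hp, z$train, labels[tr], z$test,
                          derive_seed(seed, r * 1000 + f + 500))
      truth <- labels[!tr]
      fold_acc <- c(fold_acc, 100 * mean(pred == truth))
      fold_f1 <- c(fold_f1, macro_f1(truth, pred))
    }
  }
  structure(list(accuracy_mean = mean(fold_acc), accuracy_sd = sd(fold_acc),
                 f1_mean = mean(fold_f1), fold_scores = fold_acc,
                 classifier = classifier, n_folds = n_folds,
                 n_repeats = n_repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: accuracy %.2f +- %.2f %%, macro-F1 %.3f (%d x %d-fold)\n",
              x$classifier, x$accuracy_mean, x$accuracy_sd, x$f1_mean,
              x$n_repeats, x$n_folds))
  invisible(x)
}

#' Paired statistical comparison of two feature sets
#'
#' Wilcoxon signed-rank test on paired per-fold scores, Bonferroni-corrected
#' over the comparison family, plus Cohen's d on the paired differences
#' (mean difference over its standard deviation).
#'
#' @param scores_a,scores_b Paired per-fold score vectors of equal length
#'   (at least 6).
#' @param n_comparisons Bonferroni family size (default 1).
#' @return List with `p_raw`, `p_corrected = min(1, p_raw * n_comparisons)`,
#'   `cohen_d`, `mean_diff` and `degenerate` (TRUE when all differences are
#'   zero, in which case p is 1 by convention).
#' @export
compare_feature_sets <- function(scores_a, scores_b, n_comparisons = 1) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 6)
  d <- scores_a - scores_b
  if (all(d == 0))
    return(list(p_raw = 1, p_corrected = 1, cohen_d = 0, mean_diff = 0,
                degenerate = TRUE))
  p <- suppressWarnings(wilcox.test(scores_a, scores_b, paired = TRUE)$p.value)
  list(p_raw = p, p_corrected = min(1, p * n_comparisons),
       cohen_d = if (sd(d) == 0) Inf * sign(mean(d)) else mean(d) / sd(d),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Per-channel condition-difference map
#'
#' For each subject, features are z-normalized to suppress inter-subject
#' amplitude variability, averaged across epochs within each condition and
#' aggregated per channel over the selected mode columns; the low-workload
#' pattern is subtracted from the high-workload one and the per-channel
#' differences are averaged across subjects.
#'
#' Two z-normalization conventions are offered: `"features"` (default)
#' standardizes each feature column across the subject's epochs before
#' condition averaging, so a flat (null) contrast stays near zero;
#' `"channels"` standardizes the per-condition channel pattern across
#' channels, emphasizing spatial topography at the cost of unit-variance
#' noise amplification under the null.
#'
#' @param features An `ssrime_features` matrix (or plain matrix with
#'   `channels * K` columns in channel-major order).
#' @param labels,subject_id Per-epoch condition labels and subject indices
#'   (defaulting to the attributes of `features`).
#' @param high,low Condition labels to contrast.
#' @param channel_names Channel labels (defaults to the attribute).
#' @param imf_select Indices of the per-channel feature columns to
#'   aggregate (e.g. theta/alpha-dominant modes); default all.
#' @param z_mode `"features"` or `"channels"`, see Details.
#' @return Named numeric vector, one difference per channel.
#' @export
delta_map <- function(features, labels = attr(features, "labels"),
                      subject_id = attr(features, "subject_id"),
                      high = NULL, low = NULL,
                      channel_names = attr(features, "channel_names"),
                      imf_select = NULL,
                      z_mode = c("features", "channels")) {
  features <- unclass(features)
  z_mode <- match.arg(z_mode)
  labels <- factor(labels)
  if (is.null(low)) low <- levels(labels)[1]
  if (is.null(high)) high <- levels(labels)[nlevels(labels)]
  nch <- length(channel_names)
  per <- ncol(features) / nch
  if (is.null(imf_select)) imf_select <- seq_len(per)
  if (is.null(subject_id)) subject_id <- rep(1L, nrow(features))
  zn <- function(v) if (sd(v) == 0) v - mean(v) else (v - mean(v)) / sd(v)
  diffs <- NULL
  for (s in unique(subject_id)) {
    rows <- subject_id == s
    fsub <- features[rows, , drop = FALSE]
    if (z_mode == "features" && nrow(fsub) > 1)
      fsub <- apply(fsub, 2, zn)
    chan_mean <- function(cond) {
      sel <- labels[rows] == cond
      if (!any(sel)) return(NULL)
      m <- colMeans(fsub[sel, , drop = FALSE])
      v <- vapply(seq_len(nch), function(ch)
        sum(m[(ch - 1) * per + imf_select]), numeric(1))
      if (z_mode == "channels") zn(v) else v
    }
    hi <- chan_mean(high)
    lo <- chan_mean(low)
    if (is.null(hi) || is.null(lo)) {
      warning("subject ", s, " lacks a condition; excluded from delta_map")
      next
    }
    diffs <- rbind(diffs, hi - lo)
  }
  if (is.null(diffs)) stop("no subject has both conditions")
  structure(colMeans(diffs), names = channel_names)
}

#' Component ablation study
#'
#' Decomposes the dataset once, derives the full SS-RIME descriptor and its
#' single-component-removed variants (no stabilization, no band weighting,
#' no cross-IMF normalization) plus the RIME, RWE and PSD baselines, and
#' cross-validates every variant with identical fold assignments (paired
#' design).  Full-vs-variant Wilcoxon comparisons are Bonferroni-corrected
#' over the number of comparisons made.
#'
#' The RIME baseline here is the fully ablated reading: raw mode energies
#' in extraction order, without stabilization, weighting or cross-mode
#' normalization, so it also exposes sensitivity to global amplitude
#' (the normalized relative-energy variant is the `no_stabilization` +
#' `no_weighting` combination up to reordering, and remains available via
#' [rime_vector]).
#'
#' @param eeg An `epoched_eeg`.
#' @param params Base [ssrime_params] for the full descriptor.
#' @param cparams [ceemdan_params] for the shared decomposition.
#' @param classifier,n_folds,n_repeats,grid Passed to [cross_validate].
#' @param seed Master seed (decomposition noise and fold shuffles).
#' @param contrast Optional two condition labels to restrict the dataset to.
#' @return Object of class `ablation_result`: `table` (variant, accuracy
#'   mean/sd, F1), `comparisons` (full vs each variant), and the per-variant
#'   `cv` results.
#' @export
ablation_study <- function(eeg, params = ssrime_params(),
                           cparams = ceemdan_params(), classifier = "svm",
                           n_folds = 10, n_repeats = 2, seed = 1,
                           grid = NULL, contrast = NULL) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  if (!is.null(contrast)) eeg <- subset_epochs(eeg, eeg$labels %in% contrast)
  dec <- decompose_epochs(eeg, cparams, seed)
  variant_params <- list(
    full = params,
    no_stabilization = modify_params(params, include_stabilization = FALSE),
    no_weighting = modify_params(params, include_weighting = FALSE),
    no_normalization = modify_params(params, include_normalization = FALSE))
  feats <- lapply(variant_params, function(p)
    extract_features(eeg, "ssrime", p, cparams, seed, decompositions = dec))
  feats$rime <- extract_features(eeg, "rime", params, cparams, seed,
                                 decompositions = dec,
                                 rime_normalize = FALSE)
  feats$rwe <- extract_features(eeg, "rwe", seed = seed)
  feats$psd <- extract_features(eeg, "psd", seed = seed)
  cv <- lapply(feats, function(f)
    cross_validate(f, attr(f, "labels"), classifier, n_folds, n_repeats,
                   seed, grid))
  others <- setdiff(names(cv), "full")
  comparisons <- if (length(cv$full$fold_scores) >= 6) {
    out <- lapply(others, function(v)
      compare_feature_sets(cv$full$fold_scores, cv[[v]]$fold_scores,
                           n_comparisons = length(others)))
    names(out) <- others
    out
  } else list()
  tab <- data.frame(variant = names(cv),
                    accuracy_mean = vapply(cv, `[[`, 0, "accuracy_mean"),
                    accuracy_sd = vapply(cv, `[[`, 0, "accuracy_sd"),
                    f1_mean = vapply(cv, `[[`, 0, "f1_mean"),
                    row.names = NULL)
  structure(list(table = tab, comparisons = comparisons, cv = cv,
                 seed = seed), class = "ablation_result")
}

modify_params <- function(params, ...) {
  mods <- list(...)
  params[names(mods)] <- mods
  params
}

subset_epochs <- function(eeg, keep) {
  structure(list(data = eeg$data[keep, , , drop = FALSE], fs = eeg$fs,
                 labels = droplevels(eeg$labels[keep]),
                 subject_id = eeg$subject_id[keep],
                 channel_names = eeg$channel_names),
            class = "epoched_eeg")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  print(transform(x$table, accuracy_mean = round(accuracy_mean, 2),
                  accuracy_sd = round(accuracy_sd, 2),
                  f1_mean = round(f1_mean, 3)))
  invisible(x)
}

#' Write an evaluation or ablation report
#'
#' Emits a JSON document and, for tabular content, a tab-separated table
#' next to it (`<path>.tsv`).
#'
#' @param report A `cv_result`, `ablation_result`, or plain list.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  obj <- if (inherits(report, "ablation_result"))
    list(table = report$table,
         comparisons = lapply(report$comparisons, unclass),
         seed = report$seed)
  else unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (inherits(report, "ablation_result"))
    write.table(report$table, paste0(path, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (inherits(report, "cv_result")) {
    tab <- data.frame(metric = c("accuracy_mean", "accuracy_sd", "f1_mean"),
                      value = c(report$accuracy_mean, report$accuracy_sd,
                                report$f1_mean))
    write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
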