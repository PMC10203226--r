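# Working-memory load decoding (loads 4/6/8) from representational or
# connectivity features: repeated stratified 70/30 splits, per-split
# standardization and PCA fitted on the training set only (components
# retained up to 99% cumulative explained variance), and a linear
# support-vector classifier (one-vs-one, cost 1). Accuracy differences
# between regions or directions are assessed by label permutation.

#' Assemble a feature set for decoding
#'
#' @param X Samples x features numeric matrix (no missing values).
#' @param y Load labels (4, 6 or 8), one per sample.
#' @param sample_unit One of `"trial_pair"`, `"trial"`, `"channel_pair"`.
#' @param provenance Free-form description (region/direction, period).
#' @return A `wm_features` object.
#' @export
feature_set <- function(X, y, sample_unit = "trial", provenance = "") {
  X <- as.matrix(X)
  if (anyNA(X)) stop_validation("feature matrix contains missing values")
  if (nrow(X) != length(y)) stop_validation("X rows and labels differ")
  if (any(table(y) < 2)) stop_validation("every class needs >= 2 samples")
  structure(list(X = X, y = as.factor(y), sample_unit = sample_unit,
                 provenance = provenance), class = "wm_features")
}

#' Build EED decoding features
#'
#' Stacks per-trial-pair EED maps (one flattened windows^2 vector per
#' pair) across loads — and across participants/sessions when a list of
#' per-load matrices is given per session — into one feature set with
#' the pair's load as label.
#'
#' @param pair_values_by_load Named list (`"4"`, `"6"`, `"8"`) of
#'   pairs x features matrices (e.g. from the per-pair values underlying
#'   [eed_map()]), or a list of such lists (one per session) to pool.
#' @param provenance Description string.
#' @param center_sessions When pooling several sessions, subtract each
#'   session's overall feature mean before stacking. This removes random
#'   session/participant baseline offsets that otherwise mask the
#'   within-session load structure; the operation is label-blind, so it
#'   cannot introduce spurious load information.
#' @return A `wm_features` with `sample_unit = "trial_pair"`.
#' @export
build_eed_features <- function(pair_values_by_load, provenance = "EED",
                               center_sessions = FALSE) {
  build_stacked_features(pair_values_by_load, "trial_pair", provenance,
                         center_sessions)
}

#' Build EMS decoding features
#'
#' As [build_eed_features()], but one flattened encoding x maintenance
#' map per trial (`sample_unit = "trial"`).
#'
#' @param trial_values_by_load Named per-load list of trials x features
#'   matrices (from `ems_map(..., per_trial = TRUE)$trial_values`), or a
#'   list of such lists to pool across sessions.
#' @param provenance Description string.
#' @inheritParams build_eed_features
#' @return A `wm_features`.
#' @export
build_ems_features <- function(trial_values_by_load, provenance = "EMS",
                               center_sessions = FALSE) {
  build_stacked_features(trial_values_by_load, "trial", provenance,
                         center_sessions)
}

build_stacked_features <- function(by_load, unit, provenance,
                                   center_sessions = FALSE) {
  if (!is.matrix(by_load[[1]]) && is.list(by_load[[1]])) {
    if (center_sessions) {
      by_load <- lapply(by_load, function(fl) {
        mu <- colMeans(do.call(rbind, fl))
        lapply(fl, function(m) sweep(m, 2, mu))
      })
    }
    loads <- names(by_load[[1]])
    by_load <- stats::setNames(lapply(loads, function(l) {
      do.call(rbind, lapply(by_load, `[[`, l))
    }), loads)
  }
  p <- unique(vapply(by_load, ncol, integer(1)))
  if (length(p) != 1) stop_validation("inconsistent feature lengths")
  X <- do.call(rbind, by_load)
  y <- rep(as.integer(names(by_load)), vapply(by_load, nrow, integer(1)))
  feature_set(X, y, unit, provenance)
}

#' Build PSI decoding features
#'
#' Takes z-scored directional connectivity per channel pair (pairs x
#' frequencies, computed per load) and restricts it to one direction:
#' hippocampus-leads features keep the positive z-values (negative set
#' to zero), amygdala-leads features the magnitudes of negative ones, so
#' the two directions from the same result are disjoint by sign. A
#' direction with no supra-zero bins anywhere yields a zero-filled
#' feature matrix with a warning.
#'
#' @param z_by_load Named per-load list (`"4"`, `"6"`, `"8"`) of
#'   pairs x frequencies matrices of z-scored PSI (hippocampus first
#'   signal), or a list of such lists to pool across sessions.
#' @param direction `"HIP_leads"` or `"AMY_leads"`.
#' @param provenance Description string.
#' @return A `wm_features` with `sample_unit = "channel_pair"`.
#' @export
build_psi_features <- function(z_by_load, direction = c("HIP_leads",
                                                        "AMY_leads"),
                               provenance = NULL) {
  direction <- match.arg(direction)
  if (!is.matrix(z_by_load[[1]]) && is.list(z_by_load[[1]])) {
    loads <- names(z_by_load[[1]])
    z_by_load <- stats::setNames(lapply(loads, function(l) {
      do.call(rbind, lapply(z_by_load, `[[`, l))
    }), loads)
  }
  rectify <- function(z) {
    if (direction == "HIP_leads") pmax(z, 0) else pmax(-z, 0)
  }
  feats <- lapply(z_by_load, rectify)
  if (all(vapply(feats, function(m) all(m == 0), logical(1)))) {
    warning("no bins in direction ", direction, "; features zero-filled")
  }
  X <- do.call(rbind, feats)
  y <- rep(as.integer(names(feats)), vapply(feats, nrow, integer(1)))
  feature_set(X, y, "channel_pair", provenance %||% paste0("PSI ", direction))
}

# One stratified split: per class, floor(train_frac * n_c) training rows.
stratified_split <- function(y, train_frac) {
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- floor(train_frac * length(idx) + 1e-9)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# Fit standardization + PCA on the training block only, project both.
# Keeps the first K components reaching cumulative explained variance
# var_keep. Returns list(train, test, k).
pca_project <- function(Xtr, Xte, var_keep, standardize) {
  if (standardize) {
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv <= 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  }
  pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
  ev <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(1L, which(ev >= var_keep)[1])
  list(train = pc$x[, seq_len(k), drop = FALSE],
       test = scale(Xte, center = pc$center, scale = FALSE) %*%
         pc$rotation[, seq_len(k), drop = FALSE],
       k = k)
}

#' Decode working-memory load from a feature set
#'
#' Per repeat: a stratified split takes 70% of each class for training;
#' features are standardized and reduced by PCA using training-set
#' statistics only (components to 99% cumulative variance); a linear SVM
#' (one-vs-one, cost 1) is trained and its accuracy on the held-out 30%
#' recorded. The mean over repeats is the performance measure.
#'
#' @param fs A [feature_set()].
#' @param train_frac Training fraction per class (default 0.7).
#' @param n_repeats Number of random splits (default 100).
#' @param var_keep Cumulative explained variance retained (default 0.99).
#' @param cost SVM cost parameter (default 1).
#' @param standardize Standardize features with train-fit mean/sd before
#'   PCA (default `TRUE`).
#' @param seed Master seed; each repeat uses a derived split seed.
#' @return A `wm_decoding` with per-repeat accuracies, their mean/sd and
#'   the number of principal components per repeat.
#' @export
decode_load <- function(fs, train_frac = 0.7, n_repeats = 100,
                        var_keep = 0.99, cost = 1, standardize = TRUE,
                        seed = 1L) {
  stopifnot(inherits(fs, "wm_features"))
  if (nlevels(fs$y) < 2) stop_validation("need >= 2 classes")
  acc <- numeric(n_repeats)
  ks <- integer(n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      tr <- stratified_split(fs$y, train_frac)
      te <- setdiff(seq_along(fs$y), tr)
      pr <- pca_project(fs$X[tr, , drop = FALSE],
                        fs$X[te, , drop = FALSE], var_keep, standardize)
      fit <- e1071::svm(pr$train, fs$y[tr], kernel = "linear", cost = cost,
                        scale = FALSE)
      pred <- stats::predict(fit, pr$test)
      acc[r] <- mean(pred == fs$y[te])
      ks[r] <- pr$k
    }
  })
  structure(list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
                 n_components = ks, n_repeats = n_repeats, seed = seed),
            class = "wm_decoding")
}

#' @export
print.wm_decoding <- function(x, ...) {
  cat(sprintf("<wm_decoding> mean accuracy %.2f%% +/- %.2f%% (%d repeats, K=%g)\n",
              100 * x$mean, 100 * x$sd, x$n_repeats,
              stats::median(x$n_components)))
  invisible(x)
}

shuffle_labels <- function(fs) {
  fs$y <- sample(fs$y)
  fs
}

#' Permutation test of the decoding accuracy difference
#'
#' Observed statistic: mean accuracy of `fsA` minus mean accuracy of
#' `fsB`. Null: the labels of both sets are shuffled `n_perm` times and
#' the difference recomputed each time; the two-sided p-value is the
#' smoothed fraction `(b + 1) / (n_perm + 1)` of null differences at
#' least as extreme as observed.
#'
#' @param fsA,fsB Two [feature_set()]s.
#' @param n_perm Number of label shuffles (default 200, minimum 20).
#' @param n_repeats Splits per decoding run (default 100; reduce for the
#'   null recomputations via `n_repeats_null`).
#' @param n_repeats_null Splits per null decoding run (default 5).
#' @param seed RNG seed.
#' @param ... Passed to [decode_load()].
#' @return A list with `observed` (accuracy difference), `p`,
#'   `null` (vector of null differences), and the two `wm_decoding` fits.
#' @export
accuracy_difference_test <- function(fsA, fsB, n_perm = 200,
                                     n_repeats = 100, n_repeats_null = 5,
                                     seed = 1L, ...) {
  if (n_perm < 20) stop_validation("n_perm < 20 gives too coarse a p-value")
  decA <- decode_load(fsA, n_repeats = n_repeats,
                      seed = derive_seed(seed, "A"), ...)
  decB <- decode_load(fsB, n_repeats = n_repeats,
                      seed = derive_seed(seed, "B"), ...)
  observed <- decA$mean - decB$mean
  null <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(i) {
      sA <- shuffle_labels(fsA)
      sB <- shuffle_labels(fsB)
      dA <- decode_load(sA, n_repeats = n_repeats_null,
                        seed = derive_seed(seed, paste0("pA", i)), ...)
      dB <- decode_load(sB, n_repeats = n_repeats_null,
                        seed = derive_seed(seed, paste0("pB", i)), ...)
      dA$mean - dB$mean
    }, numeric(1))
  })
  p <- (sum(abs(null) >= abs(observed)) + 1) / (n_perm + 1)
  list(observed = observed, p = p, null = null, decodingA = decA,
       decodingB = decB)
}

#' Permutation test of decoding accuracy against chance
#'
#' Compares the observed mean accuracy with a null distribution from
#' label-shuffled decoding runs; one-sided p-value with +1 smoothing.
#'
#' @param fs A [feature_set()].
#' @param n_perm Number of label shuffles (default 100).
#' @param n_repeats Splits for the observed run.
#' @param n_repeats_null Splits per null run (default 5).
#' @param seed RNG seed.
#' @param ... Passed to [decode_load()].
#' @return List with `observed` (mean accuracy), `p`, `null`, `decoding`.
#' @export
accuracy_vs_chance_test <- function(fs, n_perm = 100, n_repeats = 100,
                                    n_repeats_null = 5, seed = 1L, ...) {
  dec <- decode_load(fs, n_repeats = n_repeats,
                     seed = derive_seed(seed, "obs"), ...)
  null <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(i) {
      decode_load(shuffle_labels(fs), n_repeats = n_repeats_null,
                  seed = derive_seed(seed, paste0("p", i)), ...)$mean
    }, numeric(1))
  })
  p <- (sum(null >= dec$mean) + 1) / (n_perm + 1)
  list(observed = dec$mean, p = p, null = null, decoding = dec)
}

#' Train/test sample counts for a stratified split
#'
#' Bookkeeping helper: per-class training size is `floor(train_frac * n)`
#' and the remainder is tested, e.g. 1400 samples per load split 980/420
#' at 70%, or 172 channel pairs split 120/52.
#'
#' @param n Samples in one class.
#' @param train_frac Training fraction (default 0.7).
#' @return Named vector `c(train =, test =)`.
#' @export
split_sizes <- function(n, train_frac = 0.7) {
  tr <- floor(train_frac * n + 1e-9)   # guard binary rounding of 0.7 * n
  c(train = tr, test = n - tr)
}
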