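#' Split epochs into virtual data subsets
#'
#' Cuts a session's epochs into contiguous, non-overlapping, chronologically
#' ordered subsets of `vds_size` epochs each — virtual small training sets.
#' A trailing remainder is dropped by default (count reported via attribute
#' `"n_dropped"` and a message) or absorbed into the last subset.
#'
#' @param epochs An [epoch_collection()].
#' @param vds_size Epochs per subset; must allow both classes in every CV
#'   fold, i.e. `vds_size >= 2 * n_folds`.
#' @param n_folds CV fold count the subsets are destined for (default 5).
#' @param remainder `"drop"` (default) or `"absorb"` into the last subset.
#' @return List of `epoch_collection` subsets with attribute `"n_dropped"`.
#' @export
split_vds <- function(epochs, vds_size, n_folds = 5,
                      remainder = c("drop", "absorb")) {
  stopifnot(inherits(epochs, "epoch_collection"))
  remainder <- match.arg(remainder)
  n <- n_epochs(epochs)
  if (vds_size > n) stop("vds_size exceeds the number of epochs")
  if (vds_size < 2 * n_folds)
    stop(sprintf("vds_size %d < 2 * n_folds = %d: folds would lose a class",
                 vds_size, 2 * n_folds))
  k <- n %/% vds_size
  dropped <- n - k * vds_size
  out <- vector("list", k)
  for (i in seq_len(k)) {
    lo <- (i - 1L) * vds_size + 1L
    hi <- if (i == k && remainder == "absorb") n else i * vds_size
    out[[i]] <- subset_epochs(epochs, epochs = lo:hi)
  }
  if (remainder == "absorb") dropped <- 0L
  if (dropped > 0)
    message(sprintf("split_vds: dropped %d trailing epoch(s)", dropped))
  attr(out, "n_dropped") <- dropped
  out
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin over
#' the folds, preserving the class ratio in every fold.
#'
#' @param labels Vector in `{0, 1}`.
#' @param n_folds Number of folds, `>= 2`; every class needs at least
#'   `n_folds` members.
#' @param seed Optional RNG seed (recorded fold assignment is reproducible).
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 5, seed = NULL) {
  stopifnot(n_folds >= 2)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < n_folds)
      stop(sprintf("class %s has %d members, fewer than %d folds",
                   cls, length(idx), n_folds))
    folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Area under the ROC curve
#'
#' Probability that a random target epoch scores above a random non-target
#' epoch, with ties counted one half — computed via midranks, identical to
#' exhaustive concordant-pair counting.
#'
#' @param scores Numeric decision scores (higher = more target-like).
#' @param labels Vector in `{0, 1}`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validated AUC
#'
#' Fits the requested LDA variant on the training folds only — all
#' estimation steps, including class means, the Ledoit-Wolf intensity and
#' the decoupled channel covariance, see only training epochs — and scores
#' the held-out fold.
#'
#' @param fm A [feature_matrix()].
#' @param variant LDA variant passed to [lda_fit()].
#' @param n_folds Number of stratified folds (default 5).
#' @param seed Optional RNG seed for the fold assignment.
#' @param folds Optional precomputed fold ids (overrides `n_folds`/`seed`),
#'   allowing paired comparisons of methods on identical splits.
#' @param ... Further arguments to [lda_fit()].
#' @return Numeric vector of per-fold AUC values.
#' @export
stratified_cv_auc <- function(fm, variant = "p-cov", n_folds = 5,
                              seed = NULL, folds = NULL, ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(folds))
    folds <- stratified_folds(fm$labels, n_folds, seed)
  vapply(sort(unique(folds)), function(k) {
    tr <- folds != k
    fm_tr <- feature_matrix(fm$X[, tr, drop = FALSE], fm$labels[tr],
                            fm$n_channels, fm$n_intervals, fm$widths,
                            fm$intervals)
    model <- lda_fit(fm_tr, variant, ...)
    auc_score(decision_scores(model, fm$X[, !tr, drop = FALSE]),
              fm$labels[!tr])
  }, numeric(1))
}

#' Aggregate AUC values up the VDS / session / subject hierarchy
#'
#' Unweighted means in the stated order: virtual data subsets are averaged
#' within a session, then sessions within a subject, so every session
#' contributes equally to its subject regardless of its VDS count.
#'
#' @param results Data frame with columns `subject`, `session`, `auc`, an
#'   optional `method`, and any further columns identifying the VDS.
#' @return Data frame with one row per subject (and method, if present).
#' @export
aggregate_auc <- function(results) {
  stopifnot(all(c("subject", "session", "auc") %in% names(results)))
  by1 <- list(subject = results$subject, session = results$session)
  if ("method" %in% names(results)) by1$method <- results$method
  per_session <- stats::aggregate(list(auc = results$auc), by1, mean)
  by2 <- list(subject = per_session$subject)
  if ("method" %in% names(per_session)) by2$method <- per_session$method
  stats::aggregate(list(auc = per_session$auc), by2, mean)
}

#' Paired comparison of classification methods
#'
#' Two-sided paired Wilcoxon signed-rank tests on per-unit (typically
#' per-dataset or per-subject) AUC values, with Holm correction across the
#' comparison family and significance reported at `alpha`. Comparisons whose
#' paired differences are all zero are degenerate: they are reported with
#' `p = 1` and flagged rather than tested.
#'
#' @param auc_matrix Numeric matrix, rows = paired units, named columns =
#'   methods; `>= 2` rows.
#' @param comparisons Optional 2-column character matrix of method pairs;
#'   default all pairs.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `method_a`, `method_b`, `statistic`,
#'   `p_value`, `p_holm`, `significant`, `degenerate`.
#' @export
compare_methods <- function(auc_matrix, comparisons = NULL, alpha = 0.05) {
  auc_matrix <- as.matrix(auc_matrix)
  if (nrow(auc_matrix) < 2) stop("need at least 2 paired observations")
  if (is.null(colnames(auc_matrix)))
    colnames(auc_matrix) <- paste0("method", seq_len(ncol(auc_matrix)))
  if (is.null(comparisons))
    comparisons <- t(utils::combn(colnames(auc_matrix), 2))
  res <- lapply(seq_len(nrow(comparisons)), function(i) {
    a <- comparisons[i, 1]; b <- comparisons[i, 2]
    d <- auc_matrix[, a] - auc_matrix[, b]
    if (all(d == 0)) {
      data.frame(method_a = a, method_b = b, statistic = NA_real_,
                 p_value = 1, degenerate = TRUE)
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(auc_matrix[, a], auc_matrix[, b],
                           paired = TRUE, exact = NULL))
      data.frame(method_a = a, method_b = b,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  res$significant <- res$p_holm < alpha & !res$degenerate
  res[, c("method_a", "method_b", "statistic", "p_value", "p_holm",
          "significant", "degenerate")]
}

#' Learning curve of the AUC difference between two LDA variants
#'
#' For each training-set size (and optionally each channel subset), repeats
#' stratified cross-validation on within-class permuted subsamples of one
#' simulated session and records both variants' mean AUC on identical folds.
#' Channel subsets are approximately equidistant deterministic selections
#' over the channel list, and all sizes/subsets of one permutation share the
#' subsampling seed, so comparisons are paired throughout.
#'
#' @param config A [sim_config()] whose epoch counts cover `max(sizes)` at
#'   the configured class ratio.
#' @param sizes Integer vector of total training-set sizes.
#' @param variants Length-2 character vector of LDA variants to compare
#'   (difference reported as first minus second).
#' @param n_permutations Within-class permutations per size (default 20).
#' @param n_folds Stratified CV folds (default 5).
#' @param channel_subsets Optional integer vector of channel counts; default
#'   the full montage only.
#' @param intervals Feature [interval_set()] (default the standard 5-interval
#'   visual/tone set).
#' @param seed Base RNG seed; permutation `p` uses `seed + p`.
#' @param ... Further arguments to [lda_fit()].
#' @return Long data frame: `n_train`, `n_channels`, `permutation`, one AUC
#'   column per variant, and `auc_diff`.
#' @export
learning_curve <- function(config, sizes, variants = c("imp-p-cov", "p-cov"),
                           n_permutations = 20, n_folds = 5,
                           channel_subsets = NULL,
                           intervals = default_intervals("visual", 5),
                           seed = 1, ...) {
  stopifnot(inherits(config, "sim_config"), length(variants) == 2)
  epochs <- generate_epochs(config)
  n_total <- n_epochs(epochs)
  if (max(sizes) > n_total)
    stop("config provides fewer epochs than max(sizes)")
  C <- dim(epochs$data)[2]
  if (is.null(channel_subsets)) channel_subsets <- C
  ratio <- config$n_target / (config$n_target + config$n_nontarget)
  idx1 <- which(epochs$labels == 1L)
  idx0 <- which(epochs$labels == 0L)

  rows <- list()
  for (p in seq_len(n_permutations)) {
    set.seed(seed + p)
    perm1 <- sample(idx1); perm0 <- sample(idx0)
    fold_seed <- sample.int(.Machine$integer.max, 1L)
    for (n in sizes) {
      n1 <- max(round(n * ratio), n_folds)
      n0 <- n - n1
      take <- c(perm1[seq_len(n1)], perm0[seq_len(n0)])
      for (cs in channel_subsets) {
        ch_idx <- unique(round(seq(1, C, length.out = cs)))
        sub <- subset_epochs(epochs, epochs = take, channels = ch_idx)
        fm <- extract_features(sub, intervals)
        folds <- stratified_folds(fm$labels, n_folds, seed = fold_seed)
        aucs <- vapply(variants, function(v)
          mean(stratified_cv_auc(fm, v, folds = folds, ...)), numeric(1))
        row <- data.frame(n_train = n, n_channels = length(ch_idx),
                          permutation = p)
        row[[variants[1]]] <- aucs[1]
        row[[variants[2]]] <- aucs[2]
        row$auc_diff <- aucs[1] - aucs[2]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a learning curve
#'
#' Mean, median and twice the standard error of the AUC difference per
#' training-set size and channel count.
#'
#' @param curve Output of [learning_curve()].
#' @return Data frame with columns `n_train`, `n_channels`, `mean_diff`,
#'   `median_diff`, `two_se`, `n`.
#' @export
summarize_learning_curve <- function(curve) {
  agg <- stats::aggregate(
    list(mean_diff = curve$auc_diff),
    list(n_train = curve$n_train, n_channels = curve$n_channels), mean)
  agg$median_diff <- stats::aggregate(
    curve$auc_diff, list(curve$n_train, curve$n_channels), stats::median)$x
  sds <- stats::aggregate(
    curve$auc_diff, list(curve$n_train, curve$n_channels), stats::sd)$x
  ns <- stats::aggregate(
    curve$auc_diff, list(curve$n_train, curve$n_channels), length)$x
  agg$two_se <- 2 * sds / sqrt(ns)
  agg$n <- ns
  agg
}
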