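#' Multi-voxel ILD classification over repeated half-splits
#'
#' Repeatedly splits the trials of one ROI in half (stratified by ILD
#' class), trains a linear support vector machine (libsvm via e1071,
#' one-vs-one, cost 1) on the training half after per-voxel
#' standardization with training-half statistics, predicts the held-out
#' half, and accumulates a 9 x 9 confusion matrix (rows = presented ILD,
#' columns = predicted ILD).  Per-class accuracy is the diagonal over
#' the row sum; per-class RMS error is the root mean squared difference,
#' in dB, between predicted and presented ILD over that class's test
#' trials.
#'
#' @param tb A [extract_trial_betas()] object filtered to one ROI (no
#'   SILENT or excluded trials), or a list with elements `beta`
#'   (trials x voxels) and `ild` (numeric labels).
#' @param n_repeats Number of half-split repetitions.
#' @param seed Optional integer seed.
#' @param cost SVM regularization constant.
#' @return An object of class `mvpa_result`: `confusion`,
#'   `class_levels`, per-class `accuracy` and `rms`, `overall_accuracy`,
#'   `overall_rms`, `n_repeats`.
#' @export
run_mvpa <- function(tb, n_repeats = 1000, seed = NULL, cost = 1) {
  feat <- as.matrix(tb$beta)
  ild <- tb$ild
  keep <- !is.na(ild) & stats::complete.cases(feat)
  feat <- feat[keep, , drop = FALSE]
  ild <- ild[keep]
  classes <- sort(unique(ild))
  counts <- table(factor(ild, levels = classes))
  if (any(counts < 2))
    stop("every class needs >= 2 trials; short: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (all(apply(feat, 2, function(col) stats::var(col) == 0)))
    stop("features are identical across trials; classifier undefined")
  if (!is.null(seed)) set.seed(seed)
  k <- length(classes)
  conf <- matrix(0, k, k, dimnames = list(target = classes,
                                          predicted = classes))
  y <- factor(ild, levels = classes)
  idx_by_class <- split(seq_along(ild), y)
  for (r in seq_len(n_repeats)) {
    train <- unlist(lapply(idx_by_class, function(ix)
      sample(ix, floor(length(ix) / 2))), use.names = FALSE)
    test <- setdiff(seq_along(ild), train)
    mu <- colMeans(feat[train, , drop = FALSE])
    sdv <- apply(feat[train, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(feat[train, , drop = FALSE], 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(feat[test, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xtr, y[train], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, xte)
    conf <- conf + table(target = y[test],
                         predicted = factor(pred, levels = classes))
  }
  rowsum <- rowSums(conf)
  acc <- diag(conf) / rowsum
  names(acc) <- as.character(classes)
  sqerr <- outer(classes, classes, function(a, b) (b - a)^2)
  structure(list(confusion = conf, class_levels = classes,
                 accuracy = acc, rms = confusion_rms(conf, classes),
                 overall_accuracy = sum(diag(conf)) / sum(conf),
                 overall_rms = sqrt(sum(conf * sqerr) / sum(conf)),
                 n_repeats = n_repeats),
            class = "mvpa_result")
}

#' Per-class RMS decoding error of a confusion matrix
#'
#' Root mean squared difference, in dB, between predicted and presented
#' ILD over each presented class's test trials, weighted by the
#' confusion counts.
#'
#' @param confusion Square count matrix (rows = presented class,
#'   columns = predicted class).
#' @param class_levels Numeric ILD values labelling the rows/columns.
#' @return Named per-class RMS error, dB.
#' @export
confusion_rms <- function(confusion, class_levels) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion),
            length(class_levels) == nrow(confusion))
  sqerr <- outer(class_levels, class_levels, function(a, b) (b - a)^2)
  out <- sqrt(rowSums(confusion * sqerr) / rowSums(confusion))
  names(out) <- as.character(class_levels)
  out
}

#' @export
print.mvpa_result <- function(x, ...) {
  cat(sprintf("mvpa_result: %d classes, %d repeats, overall accuracy %.3f\n",
              length(x$class_levels), x$n_repeats, x$overall_accuracy))
  invisible(x)
}

#' Label-permutation test of MVPA performance
#'
#' Estimates the sampling distribution of classification performance
#' under the null by shuffling ILD labels (within strata if given) and
#' rerunning the half-split classification, then computes add-one
#' permutation p-values: for accuracy
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`; for RMS error the
#' direction is mirrored (smaller is better).
#'
#' @param tb As in [run_mvpa()].
#' @param n_perm Number of label permutations (>= 1).
#' @param n_repeats Half-split repeats per permutation.
#' @param observed_repeats Half-split repeats for the observed statistic
#'   (defaults to `n_repeats`).
#' @param strata Optional factor of length `n_trials`; labels are
#'   shuffled within its levels (e.g. run).
#' @param seed Optional integer seed.
#' @param cost SVM regularization constant.
#' @return List with `observed` (an `mvpa_result`), null matrices
#'   `null_accuracy`, `null_rms` (`n_perm` x classes),
#'   `null_overall_accuracy`, `null_mean_rms`, and p-values
#'   `p_accuracy`, `p_rms`, `p_overall`.
#' @export
permutation_test <- function(tb, n_perm = 1000, n_repeats = 100,
                             observed_repeats = n_repeats, strata = NULL,
                             seed = NULL, cost = 1) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- run_mvpa(tb, n_repeats = observed_repeats, cost = cost)
  k <- length(observed$class_levels)
  null_acc <- matrix(NA_real_, n_perm, k)
  null_rms <- matrix(NA_real_, n_perm, k)
  null_overall <- numeric(n_perm)
  ptb <- list(beta = as.matrix(tb$beta), ild = tb$ild)
  n <- length(ptb$ild)
  if (is.null(strata)) strata <- factor(rep(1, n))
  strata <- factor(strata)
  for (p in seq_len(n_perm)) {
    perm <- seq_len(n)
    for (s in levels(strata)) {
      ix <- which(strata == s)
      perm[ix] <- ix[sample.int(length(ix))]
    }
    null_res <- run_mvpa(list(beta = ptb$beta, ild = ptb$ild[perm]),
                         n_repeats = n_repeats, cost = cost)
    null_acc[p, ] <- null_res$accuracy
    null_rms[p, ] <- null_res$rms
    null_overall[p] <- null_res$overall_accuracy
  }
  colnames(null_acc) <- colnames(null_rms) <-
    as.character(observed$class_levels)
  p_acc <- vapply(seq_len(k), function(j)
    (1 + sum(null_acc[, j] >= observed$accuracy[j])) / (1 + n_perm),
    numeric(1))
  p_rms <- vapply(seq_len(k), function(j)
    (1 + sum(null_rms[, j] <= observed$rms[j])) / (1 + n_perm),
    numeric(1))
  names(p_acc) <- names(p_rms) <- as.character(observed$class_levels)
  list(observed = observed,
       null_accuracy = null_acc, null_rms = null_rms,
       null_overall_accuracy = null_overall,
       null_mean_rms = colMeans(null_rms),
       p_accuracy = p_acc, p_rms = p_rms,
       p_overall = (1 + sum(null_overall >= observed$overall_accuracy)) /
         (1 + n_perm))
}

#' RMS decoding error relative to chance
#'
#' Presents RMS error as `null-mean RMS - observed RMS` per class, so
#' chance performance maps to 0 and positive values indicate decoding
#' better than chance, matching the convention of plotting departures
#' from a 0 chance line.
#'
#' @param result An [run_mvpa()] result.
#' @param null_mean_rms Per-class mean RMS under the permutation null
#'   (e.g. `permutation_test(...)$null_mean_rms`).
#' @return Named per-class relative RMS, dB.
#' @export
rms_relative_to_chance <- function(result, null_mean_rms) {
  stopifnot(inherits(result, "mvpa_result"))
  if (missing(null_mean_rms) || is.null(null_mean_rms))
    stop("permutation null mean RMS is required")
  if (length(null_mean_rms) != length(result$rms))
    stop("null and observed class counts differ")
  null_mean_rms - result$rms
}

#' Paired comparison of decoding accuracy between two ROIs
#'
#' Paired t-test across subjects on per-subject mean accuracies.  The
#' degenerate zero-variance, nonzero-difference case is flagged and
#' reported as `p = 0` with infinite t.
#'
#' @param acc_a,acc_b Per-subject accuracy vectors (matching order; if
#'   both are named the names must agree).
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
compare_roi_accuracy <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    stop("subject counts differ between ROIs")
  if (!is.null(names(acc_a)) && !is.null(names(acc_b)) &&
      !identical(names(acc_a), names(acc_b)))
    stop("subject names differ between ROIs")
  d <- acc_a - acc_b
  n <- length(d)
  if (n < 2) stop("need >= 2 subjects")
  if (stats::sd(d) < 1e-15) {
    if (abs(mean(d)) < 1e-15)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                  degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Write MVPA results as TSV
#'
#' One row per class: accuracy, RMS error (dB), RMS relative to chance,
#' and permutation p-values when a permutation result is supplied.
#'
#' @param perm A [permutation_test()] result (or a bare [run_mvpa()]
#'   result, in which case null-based columns are `NA`).
#' @param path Output file path.
#' @param roi,hemisphere,mode Optional annotation columns.
#' @return The written data frame, invisibly.
#' @export
write_mvpa_tsv <- function(perm, path, roi = NA, hemisphere = NA,
                           mode = NA) {
  if (inherits(perm, "mvpa_result")) {
    res <- perm
    rel <- rep(NA_real_, length(res$rms))
    p_acc <- p_rms <- rep(NA_real_, length(res$rms))
  } else {
    res <- perm$observed
    rel <- rms_relative_to_chance(res, perm$null_mean_rms)
    p_acc <- perm$p_accuracy
    p_rms <- perm$p_rms
  }
  df <- data.frame(roi = roi, hemisphere = hemisphere, mode = mode,
                   class = res$class_levels, accuracy = res$accuracy,
                   rms_db = res$rms, rms_rel_chance = rel,
                   p_acc = p_acc, p_rms = p_rms)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
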