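#' Per-condition mean betas for one subject
#'
#' Betas are averaged across voxels within the (already filtered) ROI
#' per trial, then across trials per ILD condition.
#'
#' @param tb A [extract_trial_betas()] object, typically filtered to one
#'   ROI/hemisphere with [filter_betas()].
#' @param levels ILD levels expected in the data.
#' @return Named numeric vector of condition means, ordered by level.
#' @export
condition_means <- function(tb, levels = ild_levels()) {
  stopifnot(inherits(tb, "trial_betas"))
  keep <- !tb$excluded & !tb$is_warmup & tb$condition != "SILENT" &
    !is.na(tb$ild)
  trial_mean <- rowMeans(tb$beta[keep, , drop = FALSE])
  ild <- tb$ild[keep]
  out <- vapply(levels, function(l) {
    v <- trial_mean[ild == l]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  names(out) <- as.character(levels)
  out
}

#' Group ILD tuning function
#'
#' Builds the per-subject condition-mean matrix and the across-subject
#' group curve (mean and SEM at each of the nine ILD levels).
#'
#' @param x A list of per-subject `trial_betas` objects, or a numeric
#'   subjects x levels matrix of per-subject condition means.
#' @param levels ILD levels (columns of the result).
#' @param roi,hemisphere,mode Optional labels stored on the result.
#' @return An object of class `tuning_function`: list with
#'   `per_subject` (subjects x levels matrix) and `curve` (data frame
#'   `ild`, `mean`, `sem`).
#' @export
compute_tuning <- function(x, levels = ild_levels(), roi = NA,
                           hemisphere = NA, mode = NA) {
  if (is.list(x) && !is.data.frame(x)) {
    per_subject <- t(vapply(seq_along(x), function(i) {
      m <- condition_means(x[[i]], levels)
      if (anyNA(m))
        stop(sprintf("subject %d is missing condition(s): %s", i,
                     paste(names(m)[is.na(m)], collapse = ", ")))
      m
    }, numeric(length(levels))))
  } else {
    per_subject <- as.matrix(x)
    if (ncol(per_subject) != length(levels))
      stop("matrix input must have one column per ILD level")
    if (anyNA(per_subject)) stop("missing condition means in input")
  }
  colnames(per_subject) <- as.character(levels)
  n <- nrow(per_subject)
  mu <- colMeans(per_subject)
  sem <- if (n > 1) apply(per_subject, 2, stats::sd) / sqrt(n)
         else rep(0, length(levels))
  structure(list(per_subject = per_subject,
                 curve = data.frame(ild = levels, mean = mu, sem = sem),
                 roi = roi, hemisphere = hemisphere, mode = mode),
            class = "tuning_function")
}

#' One-way repeated-measures ANOVA across ILD levels
#'
#' Tests the main effect of ILD on the per-subject condition means with
#' subject as the repeated factor; `F` carries `(k - 1, (k - 1)(n - 1))`
#' degrees of freedom for `k` levels and `n` subjects.  Implemented as
#' the two-way ANOVA without replication `value ~ subject + level`.
#' Degenerate inputs with zero residual variance return `F = 0, p = 1`
#' when the level effect is also zero.
#'
#' @param x A [compute_tuning()] object or a subjects x levels matrix.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_ild <- function(x) {
  m <- if (inherits(x, "tuning_function")) x$per_subject else as.matrix(x)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("repeated-measures ANOVA needs >= 2 subjects")
  if (anyNA(m)) stop("incomplete cells in subject x level matrix")
  d <- data.frame(value = as.vector(m),
                  subject = factor(rep(seq_len(n), times = k)),
                  level = factor(rep(seq_len(k), each = n)))
  # a perfect fit (constant input) raises a spurious warning; the zero
  # residual-SS case is handled explicitly below
  an <- suppressWarnings(
    stats::anova(stats::lm(value ~ subject + level, data = d)))
  ss_level <- an["level", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  tol <- 1e-12 * max(1, sum(m^2))
  if (ss_err <= tol) {
    if (ss_level <= tol) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- (ss_level / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Default side groups over the nine ILD levels
#'
#' @return Named list partitioning the levels into leftward, center and
#'   rightward triplets.
#' @export
side_groups <- function() {
  list(left = c(-30, -20, -10), center = c(-5, 0, 5),
       right = c(10, 20, 30))
}

#' Full-cue vs onset-only side-group contrasts with FDR control
#'
#' For each side group (leftward, center, rightward ILD triplets) the
#' per-subject mean beta is compared between stimulus modes with a
#' paired t-test; p-values are Benjamini-Hochberg adjusted across the
#' rows of the returned table.  To control FDR across a larger family
#' (ROIs x hemispheres), bind the unadjusted rows from several calls
#' (`adjust = FALSE`) and use [adjust_contrast_family()].
#'
#' @param full,onset [compute_tuning()] objects for the two modes, with
#'   subjects in matching row order.
#' @param groups Named list of ILD-level groups.
#' @param q FDR level for the `discovery` flag.
#' @param adjust Apply BH adjustment across this table's rows.
#' @return Data frame with one row per group: subject means per mode,
#'   paired `t`, `df`, `p`, adjusted `p_fdr`, and `discovery`.
#' @export
side_contrast <- function(full, onset, groups = side_groups(), q = 0.05,
                          adjust = TRUE) {
  stopifnot(inherits(full, "tuning_function"),
            inherits(onset, "tuning_function"))
  a <- full$per_subject
  b <- onset$per_subject
  if (!all(dim(a) == dim(b)))
    stop("subject sets differ between modes")
  rows <- lapply(names(groups), function(g) {
    cols <- as.character(groups[[g]])
    x <- rowMeans(a[, cols, drop = FALSE])
    y <- rowMeans(b[, cols, drop = FALSE])
    d <- x - y
    n <- length(d)
    if (stats::sd(d) < 1e-12 * max(1, mean(abs(c(x, y))))) {
      tt <- list(statistic = 0, parameter = n - 1,
                 p.value = if (abs(mean(d)) < 1e-12) 1 else 0)
      if (abs(mean(d)) >= 1e-12) tt$statistic <- sign(mean(d)) * Inf
    } else {
      ht <- stats::t.test(x, y, paired = TRUE)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(group = g, mean_full = mean(x), mean_onset = mean(y),
               t = tt$statistic, df = tt$parameter, p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$p_fdr <- stats::p.adjust(out$p, method = "BH")
    out$discovery <- out$p_fdr <= q
  }
  out
}

#' BH-adjust a family of side contrasts
#'
#' @param tables List of unadjusted [side_contrast()] tables (e.g. one
#'   per ROI/hemisphere).
#' @param q FDR level.
#' @return Single data frame with `p_fdr` and `discovery` computed
#'   across the whole family.
#' @export
adjust_contrast_family <- function(tables, q = 0.05) {
  out <- do.call(rbind, tables)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$discovery <- out$p_fdr <= q
  out
}

#' Scaled "physical cue" null tuning curve
#'
#' Scales the modulation of a tuning curve about its mean by `factor`
#' while keeping the mean: with `factor = 1/16` this is the hypothetical
#' tuning expected if responses followed the average physical ILD of an
#' onset-only train (one cue-bearing click in sixteen), a near-flat
#' curve.
#'
#' @param tuning A [compute_tuning()] object.
#' @param factor Modulation scaling factor.
#' @return A `tuning_function` with scaled modulation (per-subject rows
#'   scaled about their own means; SEM scaled accordingly).
#' @export
scaled_null_curve <- function(tuning, factor = 1 / 16) {
  stopifnot(inherits(tuning, "tuning_function"), is.finite(factor))
  out <- tuning
  ps <- tuning$per_subject
  out$per_subject <- t(apply(ps, 1, function(r) mean(r) + (r - mean(r)) * factor))
  colnames(out$per_subject) <- colnames(ps)
  m <- mean(tuning$curve$mean)
  out$curve$mean <- m + (tuning$curve$mean - m) * factor
  out$curve$sem <- tuning$curve$sem * abs(factor)
  out
}

#' Peak-to-peak modulation depth of a tuning curve
#'
#' @param tuning A [compute_tuning()] object or numeric curve.
#' @return `max - min` of the group-mean curve.
#' @export
modulation_depth <- function(tuning) {
  v <- if (inherits(tuning, "tuning_function")) tuning$curve$mean
       else as.numeric(tuning)
  max(v) - min(v)
}
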