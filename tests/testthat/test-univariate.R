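test_that("tuning curves aggregate subject condition means correctly", {
  # single subject with a constant curve: SEM identically zero
  m1 <- matrix(2, 1, 9)
  tf1 <- compute_tuning(m1)
  expect_equal(tf1$curve$mean, rep(2, 9))
  expect_equal(tf1$curve$sem, rep(0, 9))
  # two subjects with curves c and -c: group mean zero everywhere
  c1 <- seq(-4, 4)
  tf2 <- compute_tuning(rbind(c1, -c1))
  expect_equal(tf2$curve$mean, rep(0, 9))
  # concatenation equals the weighted mean of subgroup curves
  set.seed(21)
  a <- matrix(rnorm(3 * 9), 3, 9)
  b <- matrix(rnorm(6 * 9), 6, 9)
  lhs <- compute_tuning(rbind(a, b))$curve$mean
  rhs <- (3 * compute_tuning(a)$curve$mean +
            6 * compute_tuning(b)$curve$mean) / 9
  expect_equal(lhs, rhs)
})

test_that("missing conditions are reported by subject and condition", {
  px <- quick_pipeline(seed = 51, n_vox = 3)
  broken <- px$tb
  drop <- broken$condition == "30"
  broken$beta <- broken$beta[!drop, , drop = FALSE]
  broken$condition <- broken$condition[!drop]
  broken$ild <- broken$ild[!drop]
  broken$excluded <- broken$excluded[!drop]
  broken$is_warmup <- broken$is_warmup[!drop]
  expect_error(compute_tuning(list(broken)), "subject 1.*30")
})

test_that("simulated HG-profile tuning dips at intermediate ipsilateral ILD", {
  pxs <- lapply(1:4, function(s)
    quick_pipeline(seed = 60 + s, roi = "HG", hemisphere = "L",
                   n_vox = 50, pair_multiplicity = 2)$tb)
  tf <- compute_tuning(pxs, roi = "HG", hemisphere = "L",
                       mode = "full_cue")
  mu <- tf$curve$mean
  names(mu) <- as.character(ild_levels())
  # left hemisphere: contralateral (+30) maximum, ipsilateral minimum
  expect_equal(names(which.max(mu)), "30")
  expect_lt(min(mu[c("-30", "-20", "-10", "-5")]), mu["30"] - 0.1)
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(22)
  m <- matrix(rnorm(6 * 9), 6, 9) + outer(rnorm(6), rep(0, 9), "+")
  res <- rm_anova_ild(m)
  # independent oracle: partition SS_total into subject, level, error
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  ss_lev <- n * sum((colMeans(m) - g)^2)
  ss_sub <- k * sum((rowMeans(m) - g)^2)
  ss_err <- sum((m - g)^2) - ss_lev - ss_sub
  f_oracle <- (ss_lev / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$df1, 8)
  expect_equal(res$df2, 40)
  expect_equal(res$p, pf(f_oracle, 8, 40, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA degenerate and power cases behave as expected", {
  # identical constant curves: F = 0, p = 1
  res0 <- rm_anova_ild(matrix(5, 4, 9))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_error(rm_anova_ild(matrix(1, 1, 9)), ">= 2")
  mna <- matrix(1, 3, 9); mna[2, 4] <- NA
  expect_error(rm_anova_ild(mna), "incomplete")
  # planted strong tuning is detected in every seeded replicate
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(9 * 9, sd = 0.5), 9, 9) +
      matrix(seq(0, 2, length.out = 9), 9, 9, byrow = TRUE)
    rm_anova_ild(m)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("side contrasts flag planted mode differences with FDR control", {
  # identical modes: all t = 0, no discoveries
  set.seed(23)
  m <- matrix(rnorm(9 * 9), 9, 9)
  colnames(m) <- as.character(ild_levels())
  tf <- compute_tuning(m)
  same <- side_contrast(tf, tf)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  expect_false(any(same$discovery))

  # planted lateral full-cue advantage: left/right discovered, center not
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    base <- matrix(rnorm(9 * 9, sd = 0.3), 9, 9)
    lateral_boost <- matrix(rep(c(1, 1, 1, 0, 0, 0, 1, 1, 1), each = 9), 9, 9)
    full <- compute_tuning(base + 0.6 * lateral_boost)
    onset <- compute_tuning(matrix(rnorm(9 * 9, sd = 0.3), 9, 9))
    sc <- side_contrast(full, onset)
    all(sc$discovery[sc$group %in% c("left", "right")])
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # planted onset-only midline bump: center discovered, onset > full
  set.seed(24)
  base <- matrix(rnorm(9 * 9, sd = 0.2), 9, 9)
  bump <- matrix(rep(c(0, 0, 0, 1, 1, 1, 0, 0, 0), each = 9), 9, 9)
  full <- compute_tuning(base)
  onset <- compute_tuning(base + 0.8 * bump +
                            matrix(rnorm(9 * 9, sd = 0.2), 9, 9))
  sc <- side_contrast(full, onset)
  ctr <- sc[sc$group == "center", ]
  expect_true(ctr$discovery)
  expect_lt(ctr$t, 0)   # full - onset negative: onset responses larger

  # family-level adjustment across several tables
  fam <- adjust_contrast_family(list(side_contrast(full, onset, adjust = FALSE),
                                     side_contrast(tf, tf, adjust = FALSE)))
  expect_equal(nrow(fam), 6)
  expect_true(all(c("p_fdr", "discovery") %in% names(fam)))

  bad <- compute_tuning(matrix(rnorm(5 * 9), 5, 9))
  expect_error(side_contrast(full, bad), "subject sets differ")
})

test_that("the scaled physical-cue null curve rescales modulation only", {
  flat <- compute_tuning(matrix(3, 4, 9))
  expect_equal(scaled_null_curve(flat)$curve$mean, rep(3, 9))
  set.seed(25)
  tf <- compute_tuning(matrix(rnorm(4 * 9), 4, 9))
  expect_equal(scaled_null_curve(tf, factor = 1)$curve$mean,
               tf$curve$mean)
  sc <- scaled_null_curve(tf, factor = 1 / 16)
  expect_equal(modulation_depth(sc), modulation_depth(tf) / 16)
  expect_equal(mean(sc$curve$mean), mean(tf$curve$mean))
})
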