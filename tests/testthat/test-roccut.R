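test_that("AUC equals the tie-corrected concordance probability", {
  expect_equal(compute_roc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(compute_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(compute_roc(rep(3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  # curve structure: (0,0) to (1,1), monotone, trapezoid area == auc
  set.seed(5)
  inst <- rand_binary(25, tied = TRUE)
  roc <- compute_roc(inst$scores, inst$labels)
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]), c(1, 1))
  expect_false(is.unsorted(roc$fpr))
  expect_false(is.unsorted(roc$tpr))
  trapz <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-length(roc$tpr)]) / 2)
  expect_equal(roc$auc, trapz, tolerance = 1e-12)

  expect_error(compute_roc(1:3, c(1, 1, 1)), "both classes")
  expect_error(compute_roc(1:3, c(0, 1)), "equal length")
})

test_that("rank-sum p-values: exact enumeration, ties, and the approximation", {
  expect_equal(mann_whitney_p(c(1, 2, 3, 4), c(0, 0, 1, 1), "exact"), 2 / 6)
  expect_equal(mann_whitney_p(c(5, 5, 5, 5), c(0, 0, 1, 1)), 1)

  # approximation close to exact at n = 8 balanced
  set.seed(8)
  x <- stats::rnorm(8)
  l <- rep(c(0, 1), 4)
  expect_lt(abs(mann_whitney_p(x, l, "exact") -
                mann_whitney_p(x, l, "normal_approx")), 0.05)

  expect_error(mann_whitney_p(stats::rnorm(14), rep(0:1, 7), "exact"),
               "n <= 12")
  expect_gt(mann_whitney_p(c(rep(0, 6), rep(100, 6)), rep(0:1, each = 6)), 0)
})

test_that("rank-sum p-values agree with wilcox.test in both regimes", {
  # exact path vs wilcox.test exact (no ties so the reference is exact too)
  set.seed(11)
  for (i in 1:25) {
    inst <- rand_binary(sample(4:10, 1), tied = FALSE)
    expect_equal(mann_whitney_p(inst$scores, inst$labels, "exact"),
                 stats::wilcox.test(inst$scores[inst$labels == 1],
                                    inst$scores[inst$labels == 0],
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # tie-corrected continuity-corrected normal path vs wilcox.test
  for (i in 1:25) {
    inst <- rand_binary(sample(15:40, 1), tied = TRUE)
    if (length(unique(inst$scores)) == 1L) next
    expect_equal(mann_whitney_p(inst$scores, inst$labels, "normal_approx"),
                 suppressWarnings(
                   stats::wilcox.test(inst$scores[inst$labels == 1],
                                      inst$scores[inst$labels == 0],
                                      exact = FALSE,
                                      correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("AUC matches pROC and is invariant to monotone transforms", {
  set.seed(21)
  for (i in 1:20) {
    inst <- rand_binary(sample(20:60, 1), tied = i %% 2 == 0)
    roc <- compute_roc(inst$scores, inst$labels)
    expect_equal(roc$auc,
                 as.numeric(pROC::auc(pROC::roc(
                   inst$labels, inst$scores, direction = "<",
                   quiet = TRUE))),
                 tolerance = 1e-12)
    # strictly increasing transform: same auc and rank-sum p
    tr <- exp(inst$scores / 4)
    expect_equal(compute_roc(tr, inst$labels)$auc, roc$auc, tolerance = 1e-12)
    expect_equal(mann_whitney_p(tr, inst$labels),
                 mann_whitney_p(inst$scores, inst$labels), tolerance = 1e-12)
    # label swap: auc -> 1 - auc, p unchanged
    expect_equal(compute_roc(inst$scores, 1 - inst$labels)$auc, 1 - roc$auc,
                 tolerance = 1e-12)
    expect_equal(mann_whitney_p(inst$scores, 1 - inst$labels),
                 mann_whitney_p(inst$scores, inst$labels), tolerance = 1e-12)
  }
})

test_that("Youden cutoffs: worked examples, exhaustive-scan oracle, shift rule", {
  res <- derive_cutoff(c(10, 20, 100, 200), c(0, 0, 1, 1))
  expect_equal(res$cutoff, 60)   # midpoint convention (20 + 100) / 2
  expect_equal(res$auc, 1.0)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)

  # overlapping classes: brute force over all midpoints, lowest on ties
  sc <- c(1, 2, 3, 4, 3, 4, 5, 6)
  lb <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_equal(derive_cutoff(sc, lb)$cutoff, oracle_youden_scan(sc, lb))
  set.seed(33)
  for (i in 1:30) {
    inst <- rand_binary(sample(6:20, 1), tied = TRUE)
    if (length(unique(inst$scores)) < 2L) next
    expect_equal(derive_cutoff(inst$scores, inst$labels)$cutoff,
                 oracle_youden_scan(inst$scores, inst$labels))
    # adding a constant shifts the cutoff by exactly that constant
    expect_equal(derive_cutoff(inst$scores + 13.5, inst$labels)$cutoff,
                 derive_cutoff(inst$scores, inst$labels)$cutoff + 13.5)
  }
  expect_error(derive_cutoff(rep(2, 4), c(0, 0, 1, 1)), "identical")
})

test_that("fixed-specificity cutoffs respect the specificity floor", {
  neg <- 1:10
  pos <- c(8, 9, 10, 11, 12)
  sc <- c(neg, pos)
  lb <- c(rep(0, 10), rep(1, 5))
  res <- derive_cutoff(sc, lb, criterion = "fixed_specificity",
                       spec_level = 0.9)
  expect_gte(res$specificity, 0.9)
  # brute check: maximal sensitivity among qualifying midpoints
  s <- sort(unique(sc))
  mids <- (s[-length(s)] + s[-1]) / 2
  ok <- mids[vapply(mids, function(cm) mean(neg >= cm) <= 0.1, logical(1))]
  best_sens <- max(vapply(ok, function(cm) mean(pos >= cm), numeric(1)))
  expect_equal(res$sensitivity, best_sens)
  # the top score belongs to a negative: no candidate reaches the floor
  expect_warning(
    derive_cutoff(c(1, 5, 2, 3), c(0, 0, 1, 1),
                  criterion = "fixed_specificity", spec_level = 0.9),
    "specific")
})

test_that("cross-cohort consistency flags agreeing and disagreeing cutoffs", {
  co <- list(scores = c(500, 520, 480, 1490, 1500, 1510),
             labels = c(0, 0, 0, 1, 1, 1))
  rep1 <- cross_cohort_consistency(list(co, co, co), tolerance = 0.10)
  expect_equal(rep1$max_pairwise_relative_difference, 0)
  expect_true(rep1$consistent)

  far <- list(scores = c(1500, 1600, 1400, 4400, 4500, 4600),
              labels = c(0, 0, 0, 1, 1, 1))
  rep2 <- cross_cohort_consistency(list(co, far), tolerance = 0.10)
  expect_false(rep2$consistent)
  expect_error(cross_cohort_consistency(list(co)), "at least two")
})

test_that("HER2 ROC analysis settings pick the right samples and classes", {
  fx <- six_label_fixture()
  pos <- her2_roc_analysis(fx$expression, fx$clinical, "pos_vs_low")
  expect_equal(pos$cutoff, (2500 + 4000) / 2)
  expect_equal(pos$n_high_class, 2L)  # two IHC/FISH-positive samples
  ul <- her2_roc_analysis(fx$expression, fx$clinical, "low_vs_ultralow")
  expect_equal(ul$cutoff, (1000 + 2500) / 2)

  # FISH < 2 restriction drops the FISH-amplified positives unless one has
  # a low ratio on record
  cl <- fx$clinical
  cl$fish_ratio[1] <- 1.8
  cl$fish_status[1] <- "negative"  # IHC 3+ still positive by IHC
  f3 <- her2_roc_analysis(fx$expression, cl, "pos_vs_low_fishlt2")
  expect_equal(f3$n_high_class, 1L)
  expect_equal(f3$n_low_class, 2L)

  both <- derive_her2_cutoffs(fx$expression, fx$clinical)
  expect_s3_class(both$cuts, "her2_cutoffs")
  expect_lt(both$cuts$cut_ultralow, both$cuts$cut_positive)
  expect_error(her2_roc_analysis(fx$expression[2, , drop = FALSE],
                                 fx$clinical, "pos_vs_low"),
               "216836_s_at")
})
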