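# Small direct fixture: an assignment table over n samples with a chosen
# subgroup membership, plus an expression matrix built per test.
mk_assignments <- function(member, subgroup = "HR-/HER2-low") {
  n <- length(member)
  labels <- ifelse(member, subgroup, "HR+/HER2-low")
  asg <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    hr = factor(ifelse(grepl("^HR\\+", labels), "positive", "negative"),
                levels = c("negative", "positive")),
    her2 = factor("low", levels = c("ultralow", "low", "positive")),
    label = factor(labels, levels = subgroup_labels()),
    stringsAsFactors = FALSE)
  class(asg) <- c("subgroup_assignment", "data.frame")
  asg
}

test_that("a strongly shifted gene is significant and up; a null gene is not", {
  set.seed(2)
  n <- 500
  member <- c(rep(TRUE, 50), rep(FALSE, 450))
  shifted <- stats::rnorm(n, 100, 10)
  shifted[member] <- shifted[member] + 5 * 10   # +5 within-gene SDs
  flat <- rep(42, n)
  null_gene <- stats::rnorm(n, 100, 10)
  expr <- rbind(g_shift = shifted, g_flat = flat, g_null = null_gene)
  colnames(expr) <- sprintf("S%04d", seq_len(n))
  asg <- mk_assignments(member)

  a <- gene_association(expr, asg, "g_shift", "HR-/HER2-low")
  expect_true(a$significant)
  expect_identical(a$direction, "up")
  expect_gt(a$auc, 0.95)

  a0 <- gene_association(expr, asg, "g_flat", "HR-/HER2-low")
  expect_false(a0$significant)
  expect_equal(a0$auc, 0.5)
  expect_equal(a0$p_value, 1)

  an <- gene_association(expr, asg, "g_null", "HR-/HER2-low")
  expect_false(an$significant)

  expect_error(gene_association(expr, asg, "nope", "HR-/HER2-low"), "absent")
  expect_error(gene_association(expr, asg, "g_null", "HR-/HER2+"), "empty")
})

test_that("the dual criterion requires both the p and the AUC condition", {
  # perfect separation at tiny n: AUC = 1 but the exact p cannot reach 0.01
  member <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expr <- rbind(g = c(10, 9, 1, 2, 3))
  colnames(expr) <- sprintf("S%04d", 1:5)
  a <- gene_association(expr, mk_assignments(member), "g", "HR-/HER2-low")
  expect_equal(a$auc, 1)
  expect_gt(a$p_value, 0.01)
  expect_false(a$significant)

  # tiny p but AUC below the bar fails too: simulate a mild shift at large n
  set.seed(9)
  n <- 4000
  member2 <- rep(c(TRUE, FALSE), n / 2)
  g2 <- stats::rnorm(n)
  g2[member2] <- g2[member2] + 0.25
  expr2 <- rbind(g = g2)
  colnames(expr2) <- sprintf("S%04d", seq_len(n))
  a2 <- gene_association(expr2, mk_assignments(member2), "g", "HR-/HER2-low")
  expect_lt(a2$p_value, 0.01)
  expect_lt(max(a2$auc, 1 - a2$auc), 0.6)
  expect_false(a2$significant)
})

test_that("the batch association table matches the single-gene path", {
  set.seed(31)
  n <- 60
  expr <- matrix(stats::rlnorm(20 * n, 5, 1), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("S%04d", seq_len(n))))
  member <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
  asg <- mk_assignments(member)
  tab <- gene_association_table(expr, asg)
  expect_setequal(unique(tab$subgroup), c("HR-/HER2-low", "HR+/HER2-low"))
  for (i in sample(nrow(tab), 12)) {
    single <- gene_association(expr, asg, tab$gene[i], tab$subgroup[i])
    expect_equal(tab$auc[i], single$auc, tolerance = 1e-12)
    expect_equal(tab$p_value[i], single$p_value, tolerance = 1e-12)
    expect_identical(tab$significant[i], single$significant)
  }
})

test_that("signature activation cells count measured genes only", {
  set.seed(7)
  n <- 300
  member <- c(rep(TRUE, 60), rep(FALSE, 240))
  mk_gene <- function(shift) {
    g <- stats::rnorm(n, 50, 5)
    g[member] <- g[member] + shift
    g
  }
  expr <- rbind(hit1 = mk_gene(25), hit2 = mk_gene(25), null1 = mk_gene(0),
                null2 = mk_gene(0))
  colnames(expr) <- sprintf("S%04d", seq_len(n))
  asg <- mk_assignments(member, "HR-/HER2-ultralow")

  sigs <- list(mixed = c("hit1", "hit2", "null1", "null2", "absent_a",
                         "absent_b"),
               solo = "hit1")
  expect_message(
    act <- signature_activation_matrix(expr, asg, sigs), "absent")
  expect_equal(act$n_measured[["mixed"]], 4L)
  expect_equal(act$fraction["mixed", "HR-/HER2-ultralow"], 0.5)
  expect_equal(act$fraction_up["mixed", "HR-/HER2-ultralow"], 0.5)
  expect_equal(act$fraction["solo", "HR-/HER2-ultralow"], 1.0)
  # complement subgroup sees the same genes as "down", never as "up"
  expect_equal(act$fraction_up["solo", "HR+/HER2-low"], 0)

  expect_error(signature_activation_matrix(expr, asg,
                                           list(gone = c("x", "y"))),
               "gone")
})

test_that("activation cells are invariant to gene and sample order", {
  set.seed(17)
  n <- 120
  member <- sample(c(TRUE, FALSE), n, replace = TRUE)
  expr <- matrix(stats::rlnorm(10 * n, 4, 0.8), 10, n,
                 dimnames = list(paste0("g", 1:10),
                                 sprintf("S%04d", seq_len(n))))
  expr[1:3, member] <- expr[1:3, member] * 3
  asg <- mk_assignments(member)
  sigs <- list(s = paste0("g", 1:6))
  a1 <- signature_activation_matrix(expr, asg, sigs)
  perm <- sample(n)
  a2 <- signature_activation_matrix(expr[sample(10), perm], asg,
                                    list(s = paste0("g", sample(1:6))))
  expect_equal(a1$fraction, a2$fraction)
  expect_equal(a1$fraction_up, a2$fraction_up)
})

test_that("overlap fractions follow set arithmetic under both methods", {
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b"), "min_set"), 1)
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b"), "jaccard"), 1)
  expect_equal(overlap_fraction(c("a"), c("b"), "min_set"), 0)
  expect_equal(overlap_fraction(c("a"), c("b"), "jaccard"), 0)
  expect_equal(overlap_fraction(c("x", "y", "z"), c("y", "z", "w"),
                                "jaccard"), 0.5)
  expect_equal(overlap_fraction(c("x", "y", "z"), c("y", "z", "w"),
                                "min_set"), 2 / 3)
  expect_equal(overlap_fraction(character(0), c("a")), 0)
  expect_error(overlap_fraction(character(0), character(0)), "undefined")
  # duplicates do not inflate the sets
  expect_equal(overlap_fraction(c("a", "a", "b"), c("b", "b"), "min_set"), 1)
})
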