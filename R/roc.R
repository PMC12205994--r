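# ROC curves, AUC, rank-sum p-values, and ROC-based cutoff derivation for
# calibrating marker thresholds (HER2-positive and HER2-ultralow boundaries)
# against IHC/FISH-defined class labels, plus the cross-cohort consistency
# check used to argue that a derived cutoff transfers between datasets.

.check_binary <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not contain NA")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n1 <- sum(labels == 1)
  if (n1 == 0L || n1 == length(labels))
    stop("both classes must be non-empty")
  invisible(TRUE)
}

#' Empirical ROC curve and AUC
#'
#' Computes the empirical receiver operating characteristic of `scores`
#' against binary `labels` (1 = high class) under the convention that a
#' sample is called positive when its score is at or above the threshold.
#' The AUC equals the tie-corrected concordance probability: the fraction of
#' (positive, negative) pairs in which the positive sample outscores the
#' negative one, ties counted half.
#'
#' @param scores Numeric marker values.
#' @param labels Binary class labels (0/1), same length; both classes must be
#'   present.
#' @return An object of class `roc_curve`: descending `thresholds` (starting
#'   at `Inf`), matching `fpr` and `tpr` sequences from (0,0) to (1,1), and
#'   the trapezoidal `auc`.
#' @examples
#' compute_roc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
compute_roc <- function(scores, labels) {
  .check_binary(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n1 <- sum(l == 1)
  n0 <- length(l) - n1
  last <- which(!duplicated(s, fromLast = TRUE))  # collapse tied scores
  tpr <- c(0, cumsum(l == 1)[last] / n1)
  fpr <- c(0, cumsum(l == 0)[last] / n0)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, s[!duplicated(s)]),
                 fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", length(x$fpr), "operating points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Two-sided Mann-Whitney rank-sum p-value
#'
#' Two-sided p-value for the rank-sum (Mann-Whitney U) comparison of the two
#' label classes. `exact` enumerates every assignment of the observed scores
#' to the two groups (feasible up to n = 12 in total) and reports the
#' probability of a U at least as extreme as observed; `normal_approx` uses
#' the tie-corrected normal approximation with continuity correction; `auto`
#' (default) chooses exact when feasible. P-values are floored at the smallest
#' representable positive double, never truncated to zero.
#'
#' @inheritParams compute_roc
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return A p-value in (0, 1].
#' @examples
#' mann_whitney_p(c(1, 2, 3, 4), c(0, 0, 1, 1), mode = "exact")  # 2/6
#' @export
mann_whitney_p <- function(scores, labels,
                           mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  .check_binary(scores, labels)
  n <- length(scores)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  r <- rank(scores)
  u1 <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  mu <- n1 * n0 / 2
  if (mode == "auto") mode <- if (n <= 12L) "exact" else "normal_approx"
  if (mode == "exact") {
    if (n > 12L) stop("exact enumeration is limited to n <= 12")
    idx <- utils::combn(n, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u1 - mu) - 1e-9)
  } else {
    tie <- rle(sort(r))$lengths
    v <- n1 * n0 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (v <= 0) return(1)  # all scores tied: no separation
    z <- max((abs(u1 - mu) - 0.5) / sqrt(v), 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

# Candidate cutoffs (midpoints of adjacent distinct scores) with the tpr/fpr
# each achieves under the "score >= cutoff is high class" convention.
.cutoff_candidates <- function(scores, labels) {
  s <- sort(unique(scores))
  if (length(s) < 2L)
    stop("cannot derive a cutoff: all scores are identical")
  f <- factor(scores, levels = s)
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  c1 <- tapply(labels == 1, f, sum, default = 0)
  c0 <- tapply(labels == 0, f, sum, default = 0)
  m <- length(s)
  list(mids = (s[-m] + s[-1]) / 2,
       tpr = unname((n1 - cumsum(c1)[-m]) / n1),
       fpr = unname((n0 - cumsum(c0)[-m]) / n0),
       n1 = n1, n0 = n0)
}

#' Derive a marker cutoff from the ROC
#'
#' Selects the operating point of the empirical ROC and reports the cutoff as
#' the midpoint between the two adjacent distinct observed scores bracketing
#' it, so that neither "at or above" nor "strictly above" can flip any
#' training sample. `youden` maximizes sensitivity + specificity - 1 (ties
#' broken toward the lowest cutoff, favouring sensitivity);
#' `fixed_specificity` maximizes sensitivity subject to specificity at or
#' above `spec_level` (falling back, with a warning, to the most specific
#' candidate if none qualifies). The rank-sum p-value accompanies the cutoff
#' as evidence that the classes differ at all.
#'
#' @inheritParams compute_roc
#' @param criterion `"youden"` (default) or `"fixed_specificity"`.
#' @param spec_level Minimum specificity for `fixed_specificity`.
#' @return An object of class `cutoff_result`: `cutoff`, `auc`, `p_value`,
#'   `n_high_class`, `n_low_class`, `criterion`, and the operating
#'   `sensitivity`/`specificity`.
#' @examples
#' derive_cutoff(c(10, 20, 100, 200), c(0, 0, 1, 1))$cutoff  # 60
#' @export
derive_cutoff <- function(scores, labels,
                          criterion = c("youden", "fixed_specificity"),
                          spec_level = 0.90) {
  criterion <- match.arg(criterion)
  .check_binary(scores, labels)
  cand <- .cutoff_candidates(scores, labels)
  if (criterion == "youden") {
    j <- cand$tpr - cand$fpr
    pick <- which(j >= max(j) - 1e-12)[1L]  # lowest cutoff on ties
  } else {
    ok <- which(1 - cand$fpr >= spec_level - 1e-12)
    if (length(ok)) {
      pick <- ok[which.max(cand$tpr[ok])]  # first = lowest cutoff on ties
    } else {
      warning("no cutoff reaches specificity ", spec_level,
              "; using the most specific candidate")
      pick <- which(cand$fpr == min(cand$fpr))[1L]
    }
  }
  roc <- compute_roc(scores, labels)
  structure(list(cutoff = cand$mids[pick],
                 auc = roc$auc,
                 p_value = mann_whitney_p(scores, labels),
                 n_high_class = cand$n1,
                 n_low_class = cand$n0,
                 criterion = criterion,
                 sensitivity = cand$tpr[pick],
                 specificity = 1 - cand$fpr[pick]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "Cutoff %.6g (%s): AUC %.4f, p %.3g, sens %.3f, spec %.3f (n = %d/%d)\n",
    x$cutoff, x$criterion, x$auc, x$p_value, x$sensitivity, x$specificity,
    x$n_high_class, x$n_low_class))
  invisible(x)
}

#' Cross-cohort cutoff consistency
#'
#' Derives a cutoff independently in each cohort and reports whether every
#' pairwise relative difference (absolute difference divided by the pair
#' mean) stays within `tolerance` -- the reproducibility argument for
#' transferring a calibration-cohort cutoff to a larger database.
#'
#' @param cohorts List of at least two cohorts, each a list with `scores` and
#'   `labels`.
#' @param criterion,spec_level Passed to [derive_cutoff()].
#' @param tolerance Maximum tolerated pairwise relative difference.
#' @return An object of class `consistency_report`: per-cohort `results`,
#'   `max_pairwise_relative_difference`, `tolerance`, `consistent`.
#' @export
cross_cohort_consistency <- function(cohorts, criterion = "youden",
                                     tolerance = 0.10, spec_level = 0.90) {
  if (!is.list(cohorts) || length(cohorts) < 2L)
    stop("need at least two cohorts")
  results <- lapply(cohorts, function(co)
    derive_cutoff(co$scores, co$labels, criterion, spec_level))
  cuts <- vapply(results, `[[`, numeric(1L), "cutoff")
  reldiff <- abs(outer(cuts, cuts, `-`)) /
    outer(cuts, cuts, function(a, b) (a + b) / 2)
  maxd <- max(reldiff)
  structure(list(results = results,
                 cutoffs = cuts,
                 max_pairwise_relative_difference = maxd,
                 tolerance = tolerance,
                 consistent = maxd <= tolerance),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Cutoffs:", paste(format(x$cutoffs, digits = 6), collapse = ", "),
      "\nmax pairwise relative difference:",
      format(x$max_pairwise_relative_difference, digits = 4),
      "(tolerance", paste0(format(x$tolerance), ")"),
      "->", if (x$consistent) "consistent" else "NOT consistent", "\n")
  invisible(x)
}

#' HER2 ROC analysis against IHC/FISH status
#'
#' Reproduces the three marker-calibration settings: HER2-positive vs
#' HER2-low (`pos_vs_low`, yielding the positivity cutoff), HER2-low vs
#' HER2-ultralow (`low_vs_ultralow`, yielding the ultralow cutoff), and
#' HER2-positive vs HER2-low restricted to samples with a FISH ratio below 2
#' (`pos_vs_low_fishlt2`). Class membership comes from
#' [her2_ihc_class()]; the marker is the HER2 probe row of the expression
#' matrix. Samples without the required annotation are dropped.
#'
#' @param expression Probe-by-sample matrix.
#' @param clinical Clinical table (see [read_clinical_table()]).
#' @param comparison Which analysis setting to run.
#' @param her2_probe Row identifier of the HER2 probe.
#' @param criterion,spec_level Passed to [derive_cutoff()].
#' @return A `cutoff_result`.
#' @export
her2_roc_analysis <- function(expression, clinical,
                              comparison = c("pos_vs_low", "low_vs_ultralow",
                                             "pos_vs_low_fishlt2"),
                              her2_probe = "216836_s_at",
                              criterion = "youden", spec_level = 0.90) {
  comparison <- match.arg(comparison)
  if (!her2_probe %in% rownames(expression))
    stop("HER2 probe ", her2_probe, " absent from expression matrix")
  cls <- her2_ihc_class(clinical)
  keep <- clinical$sample_id %in% colnames(expression) & !is.na(cls)
  cls <- as.character(cls)[keep]
  ids <- clinical$sample_id[keep]
  if (comparison == "pos_vs_low_fishlt2") {
    fr <- clinical$fish_ratio[keep]
    sel <- cls %in% c("positive", "low") & !is.na(fr) & fr < 2
  } else if (comparison == "pos_vs_low") {
    sel <- cls %in% c("positive", "low")
  } else {
    sel <- cls %in% c("low", "ultralow")
  }
  if (!sum(sel)) stop("no samples available for comparison ", comparison)
  high <- if (comparison == "low_vs_ultralow") "low" else "positive"
  derive_cutoff(expression[her2_probe, ids[sel]],
                as.integer(cls[sel] == high), criterion, spec_level)
}

#' Derive the HER2 positivity and ultralow cutoffs
#'
#' Runs `pos_vs_low` and `low_vs_ultralow` ROC analyses and assembles the
#' resulting thresholds into a [her2_cutoffs()] pair ready for
#' [assign_subgroups()].
#'
#' @inheritParams her2_roc_analysis
#' @return A list with the two `cutoff_result` objects (`cut_positive`,
#'   `cut_ultralow`) and the combined `cuts`.
#' @export
derive_her2_cutoffs <- function(expression, clinical,
                                her2_probe = "216836_s_at",
                                criterion = "youden", spec_level = 0.90) {
  pos <- her2_roc_analysis(expression, clinical, "pos_vs_low",
                           her2_probe, criterion, spec_level)
  ul <- her2_roc_analysis(expression, clinical, "low_vs_ultralow",
                          her2_probe, criterion, spec_level)
  list(cut_positive = pos, cut_ultralow = ul,
       cuts = her2_cutoffs(ul$cutoff, pos$cutoff))
}
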