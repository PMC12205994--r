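# Turns marker expression plus cutoffs into the six hormone-receptor by HER2
# molecular subgroups and tabulates their distribution. HER2 class is always
# called from mRNA; hormone-receptor status prefers the recorded clinical
# annotation and falls back to the ESR1 probe rule (cutoff 500) when absent.

#' The six HR x HER2 subgroup labels
#'
#' @return Character vector of the six labels in canonical order.
#' @export
subgroup_labels <- function() {
  c("HR+/HER2+", "HR+/HER2-low", "HR+/HER2-ultralow",
    "HR-/HER2+", "HR-/HER2-low", "HR-/HER2-ultralow")
}

#' HER2 cutoff pair
#'
#' Bundles the two expression thresholds that partition HER2 mRNA levels into
#' ultralow / low / positive. Defaults are the published thresholds on the
#' mean-1000-scaled MAS5 intensity scale: below 1780 is ultralow, 3034 and
#' above is positive.
#'
#' @param cut_ultralow Upper boundary of the ultralow class (exclusive).
#' @param cut_positive Lower boundary of the positive class (inclusive).
#' @return An object of class `her2_cutoffs`.
#' @export
her2_cutoffs <- function(cut_ultralow = 1780, cut_positive = 3034) {
  if (!is.numeric(cut_ultralow) || !is.numeric(cut_positive) ||
      length(cut_ultralow) != 1L || length(cut_positive) != 1L ||
      !is.finite(cut_ultralow) || !is.finite(cut_positive))
    stop("cutoffs must be single finite numbers")
  if (cut_ultralow >= cut_positive)
    stop("cut_ultralow (", cut_ultralow, ") must be below cut_positive (",
         cut_positive, ")")
  structure(list(cut_ultralow = cut_ultralow, cut_positive = cut_positive),
            class = "her2_cutoffs")
}

#' @export
print.her2_cutoffs <- function(x, ...) {
  cat(sprintf("HER2 cutoffs: ultralow < %.6g <= low < %.6g <= positive\n",
              x$cut_ultralow, x$cut_positive))
  invisible(x)
}

#' Classify HER2 expression into ultralow / low / positive
#'
#' Boundary convention: positive when expression is at or above
#' `cut_positive`, ultralow when strictly below `cut_ultralow`, low
#' otherwise. Cutoffs derived by [derive_cutoff()] are midpoints between
#' observed values, so no training sample sits on a boundary.
#'
#' @param expr Nonnegative HER2 expression value(s).
#' @param cuts A [her2_cutoffs()] pair.
#' @return Factor with levels `ultralow`, `low`, `positive`.
#' @examples
#' classify_her2(c(1000, 2500, 3500), her2_cutoffs(1780, 3034))
#' @export
classify_her2 <- function(expr, cuts = her2_cutoffs()) {
  if (!inherits(cuts, "her2_cutoffs")) stop("cuts must be a her2_cutoffs object")
  if (any(expr < 0, na.rm = TRUE)) stop("expression must be nonnegative")
  out <- ifelse(expr >= cuts$cut_positive, "positive",
                ifelse(expr < cuts$cut_ultralow, "ultralow", "low"))
  factor(out, levels = c("ultralow", "low", "positive"))
}

#' Classify hormone-receptor status from ESR1 expression
#'
#' Positive when ESR1 expression is at or above the cutoff (default 500 on
#' the mean-1000-scaled intensity scale).
#'
#' @param esr1_expr Nonnegative ESR1 expression value(s).
#' @param cutoff Positivity threshold.
#' @return Factor with levels `negative`, `positive`.
#' @export
classify_hr <- function(esr1_expr, cutoff = 500) {
  if (any(esr1_expr < 0, na.rm = TRUE)) stop("expression must be nonnegative")
  factor(ifelse(esr1_expr >= cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' HER2 class from IHC/FISH annotation
#'
#' Maps clinical pathology annotation to the IHC/FISH-defined HER2 classes
#' used as the reference standard when calibrating expression cutoffs:
#' `positive` = IHC 3+ or FISH-amplified; `low` = IHC 1+/2+ without
#' amplification; `ultralow` = IHC 0 with the faint/incomplete staining
#' pattern; `zero` = IHC 0 without it (excluded downstream). Samples whose
#' annotation cannot be resolved are `NA`.
#'
#' @param clinical Clinical table.
#' @return Factor with levels `zero`, `ultralow`, `low`, `positive`.
#' @export
her2_ihc_class <- function(clinical) {
  ihc <- clinical$ihc_score
  fish <- clinical$fish_status
  faint <- clinical$faint_staining_flag
  out <- rep(NA_character_, nrow(clinical))
  out[!is.na(fish) & fish == "positive"] <- "positive"
  out[!is.na(ihc) & ihc == 3] <- "positive"
  low <- !is.na(ihc) & ihc %in% c(1, 2) &
    (is.na(fish) | fish == "negative")
  out[low] <- "low"
  zero <- !is.na(ihc) & ihc == 0
  out[zero & !is.na(faint) & faint] <- "ultralow"
  out[zero & (is.na(faint) | !faint)] <- "zero"
  factor(out, levels = c("zero", "ultralow", "low", "positive"))
}

#' Assign samples to the six HR x HER2 subgroups
#'
#' Operates on the intersection of expression-matrix samples and clinical
#' rows (discarded identifiers are reported via `message()` and returned as
#' attributes). HER2 class is called from the HER2 probe expression with
#' `cuts`; hormone-receptor status uses the recorded `hr_status` when present
#' and the ESR1 probe rule otherwise. Samples annotated IHC 0 without the
#' faint-staining pattern (HER2-zero) are excluded from the assignment and
#' from every downstream stage.
#'
#' @param expression Probe-by-sample matrix.
#' @param clinical Clinical table.
#' @param her2_probe,esr1_probe Probe row identifiers.
#' @param cuts A [her2_cutoffs()] pair.
#' @param esr1_cutoff ESR1 positivity threshold for imputing HR status.
#' @return A `data.frame` (class `subgroup_assignment`) with columns
#'   `sample_id`, `hr`, `her2`, `label`; attributes `excluded_her2_zero` and
#'   `unmatched` list the discarded sample identifiers.
#' @export
assign_subgroups <- function(expression, clinical,
                             her2_probe = "216836_s_at",
                             esr1_probe = "205225_at",
                             cuts = her2_cutoffs(),
                             esr1_cutoff = 500) {
  if (!her2_probe %in% rownames(expression))
    stop("HER2 probe ", her2_probe, " absent from expression matrix")
  ids <- intersect(colnames(expression), clinical$sample_id)
  if (!length(ids)) stop("no samples shared by expression matrix and clinical table")
  unmatched <- c(setdiff(colnames(expression), ids),
                 setdiff(clinical$sample_id, ids))
  if (length(unmatched))
    message("dropping ", length(unmatched),
            " sample(s) absent from matrix or clinical table")
  cl <- clinical[match(ids, clinical$sample_id), ]

  zero <- !is.na(cl$ihc_score) & cl$ihc_score == 0 &
    (is.na(cl$faint_staining_flag) | !cl$faint_staining_flag)
  if (any(zero))
    message("excluding ", sum(zero), " HER2-zero sample(s) (IHC 0, no staining)")
  excluded <- ids[zero]
  ids <- ids[!zero]
  cl <- cl[!zero, ]
  if (!length(ids)) stop("no samples left after HER2-zero exclusion")

  her2 <- classify_her2(expression[her2_probe, ids], cuts)
  hr <- factor(cl$hr_status, levels = c("negative", "positive"))
  need <- is.na(hr)
  if (any(need)) {
    if (!esr1_probe %in% rownames(expression))
      stop("hr_status missing for ", sum(need), " sample(s) and ESR1 probe ",
           esr1_probe, " absent from expression matrix")
    hr[need] <- classify_hr(expression[esr1_probe, ids[need]], esr1_cutoff)
  }
  label <- paste0("HR", ifelse(hr == "positive", "+", "-"), "/HER2",
                  c(ultralow = "-ultralow", low = "-low",
                    positive = "+")[as.character(her2)])
  out <- data.frame(sample_id = ids, hr = hr, her2 = her2,
                    label = factor(label, levels = subgroup_labels()),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("subgroup_assignment", "data.frame")
  attr(out, "excluded_her2_zero") <- excluded
  attr(out, "unmatched") <- unmatched
  out
}

#' Tabulate the subgroup distribution
#'
#' @param assignments Output of [assign_subgroups()].
#' @return A `data.frame` with one row per subgroup label, `count`, and
#'   `fraction` (fractions sum to one).
#' @export
subgroup_distribution <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments")
  counts <- table(factor(assignments$label, levels = subgroup_labels()))
  data.frame(label = names(counts),
             count = as.integer(counts),
             fraction = as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}
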