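# Per-gene one-vs-rest association testing with the dual significance
# criterion (rank-sum P below a threshold AND ROC AUC beyond a threshold),
# aggregation to percent-significant per signature per subgroup, and the
# overlap fraction between subgroups' significant-hit sets. Default
# thresholds: P < 0.01, AUC > 0.6, with the AUC criterion applied two-sided
# (effective AUC = max(auc, 1 - auc)) and the direction reported so
# activation-only readouts can filter to "up".

# Tie-corrected normal-approximation rank-sum machinery shared by the batch
# path; identical formula to mann_whitney_p(mode = "normal_approx").
.mw_batch <- function(R, tiesum, member) {
  n <- ncol(R)
  n1 <- sum(member)
  n0 <- n - n1
  u1 <- as.numeric(R %*% member) - n1 * (n1 + 1) / 2
  mu <- n1 * n0 / 2
  v <- n1 * n0 / 12 * ((n + 1) - tiesum / (n * (n - 1)))
  z <- pmax(abs(u1 - mu) - 0.5, 0) / sqrt(v)
  p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  p[v <= 0] <- 1
  list(auc = u1 / (n1 * n0),
       p = pmin(pmax(p, .Machine$double.xmin), 1))
}

#' One-vs-rest association of a single gene with a subgroup
#'
#' Compares the gene's expression in the subgroup's samples against all other
#' assigned samples: AUC from [compute_roc()] with the subgroup as positive
#' class, two-sided p from [mann_whitney_p()]. A gene is significant when the
#' p-value is below `p_threshold` AND the effective AUC
#' `max(auc, 1 - auc)` exceeds `auc_threshold`; direction is `up` when
#' auc > 0.5.
#'
#' @param expression Probe/gene-by-sample matrix.
#' @param assignments Output of [assign_subgroups()].
#' @param gene Row identifier.
#' @param subgroup One of [subgroup_labels()].
#' @param p_threshold,auc_threshold The dual significance thresholds.
#' @return An object of class `gene_association`: `gene`, `subgroup`,
#'   `p_value`, `auc`, `direction`, `significant`.
#' @export
gene_association <- function(expression, assignments, gene, subgroup,
                             p_threshold = 0.01, auc_threshold = 0.6) {
  if (!gene %in% rownames(expression))
    stop("gene ", gene, " absent from expression matrix")
  ids <- intersect(assignments$sample_id, colnames(expression))
  lab <- as.character(assignments$label[match(ids, assignments$sample_id)])
  member <- as.integer(lab == subgroup)
  if (sum(member) == 0L) stop("subgroup ", subgroup, " is empty")
  if (sum(member) == length(member)) stop("complement of ", subgroup, " is empty")
  scores <- expression[gene, ids]
  auc <- compute_roc(scores, member)$auc
  p <- mann_whitney_p(scores, member)
  structure(list(gene = gene, subgroup = subgroup, p_value = p, auc = auc,
                 direction = if (auc > 0.5) "up" else "down",
                 significant = p < p_threshold &&
                   max(auc, 1 - auc) > auc_threshold),
            class = "gene_association")
}

#' @export
print.gene_association <- function(x, ...) {
  cat(sprintf("%s vs %s: AUC %.3f (%s), p %.3g -> %s\n", x$gene, x$subgroup,
              x$auc, x$direction, x$p_value,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Per-gene association table over all subgroups
#'
#' Vectorized one-vs-rest testing of many genes against every subgroup
#' present in the assignment. Ranks are computed once per gene; for cohorts
#' of more than 12 samples the tie-corrected normal approximation is used
#' (the same formula as [mann_whitney_p()]), for tiny cohorts the exact
#' single-gene path.
#'
#' @inheritParams gene_association
#' @param genes Row identifiers to test (default: all rows).
#' @return A `data.frame` with columns `gene`, `subgroup`, `auc`, `p_value`,
#'   `direction`, `significant`.
#' @export
gene_association_table <- function(expression, assignments, genes = NULL,
                                   p_threshold = 0.01, auc_threshold = 0.6) {
  if (is.null(genes)) genes <- rownames(expression)
  absent <- setdiff(genes, rownames(expression))
  if (length(absent)) stop("gene(s) absent from expression matrix: ",
                           paste(utils::head(absent, 3L), collapse = ", "))
  ids <- intersect(assignments$sample_id, colnames(expression))
  if (length(ids) < 2L) stop("need at least two assigned samples")
  lab <- as.character(assignments$label[match(ids, assignments$sample_id)])
  subgroups <- subgroup_labels()[subgroup_labels() %in% unique(lab)]
  subgroups <- subgroups[vapply(subgroups, function(s)
    any(lab == s) && any(lab != s), logical(1L))]
  if (!length(subgroups)) stop("no subgroup with a non-empty complement")
  X <- expression[genes, ids, drop = FALSE]

  if (length(ids) <= 12L) {
    rows <- list()
    for (s in subgroups) for (g in genes) {
      a <- gene_association(expression, assignments, g, s,
                            p_threshold, auc_threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, subgroup = s, auc = a$auc, p_value = a$p_value,
                   direction = a$direction, significant = a$significant,
                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }

  R <- t(apply(X, 1L, rank))
  tiesum <- vapply(seq_len(nrow(X)), function(i) {
    l <- rle(sort(X[i, ]))$lengths
    sum(l^3 - l)
  }, numeric(1L))
  out <- do.call(rbind, lapply(subgroups, function(s) {
    res <- .mw_batch(R, tiesum, as.numeric(lab == s))
    data.frame(gene = genes, subgroup = s, auc = res$auc, p_value = res$p,
               direction = ifelse(res$auc > 0.5, "up", "down"),
               significant = res$p < p_threshold &
                 pmax(res$auc, 1 - res$auc) > auc_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Signature activation matrix (percent significant genes per subgroup)
#'
#' For each signature and subgroup, the fraction of the signature's measured
#' genes (those present in the matrix; absent genes are excluded from the
#' denominator and reported via `message()`) that meet the dual significance
#' criterion. Two matrices are returned: `fraction` counts hits in either
#' direction, `fraction_up` counts activation only. Gene matching is by
#' exact identifier.
#'
#' @inheritParams gene_association
#' @param signatures Named list of gene identifier vectors (see
#'   [read_gmt()]).
#' @return An object of class `signature_activation`: matrices `fraction`
#'   and `fraction_up` (signatures x subgroups), `n_measured` per signature,
#'   `thresholds`, and the long `hits` table of significant
#'   (signature, gene, subgroup, direction) records.
#' @export
signature_activation_matrix <- function(expression, assignments, signatures,
                                        p_threshold = 0.01,
                                        auc_threshold = 0.6) {
  stopifnot(is.list(signatures), length(signatures) > 0L,
            !is.null(names(signatures)))
  measured <- lapply(signatures, intersect, rownames(expression))
  empty <- names(signatures)[lengths(measured) == 0L]
  if (length(empty))
    stop("no genes of signature(s) present in the matrix: ",
         paste(empty, collapse = ", "))
  n_absent <- sum(lengths(signatures)) - sum(lengths(measured))
  if (n_absent > 0)
    message(n_absent, " signature gene(s) absent from the matrix excluded ",
            "from denominators")
  genes <- unique(unlist(measured))
  tab <- gene_association_table(expression, assignments, genes,
                                p_threshold, auc_threshold)
  subgroups <- unique(tab$subgroup)
  cell <- function(sig_genes, s, up_only) {
    rows <- tab[tab$subgroup == s & tab$gene %in% sig_genes, ]
    hit <- rows$significant
    if (up_only) hit <- hit & rows$direction == "up"
    mean(hit)
  }
  mk <- function(up_only) {
    m <- vapply(subgroups, function(s)
      vapply(measured, cell, numeric(1L), s = s, up_only = up_only),
      numeric(length(measured)))
    matrix(m, nrow = length(measured), ncol = length(subgroups),
           dimnames = list(names(signatures), subgroups))
  }
  sig_rows <- tab[tab$significant, ]
  hits <- do.call(rbind, lapply(names(measured), function(nm) {
    h <- sig_rows[sig_rows$gene %in% measured[[nm]], ]
    if (!nrow(h)) return(NULL)
    data.frame(signature = nm, gene = h$gene, subgroup = h$subgroup,
               direction = h$direction, stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    hits <- data.frame(signature = character(), gene = character(),
                       subgroup = character(), direction = character(),
                       stringsAsFactors = FALSE)
  structure(list(fraction = mk(FALSE), fraction_up = mk(TRUE),
                 n_measured = lengths(measured),
                 thresholds = c(p = p_threshold, auc = auc_threshold),
                 hits = hits),
            class = "signature_activation")
}

#' @export
print.signature_activation <- function(x, ...) {
  cat("Signature activation (fraction significant, either direction; ",
      "p < ", x$thresholds[["p"]], ", effective AUC > ",
      x$thresholds[["auc"]], "):\n", sep = "")
  print(round(x$fraction, 3))
  invisible(x)
}

#' Extract a subgroup's significant (signature, gene) hit set
#'
#' @param activation A `signature_activation` object.
#' @param subgroups Subgroup label(s) whose hits to pool.
#' @param direction `"up"` for activation-only hits, `"any"` for both.
#' @return Character vector of unique `"signature|gene"` identifiers.
#' @export
signature_hits <- function(activation, subgroups,
                           direction = c("up", "any")) {
  direction <- match.arg(direction)
  h <- activation$hits
  h <- h[h$subgroup %in% subgroups, ]
  if (direction == "up") h <- h[h$direction == "up", ]
  unique(paste(h$signature, h$gene, sep = "|"))
}

#' Overlap fraction between two significant-hit sets
#'
#' `min_set` divides the intersection size by the smaller set's size;
#' `jaccard` divides by the union's. With exactly one empty set the overlap
#' is zero under both methods; two empty sets are an error (the overlap is
#' undefined).
#'
#' @param hits_a,hits_b Character vectors of hit identifiers (e.g. from
#'   [signature_hits()]).
#' @param method `"min_set"` or `"jaccard"`.
#' @return The overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(hits_a, hits_b,
                             method = c("min_set", "jaccard")) {
  method <- match.arg(method)
  a <- unique(hits_a)
  b <- unique(hits_b)
  if (!length(a) && !length(b))
    stop("overlap undefined: both hit sets are empty")
  i <- length(intersect(a, b))
  if (method == "min_set") {
    if (min(length(a), length(b)) == 0L) return(0)
    i / min(length(a), length(b))
  } else {
    i / length(union(a, b))
  }
}

#' Pairwise subgroup overlap matrix
#'
#' Overlap of significant-hit sets for every pair of subgroups present in
#' the activation result.
#'
#' @inheritParams signature_hits
#' @param method Passed to [overlap_fraction()].
#' @return A symmetric matrix of overlap fractions (diagonal 1 where the
#'   subgroup has any hit, `NA` where both sets of a pair are empty).
#' @export
overlap_matrix <- function(activation, method = c("min_set", "jaccard"),
                           direction = c("up", "any")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  subs <- colnames(activation$fraction)
  sets <- lapply(subs, function(s)
    signature_hits(activation, s, direction))
  names(sets) <- subs
  m <- matrix(NA_real_, length(subs), length(subs),
              dimnames = list(subs, subs))
  for (i in seq_along(subs)) for (j in seq_along(subs)) {
    if (length(sets[[i]]) || length(sets[[j]]))
      m[i, j] <- overlap_fraction(sets[[i]], sets[[j]], method)
  }
  m
}
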