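# Statistical comparisons underlying the figures: per-gene Wilcoxon
# rank-sum tests, marker detection with detection-fraction and logFC
# filters, gene-set signature scores, and Welch t-tests on per-replicate
# fractions or per-cell ratios.

expr_values <- function(expr) {
  if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
}

resolve_cells <- function(values, cells) {
  if (is.character(cells)) {
    idx <- match(cells, rownames(values))
    if (anyNA(idx)) stopf("unknown cell id(s): %s",
                          paste(head(cells[is.na(idx)], 3), collapse = ", "))
    idx
  } else as.integer(cells)
}

# Two-sided rank-sum p for one gene: exact enumeration when both groups are
# small and tie-free, otherwise the tie- and continuity-corrected normal
# approximation (both via stats::wilcox.test).
wilcox_p <- function(xa, xb, exact_max = 8L) {
  if (length(unique(c(xa, xb))) == 1L) {
    # fully tied: the rank distribution is degenerate and the normal
    # approximation is 0/0; no evidence either way
    return(c(statistic = length(xa) * length(xb) / 2, p = 1))
  }
  use_exact <- length(xa) <= exact_max && length(xb) <= exact_max &&
    !anyDuplicated(c(xa, xb))
  wt <- suppressWarnings(
    wilcox.test(xa, xb, exact = use_exact, correct = TRUE))
  c(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Per-gene two-sided Wilcoxon rank-sum tests between two cell groups
#'
#' @param expr An [expr_matrix()] or numeric matrix (cells x genes).
#' @param cells_A,cells_B Disjoint cell id or index vectors.
#' @param genes Optional subset of genes to test (default all).
#' @return Data.frame with `gene`, `statistic` (rank-sum W of group A),
#'   `p_value`. Exact enumeration is used for groups of up to 8 tie-free
#'   observations, the tie-corrected normal approximation with continuity
#'   correction otherwise.
#' @export
wilcoxon_gene_test <- function(expr, cells_A, cells_B, genes = NULL) {
  values <- expr_values(expr)
  ia <- resolve_cells(values, cells_A)
  ib <- resolve_cells(values, cells_B)
  if (!length(ia) || !length(ib)) stopf("both cell groups must be non-empty")
  if (length(intersect(ia, ib))) stopf("cell groups overlap")
  if (is.null(genes)) genes <- colnames(values)
  res <- vapply(genes, function(g)
    wilcox_p(values[ia, g], values[ib, g]), numeric(2))
  data.frame(gene = genes, statistic = res["statistic", ],
             p_value = res["p", ], row.names = NULL)
}

#' Detect positive marker genes per label with detection and logFC filters
#'
#' For each label versus all other cells: genes are kept for testing only if
#' detected (expression > 0) in at least `min_pct` of cells in one of the
#' two groups and if the natural-log fold change of mean expression (counts
#' scale, pseudocount 1) meets `logfc_threshold` (positive only when
#' `only_pos`). Kept genes get a two-sided Wilcoxon rank-sum p and a
#' Bonferroni-adjusted p over the genes tested for that label.
#'
#' @param expr An [expr_matrix()] (log-normalized; detection and mean
#'   expression are computed on the back-transformed `expm1` scale).
#' @param labels Per-cell labels; defaults to `expr$group`.
#' @param only_pos Report only positively enriched genes (default TRUE).
#' @param min_pct Detection-fraction threshold (default 0.25).
#' @param logfc_threshold Natural-log fold-change threshold (default 0.25).
#' @param p_adjust `"bonferroni"` (default) or `"BH"`.
#' @return Named list (one data.frame per label) with columns `gene`,
#'   `log_fc`, `pct_in`, `pct_out`, `p_value`, `p_adjusted`, sorted by
#'   `p_value`.
#' @export
find_markers <- function(expr, labels = NULL, only_pos = TRUE,
                         min_pct = 0.25, logfc_threshold = 0.25,
                         p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  values <- expr_values(expr)
  if (is.null(labels) && inherits(expr, "expr_matrix")) labels <- expr$group
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stopf("need at least 2 labels")
  raw <- expm1(values)   # back to the normalized counts scale
  out <- list()
  for (lv in levels(labels)) {
    in_grp <- labels == lv
    if (sum(in_grp) < 3L) {
      warnf("label '%s' has fewer than 3 cells; skipped", lv)
      next
    }
    pct_in <- colMeans(values[in_grp, , drop = FALSE] > 0)
    pct_out <- colMeans(values[!in_grp, , drop = FALSE] > 0)
    log_fc <- log(colMeans(raw[in_grp, , drop = FALSE]) + 1) -
      log(colMeans(raw[!in_grp, , drop = FALSE]) + 1)
    keep <- pmax(pct_in, pct_out) >= min_pct &
      (if (only_pos) log_fc >= logfc_threshold
       else abs(log_fc) >= logfc_threshold)
    genes <- colnames(values)[keep]
    if (!length(genes)) {
      out[[lv]] <- data.frame(gene = character(0), log_fc = numeric(0),
                              pct_in = numeric(0), pct_out = numeric(0),
                              p_value = numeric(0), p_adjusted = numeric(0))
      next
    }
    wt <- wilcoxon_gene_test(values, which(in_grp), which(!in_grp), genes)
    tab <- data.frame(gene = genes, log_fc = log_fc[keep],
                      pct_in = pct_in[keep], pct_out = pct_out[keep],
                      p_value = wt$p_value,
                      p_adjusted = p.adjust(wt$p_value, method = p_adjust),
                      row.names = NULL)
    out[[lv]] <- tab[order(tab$p_value), ]
  }
  out
}

#' Per-cell signature score of a gene set
#'
#' The mean normalized expression of the (deduplicated) set genes present
#' in the matrix — the same estimator as the phase scores, applied to an
#' arbitrary set such as E2F target genes.
#'
#' @param expr An [expr_matrix()] or matrix.
#' @param geneset Character vector of gene ids.
#' @return Named numeric vector, one score per cell.
#' @export
signature_score <- function(expr, geneset) {
  values <- expr_values(expr)
  genes <- intersect(unique(geneset), colnames(values))
  if (!length(genes)) stopf("no geneset gene is present in the matrix")
  if (length(genes) < length(unique(geneset))) {
    warnf("%d signature gene(s) absent from the matrix; dropped",
          length(unique(geneset)) - length(genes))
  }
  rowMeans(values[, genes, drop = FALSE])
}

#' Welch t-test on per-replicate fractions or per-cell ratios
#'
#' Two-sided Welch (unequal-variance) t-test with Welch-Satterthwaite
#' degrees of freedom, with optional Bonferroni adjustment when the test is
#' one of a family (e.g. several nuclear/cytoplasmic ratio comparisons).
#'
#' @param a,b Numeric vectors of per-replicate fractions (or per-cell
#'   ratios), at least 2 values each.
#' @param bonferroni_m Number of tests in the family (default 1).
#' @return List with `statistic`, `df`, `p_value`,
#'   `p_adjusted` (= min(1, m * p)), and the group means.
#' @export
welch_fraction_test <- function(a, b, bonferroni_m = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stopf("need at least 2 observations per group for a Welch test")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       p_adjusted = min(1, bonferroni_m * tt$p.value),
       mean_a = mean(a), mean_b = mean(b))
}

#' Per-section positive-cell fraction records
#'
#' Convenience constructor for replicate-level counting data (positive
#' cells over total cells per biological replicate).
#'
#' @param positive,total Integer vectors per replicate.
#' @param replicate_id Optional replicate identifiers.
#' @return Data.frame with `replicate_id`, `positive`, `total`, `fraction`.
#' @export
section_fractions <- function(positive, total, replicate_id = NULL) {
  positive <- as.integer(positive); total <- as.integer(total)
  if (length(positive) != length(total)) stopf("length mismatch")
  if (any(positive < 0 | total <= 0 | positive > total)) {
    stopf("need 0 <= positive <= total with total > 0")
  }
  data.frame(
    replicate_id = replicate_id %||% sprintf("rep%d", seq_along(positive)),
    positive = positive, total = total, fraction = positive / total)
}
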