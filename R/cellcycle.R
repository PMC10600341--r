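#' Parameters of the phase-assignment rule
#'
#' @param r_min Minimum Pearson correlation between a reference gene and its
#'   phase score for the gene to be retained (default 0.2; genes with
#'   correlation below this are considered weakly phase-associated and
#'   excluded).
#' @param tau_low Low-signal cutoff in column z-score units: a cell whose
#'   five phase z-scores are all below `tau_low` carries no cycling
#'   signature and is labeled G1 (default 0).
#' @param delta_margin Required similarity margin of the best phase over the
#'   runner-up before a G1/S or S call is made (default 0.3).
#' @param sim_min Minimum pattern similarity for any classification
#'   (default 0.3); cells below it are unclassified.
#' @param similarity `"pearson"` (default) or `"spearman"` for the
#'   pattern-matching correlation.
#' @return A validated list of class `assign_params`.
#' @export
assign_params <- function(r_min = 0.2, tau_low = 0, delta_margin = 0.3,
                          sim_min = 0.3, similarity = c("pearson", "spearman")) {
  similarity <- match.arg(similarity)
  if (r_min < 0 || r_min >= 1) stopf("r_min must be in [0, 1)")
  if (sim_min < -1 || sim_min > 1) stopf("sim_min must be in [-1, 1]")
  if (delta_margin < 0) stopf("delta_margin must be >= 0")
  structure(list(r_min = r_min, tau_low = tau_low,
                 delta_margin = delta_margin, sim_min = sim_min,
                 similarity = similarity),
            class = "assign_params")
}

# Drop set genes not present in the expression matrix (with one warning).
intersect_sets <- function(expr, sets) {
  present <- lapply(sets, function(g) intersect(g, expr$gene_ids))
  n_miss <- sum(lengths(sets)) - sum(lengths(present))
  if (n_miss > 0) {
    warnf("%d reference gene(s) absent from the expression matrix; dropped",
          n_miss)
  }
  empty <- names(present)[lengths(present) == 0L]
  if (length(empty)) {
    stopf("phase '%s' has no genes present in the expression matrix",
          empty[1])
  }
  present
}

#' Exclude reference genes weakly correlated with their phase score
#'
#' For each phase, a provisional score is the per-cell mean expression of
#' that phase's genes (computed from the full initial set, single pass). A
#' gene is retained iff the correlation across cells between its expression
#' and its own phase's score is at least `r_min`. Genes with zero variance
#' (correlation undefined) are excluded. This removes reference genes that
#' do not track the cell-cycle signal in the dataset at hand.
#'
#' @param expr An [expr_matrix()] with at least 3 cells.
#' @param sets A [phase_gene_sets()]; genes absent from `expr` are dropped
#'   with a warning.
#' @param r_min Correlation threshold (default 0.2).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @param iterate If TRUE, recompute scores from the retained genes and
#'   re-filter until the retained set is stable (sensitivity-analysis mode;
#'   the default is the single-pass rule).
#' @return A [phase_gene_sets()] of retained genes.
#' @export
filter_reference_genes <- function(expr, sets, r_min = 0.2,
                                   method = c("pearson", "spearman"),
                                   iterate = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  if (nrow(expr$values) < 3L) stopf("need at least 3 cells to correlate")
  sets <- intersect_sets(expr, sets)
  one_pass <- function(current) {
    scores <- vapply(current, function(g)
      rowMeans(expr$values[, g, drop = FALSE]), numeric(nrow(expr$values)))
    out <- current
    for (p in names(current)) {
      g <- current[[p]]
      r <- suppressWarnings(
        cor(expr$values[, g, drop = FALSE], scores[, p], method = method))
      keep <- !is.na(r) & r >= r_min
      if (!any(keep)) {
        stopf("phase '%s' lost all reference genes at r_min = %g", p, r_min)
      }
      out[[p]] <- g[keep]
    }
    out
  }
  retained <- one_pass(sets)
  if (iterate) {
    repeat {
      nxt <- one_pass(retained)
      if (identical(nxt, retained)) break
      retained <- nxt
    }
  }
  phase_gene_sets(retained)
}

#' Per-cell phase scores as reference-gene averages
#'
#' The score of cell c for phase k is the arithmetic mean of the normalized
#' expression of phase k's reference genes in cell c.
#'
#' @param expr An [expr_matrix()].
#' @param sets A [phase_gene_sets()] (typically the output of
#'   [filter_reference_genes()]); genes absent from `expr` are dropped with
#'   a warning, and a phase with no present genes is an error.
#' @return An object of class `phase_scores`: list with `scores` (cells x 5
#'   matrix in [cc_phases()] order), `retained_genes`, `group`.
#' @export
compute_phase_scores <- function(expr, sets) {
  stopifnot(inherits(expr, "expr_matrix"))
  present <- intersect_sets(expr, sets)
  scores <- vapply(present, function(g)
    rowMeans(expr$values[, g, drop = FALSE]), numeric(nrow(expr$values)))
  rownames(scores) <- expr$cell_ids
  structure(list(scores = scores, retained_genes = phase_gene_sets(present),
                 group = expr$group),
            class = "phase_scores")
}

#' Two-stage scaling of phase scores into per-cell patterns
#'
#' Stage 1 z-scores each phase column across cells, putting the five phases
#' on a common scale. Stage 2 centers each cell's 5-vector at zero,
#' producing the cell's phase-specific score "pattern" — the shape that is
#' matched against idealized phase patterns during assignment.
#'
#' @param ps A `phase_scores` object (or a bare cells x 5 matrix).
#' @return An object of class `scaled_scores`: list with `zscores` (stage 1)
#'   and `pattern` (stage 2), plus `group` when available.
#' @export
scale_scores <- function(ps) {
  scores <- if (inherits(ps, "phase_scores")) ps$scores else as.matrix(ps)
  if (nrow(scores) < 2L) stopf("need at least 2 cells to scale")
  sds <- apply(scores, 2L, sd)
  if (any(sds == 0)) {
    stopf("phase column '%s' has zero variance; cannot z-score",
          colnames(scores)[which(sds == 0)[1]])
  }
  z <- scale(scores)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  pattern <- z - rowMeans(z)
  structure(list(zscores = z, pattern = pattern,
                 group = if (inherits(ps, "phase_scores")) ps$group else NULL),
            class = "scaled_scores")
}

# Pearson/Spearman correlation of every row of `m` with every row of `pat`.
row_cor <- function(m, pat, method) {
  if (method == "spearman") {
    m <- t(apply(m, 1L, rank))
    pat <- t(apply(pat, 1L, rank))
  }
  ms <- m - rowMeans(m)
  ps <- pat - rowMeans(pat)
  denom <- outer(sqrt(rowSums(ms^2)), sqrt(rowSums(ps^2)))
  out <- tcrossprod(ms, ps) / denom
  out[!is.finite(out)] <- NA_real_
  out
}

#' Assign a cell-cycle label to every cell
#'
#' Each cell's scaled pattern is compared (by correlation) to the five
#' idealized phase patterns. The decision sequence per cell:
#' \enumerate{
#'   \item best similarity below `sim_min` (or undefined) — unclassified;
#'   \item all five phase z-scores below `tau_low` — G1 (no cycling
#'     signature);
#'   \item best phase G1/S or S with a similarity margin of at least
#'     `delta_margin` over the runner-up — that phase;
#'   \item best phase G2, G2/M or M/G1 — the collapsed G2/M/G1 label
#'     (expression patterns across these phases are too similar to resolve
#'     further);
#'   \item otherwise — unclassified.
#' }
#' Ties in the argmax are broken by the fixed phase order.
#'
#' @param scaled A `scaled_scores` object from [scale_scores()].
#' @param params An [assign_params()].
#' @param patterns Optional 5 x 5 matrix of idealized patterns (rows =
#'   phases); defaults to [ideal_phase_patterns()].
#' @return An object of class `cc_labels`: data.frame with columns
#'   `cell_id`, `best_phase`, `similarity` (to the best pattern), `margin`,
#'   and `label` (factor over [cc_labels()]).
#' @export
assign_phase <- function(scaled, params = assign_params(),
                         patterns = ideal_phase_patterns()) {
  stopifnot(inherits(scaled, "scaled_scores"), inherits(params, "assign_params"))
  phases <- cc_phases()
  stopifnot(identical(rownames(patterns), phases))
  sim <- row_cor(scaled$pattern, patterns, params$similarity)
  # which.max breaks ties by the first (fixed phase-order) index
  best_idx <- apply(sim, 1L, function(s) {
    s[is.na(s)] <- -Inf
    which.max(s)
  })
  n <- nrow(sim)
  best_sim <- sim[cbind(seq_len(n), best_idx)]
  second <- vapply(seq_len(n), function(i) {
    s <- sim[i, -best_idx[i]]
    s[is.na(s)] <- -Inf
    max(s)
  }, numeric(1))
  margin <- best_sim - second
  best_phase <- phases[best_idx]
  low_all <- rowSums(scaled$zscores < params$tau_low) == ncol(scaled$zscores)

  label <- rep("unclassified", n)
  ok <- !is.na(best_sim) & best_sim >= params$sim_min
  g1 <- ok & low_all
  label[g1] <- "G1"
  sharp <- ok & !g1 & best_phase %in% c("G1/S", "S") &
    margin >= params$delta_margin
  label[sharp] <- best_phase[sharp]
  late <- ok & !g1 & best_phase %in% c("G2", "G2/M", "M/G1")
  label[late] <- "G2/M/G1"

  out <- data.frame(
    cell_id = rownames(scaled$pattern) %||% as.character(seq_len(n)),
    best_phase = factor(best_phase, levels = phases),
    similarity = best_sim,
    margin = margin,
    label = factor(label, levels = cc_labels()),
    stringsAsFactors = FALSE
  )
  if (!is.null(scaled$group)) out$group <- scaled$group
  attr(out, "params") <- params
  class(out) <- c("cc_labels", "data.frame")
  out
}

#' Group-wise proportions of cell-cycle labels
#'
#' @param labels A `cc_labels` data.frame from [assign_phase()] (or any
#'   data.frame with a `label` column), or a factor/character vector.
#' @param group Per-cell group labels; taken from `labels$group` if present.
#' @return An object of class `phase_proportion_table`: list with `counts`
#'   (groups x labels integer matrix) and `proportions` (rows summing to 1).
#' @export
phase_proportions <- function(labels, group = NULL) {
  if (is.data.frame(labels)) {
    if (is.null(group)) group <- labels$group
    labels <- labels$label
  }
  if (is.null(group)) stopf("per-cell group labels are required")
  labels <- factor(labels, levels = cc_labels())
  group <- as.factor(group)   # keeps declared-but-empty levels visible
  if (any(table(group) == 0)) stopf("empty group level present")
  counts <- table(group = group, label = labels)
  props <- sweep(counts, 1L, rowSums(counts), "/")
  structure(list(counts = unclass(counts), proportions = unclass(props)),
            class = "phase_proportion_table")
}

#' @method print phase_proportion_table
#' @export
print.phase_proportion_table <- function(x, digits = 3, ...) {
  cat("Cell-cycle label proportions by group:\n")
  print(round(x$proportions, digits))
  cat("counts:\n")
  print(x$counts)
  invisible(x)
}

#' Chi-square test of homogeneity of label composition across groups
#'
#' Tests whether groups share one label distribution, using the group x
#' label count table. Label categories with zero count in every group are
#' dropped (they contribute no information and would break the expected
#' counts).
#'
#' @param table A `phase_proportion_table` from [phase_proportions()].
#' @return A list with `statistic`, `df`, `p_value`, and the tested table.
#' @export
compare_proportions <- function(table) {
  stopifnot(inherits(table, "phase_proportion_table"))
  counts <- table$counts
  if (nrow(counts) < 2L) stopf("need at least 2 groups to compare")
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2L) stopf("need at least 2 non-empty label categories")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = counts)
}
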