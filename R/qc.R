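#' Filter low-quality cells by detected-gene count
#'
#' Retains cells expressing more than `min_genes` genes (count > 0), the
#' standard low-quality-cell guard for droplet scRNA-seq. The comparison is
#' strict by default: a cell with exactly `min_genes` detected genes is
#' removed. Gene set and cell order are preserved.
#'
#' @param x A [count_matrix()].
#' @param min_genes Detection threshold (default 200).
#' @param strict If TRUE (default) keep cells with detected genes
#'   `> min_genes`; if FALSE use `>=`.
#' @param include_cells Optional character vector of cell ids to restrict to
#'   before filtering (e.g. cells already known to be germ cells rather than
#'   contaminating somatic cells).
#' @return A filtered [count_matrix()] with attribute `"qc"` holding a
#'   summary (cells before/after, detected-gene quantiles).
#' @export
filter_cells <- function(x, min_genes = 200, strict = TRUE,
                         include_cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  group <- x$group
  if (!is.null(include_cells)) {
    keep0 <- x$cell_ids %in% include_cells
    counts <- counts[keep0, , drop = FALSE]
    group <- group[keep0]
  }
  detected <- rowSums(counts > 0)
  keep <- if (strict) detected > min_genes else detected >= min_genes
  if (!any(keep)) {
    warnf("all %d cells removed by the >%s detected-genes filter",
          nrow(counts), format(min_genes))
  }
  out <- count_matrix(counts[keep, , drop = FALSE], group = group[keep])
  attr(out, "qc") <- list(
    cells_before = nrow(counts), cells_after = sum(keep),
    min_genes = min_genes, strict = strict,
    detected_quantiles = quantile(detected, c(0, .25, .5, .75, 1))
  )
  out
}

#' Library-size log-normalization
#'
#' `value(c, g) = log(1 + scale_factor * count(c, g) / total(c))` with
#' natural log — the standard library-size normalization for UMI counts. The
#' cell-cycle scoring downstream (within-cell averages, cross-cell
#' correlations, z-scaling) only requires a monotone per-cell normalization,
#' so this simple scheme suffices; the method and parameters are recorded in
#' the result's provenance.
#'
#' @param x A [count_matrix()].
#' @param scale_factor Pseudo library size (default 1e4).
#' @return An [expr_matrix()].
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- rowSums(x$counts)
  if (any(totals == 0)) {
    stopf("cell(s) with zero total count: %s",
          paste(head(x$cell_ids[totals == 0], 5), collapse = ", "))
  }
  values <- log1p(scale_factor * x$counts / totals)
  expr_matrix(values, group = x$group,
              provenance = list(method = "lognormalize",
                                scale_factor = scale_factor,
                                log_base = "natural"))
}
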