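#' Cell x gene count matrix with group labels
#'
#' Light container for raw UMI-style counts. Rows are cells, columns genes.
#'
#' @param counts Integer matrix (cells x genes) with unique row and column
#'   names, or anything coercible via `as.matrix`.
#' @param group Per-cell group label (e.g. genotype), recycled if length 1.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `cell_ids`, `gene_ids`, `group` (factor).
#' @export
count_matrix <- function(counts, group = "all") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%05d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stopf("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stopf("duplicate gene ids")
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (length(group) == 1L) group <- rep(group, nrow(counts))
  if (length(group) != nrow(counts)) {
    stopf("group has length %d but there are %d cells",
          length(group), nrow(counts))
  }
  structure(
    list(counts = counts, cell_ids = rownames(counts),
         gene_ids = colnames(counts), group = factor(group)),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @method print count_matrix
#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(group = x$group))
  invisible(x)
}

#' Normalized expression matrix
#'
#' @param values Numeric matrix (cells x genes), finite, with dimnames.
#' @param group Per-cell group labels (factor or character).
#' @param provenance Named list recording how the values were produced
#'   (normalization, parameters); carried into downstream reports.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, group = "all", provenance = list()) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stopf("expression values must be finite")
  if (length(group) == 1L) group <- rep(group, nrow(values))
  structure(
    list(values = values, cell_ids = rownames(values),
         gene_ids = colnames(values), group = factor(group),
         provenance = provenance),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (length(x$provenance)) x$provenance$method %||% "custom"
              else "unspecified"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase reference gene sets
#'
#' Named gene lists, one per cell-cycle phase, in the canonical phase order.
#' A gene may belong to at most one phase.
#'
#' @param sets Named list of character vectors; names must be exactly the
#'   five phases of [cc_phases()] (any order; stored in canonical order).
#' @return An object of class `phase_gene_sets`.
#' @export
phase_gene_sets <- function(sets) {
  phases <- cc_phases()
  if (!setequal(names(sets), phases)) {
    stopf("gene sets must be named exactly: %s", paste(phases, collapse = ", "))
  }
  sets <- sets[phases]
  if (any(lengths(sets) == 0L)) {
    stopf("phase '%s' has no genes", phases[which(lengths(sets) == 0L)[1L]])
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  all_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stopf("gene(s) assigned to more than one phase: %s",
          paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  }
  structure(sets, class = "phase_gene_sets")
}

#' @method print phase_gene_sets
#' @export
print.phase_gene_sets <- function(x, ...) {
  cat("phase_gene_sets:\n")
  for (p in names(x)) cat(sprintf("  %-5s %d genes\n", p, length(x[[p]])))
  invisible(x)
}
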