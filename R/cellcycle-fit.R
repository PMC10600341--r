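#' Fit the cell-cycle phase classifier to an expression matrix
#'
#' Runs the full scoring pipeline: correlation-based reference-gene
#' filtering, per-cell average-expression phase scores, two-stage scaling,
#' and pattern-based label assignment, returning everything as one fitted
#' object with print/summary/plot methods.
#'
#' @param expr An [expr_matrix()] (see [lognormalize()]).
#' @param sets A [phase_gene_sets()] of reference genes.
#' @param params An [assign_params()].
#' @param patterns Idealized phase patterns (see [ideal_phase_patterns()]).
#' @return An object of class `cell_cycle_fit` with elements
#'   `retained_genes`, `scores` (`phase_scores`), `scaled`
#'   (`scaled_scores`), `labels` (`cc_labels`), `proportions`
#'   (`phase_proportion_table`), `params`, and `provenance`.
#' @examples
#' sim <- simulate_counts(sim_design(n_cells_per_group = 150, seed = 7))
#' expr <- lognormalize(sim$counts)
#' fit <- cell_cycle_fit(expr, sim$gene_sets)
#' summary(fit)
#' @export
cell_cycle_fit <- function(expr, sets, params = assign_params(),
                           patterns = ideal_phase_patterns()) {
  retained <- filter_reference_genes(expr, sets, r_min = params$r_min)
  scores <- compute_phase_scores(expr, retained)
  scaled <- scale_scores(scores)
  labels <- assign_phase(scaled, params, patterns)
  props <- if (nlevels(expr$group) >= 1L)
    phase_proportions(labels$label, expr$group) else NULL
  structure(list(
    retained_genes = retained, scores = scores, scaled = scaled,
    labels = labels, proportions = props, params = params,
    patterns = patterns,
    provenance = c(expr$provenance,
                   list(n_cells = nrow(expr$values),
                        n_reference_genes = sum(lengths(retained))))
  ), class = "cell_cycle_fit")
}

#' @method print cell_cycle_fit
#' @export
print.cell_cycle_fit <- function(x, ...) {
  cat(sprintf("cell_cycle_fit: %d cells, %d retained reference genes\n",
              x$provenance$n_cells, x$provenance$n_reference_genes))
  print(table(x$labels$label))
  invisible(x)
}

#' @method summary cell_cycle_fit
#' @export
summary.cell_cycle_fit <- function(object, ...) {
  structure(list(
    n_cells = object$provenance$n_cells,
    retained = lengths(object$retained_genes),
    label_table = table(object$labels$label),
    proportions = object$proportions,
    params = object$params
  ), class = "summary.cell_cycle_fit")
}

#' @method print summary.cell_cycle_fit
#' @export
print.summary.cell_cycle_fit <- function(x, ...) {
  cat(sprintf("Cell-cycle classification of %d cells\n", x$n_cells))
  cat("Retained reference genes per phase:\n")
  print(x$retained)
  cat("Labels:\n")
  print(x$label_table)
  if (!is.null(x$proportions)) print(x$proportions)
  cat(sprintf("params: r_min=%g tau_low=%g delta_margin=%g sim_min=%g (%s)\n",
              x$params$r_min, x$params$tau_low, x$params$delta_margin,
              x$params$sim_min, x$params$similarity))
  invisible(x)
}

#' @export
fitted.cell_cycle_fit <- function(object, ...) object$labels$label

#' Stacked-bar plot of label proportions by group
#'
#' @param x A `cell_cycle_fit` or `phase_proportion_table`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.cell_cycle_fit <- function(x, ...) {
  if (is.null(x$proportions)) stopf("fit has no group information")
  plot(x$proportions, ...)
}

#' @export
plot.phase_proportion_table <- function(x, ...) {
  cols <- c("grey70", "#d95f02", "#1b9e77", "#7570b3", "grey40")
  op <- par(mar = c(4, 4, 2, 8), xpd = TRUE)
  on.exit(par(op))
  barplot(t(x$proportions), col = cols, border = NA,
          ylab = "proportion of cells",
          main = "Cell-cycle status by group", ...)
  legend("topright", inset = c(-0.35, 0), legend = colnames(x$proportions),
         fill = cols, bty = "n")
  invisible(x)
}
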