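#' Canonical cell-cycle phase order
#'
#' The five reference phases, in their cyclic order along the cell cycle:
#' G1/S -> S -> G2 -> G2/M -> M/G1 -> (back to G1/S). All score matrices and
#' gene-set objects in the package use this column order.
#'
#' @return Character vector of length 5.
#' @export
cc_phases <- function() c("G1/S", "S", "G2", "G2/M", "M/G1")

#' Assignment labels produced by the classifier
#'
#' Cells are labeled G1/S or S when their score pattern singles out one of
#' those phases; cells peaking anywhere in G2, G2/M or M/G1 receive the
#' collapsed G2/M/G1 label (expression patterns across those phases are too
#' similar to resolve); cells with uniformly low phase scores are called G1
#' (no active cycling signature); everything else is unclassified.
#'
#' @return Character vector of the five label categories.
#' @export
cc_labels <- function() c("G1", "G1/S", "S", "G2/M/G1", "unclassified")

# File-system safe tokens for phase names ("/" is unusable in gene ids/paths)
phase_token <- function(phase) {
  gsub("/", "", phase, fixed = TRUE)
}

#' Idealized phase score patterns
#'
#' One row per phase: 1 at the phase itself, 0.5 at the two cyclically
#' adjacent phases, 0 elsewhere, then row-centered. The half-weight on
#' neighbours encodes the gradual hand-over of phase-specific transcription
#' between adjacent phases; a cell's scaled score pattern is compared to
#' these rows by Pearson correlation during assignment. Supplying a custom
#' matrix to [assign_phase()] replaces this default.
#'
#' @return A 5 x 5 numeric matrix, rows and columns named by [cc_phases()].
#' @export
ideal_phase_patterns <- function() {
  phases <- cc_phases()
  k <- length(phases)
  pat <- matrix(0, k, k, dimnames = list(phases, phases))
  for (i in seq_len(k)) {
    pat[i, i] <- 1
    pat[i, (i %% k) + 1L] <- 0.5
    pat[i, ((i - 2L) %% k) + 1L] <- 0.5
  }
  sweep(pat, 1L, rowMeans(pat))
}
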