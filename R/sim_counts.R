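#' Design of a synthetic two-group cell-cycle count experiment
#'
#' Describes a negative-binomial scRNA-seq simulation in which groups (e.g.
#' control and mutant genotypes) differ only in their cell-cycle phase
#' composition. Each phase owns a block of marker genes whose mean is
#' elevated by `marker_fold_change` in cells truly in that phase; background
#' genes are phase-independent. Counts follow NB(mu, phi) with variance
#' mu + phi * mu^2, scaled per cell by a lognormal size factor.
#'
#' @param n_cells_per_group Cells per group; a single count or a named
#'   vector aligned with `group_phase_proportions`.
#' @param group_phase_proportions Named list (one entry per group) of
#'   5-vectors of phase proportions in the order of [cc_phases()], each
#'   summing to 1.
#' @param n_markers_per_phase Marker genes per phase (default 20).
#' @param n_background_genes Phase-independent genes (default 100).
#' @param marker_fold_change Mean multiplier of a marker in its own phase
#'   (>= 1; default 2.5).
#' @param base_mean Baseline expected count per gene (default 10).
#' @param nb_dispersion NB dispersion phi (variance mu + phi mu^2); 0 gives
#'   Poisson counts (default 0.1).
#' @param library_size_cv Coefficient of variation of per-cell size factors
#'   (default 0.1; 0 disables library-size variation).
#' @param noncycling_fraction Per-group fraction of non-cycling cells with no
#'   marker elevation (a G0-like state; default 0). Single value or named
#'   vector. Phase proportions are rescaled by (1 - fraction).
#' @param stratified If TRUE, per-group phase counts are fixed to the exact
#'   rounded proportions (largest-remainder) instead of i.i.d. sampling.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `sim_design`.
#' @export
sim_design <- function(n_cells_per_group = 1000,
                       group_phase_proportions = list(
                         control = rep(0.2, 5)),
                       n_markers_per_phase = 20,
                       n_background_genes = 100,
                       marker_fold_change = 2.5,
                       base_mean = 10,
                       nb_dispersion = 0.1,
                       library_size_cv = 0.1,
                       noncycling_fraction = 0,
                       stratified = FALSE,
                       seed = 1L) {
  groups <- names(group_phase_proportions)
  if (is.null(groups) || any(groups == "")) {
    stopf("group_phase_proportions must be a named list")
  }
  for (g in groups) {
    p <- group_phase_proportions[[g]]
    if (length(p) != 5L) stopf("group '%s': need 5 phase proportions", g)
    check_prob_vector(p, sprintf("phase proportions of group '%s'", g))
  }
  if (length(n_cells_per_group) == 1L) {
    n_cells_per_group <- setNames(rep(n_cells_per_group, length(groups)), groups)
  }
  if (!setequal(names(n_cells_per_group), groups)) {
    stopf("n_cells_per_group names must match the groups")
  }
  n_cells_per_group <- vapply(groups, function(g)
    as.numeric(check_count(n_cells_per_group[[g]],
                           sprintf("n_cells_per_group['%s']", g))),
    numeric(1))
  if (length(noncycling_fraction) == 1L) {
    noncycling_fraction <- setNames(rep(noncycling_fraction, length(groups)),
                                    groups)
  }
  if (any(noncycling_fraction < 0 | noncycling_fraction > 1)) {
    stopf("noncycling_fraction must be in [0, 1]")
  }
  if (marker_fold_change < 1) stopf("marker_fold_change must be >= 1")
  if (nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (library_size_cv < 0) stopf("library_size_cv must be >= 0")
  if (base_mean <= 0) stopf("base_mean must be > 0")
  structure(list(
    n_cells_per_group = n_cells_per_group,
    group_phase_proportions = group_phase_proportions,
    n_markers_per_phase = check_count(n_markers_per_phase, "n_markers_per_phase"),
    n_background_genes = check_count(n_background_genes, "n_background_genes",
                                     min = 0L),
    marker_fold_change = marker_fold_change,
    base_mean = base_mean,
    nb_dispersion = nb_dispersion,
    library_size_cv = library_size_cv,
    noncycling_fraction = noncycling_fraction[groups],
    stratified = isTRUE(stratified),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "sim_design")
}

# Largest-remainder rounding of n * p to integers summing to n.
stratified_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# NB draw with variance mu + phi mu^2; phi = 0 degenerates to Poisson.
rnb_counts <- function(n, mu, phi) {
  if (phi == 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a count matrix with known phase structure
#'
#' Generates cells group by group: each cell receives a true phase label
#' (sampled from the group's proportions, or exact counts in stratified
#' mode), a lognormal size factor, and NB counts whose per-gene means are
#' `base_mean` times the marker fold change for markers of the cell's own
#' phase, `base_mean` otherwise. Non-cycling cells get no marker elevation.
#' Fully reproducible from `design$seed` via per-group substreams.
#'
#' @param design A [sim_design()].
#' @return A list with elements `counts` (a [count_matrix()] with group
#'   labels), `true_phase` (per-cell character vector; `"NC"` marks
#'   non-cycling cells), and `gene_sets` (a [phase_gene_sets()] mapping each
#'   phase to its marker genes).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  phases <- cc_phases()
  nm <- design$n_markers_per_phase
  marker_genes <- lapply(phases, function(p)
    sprintf("%s.m%03d", phase_token(p), seq_len(nm)))
  names(marker_genes) <- phases
  bg_genes <- if (design$n_background_genes > 0)
    sprintf("BG.%04d", seq_len(design$n_background_genes)) else character(0)
  gene_ids <- c(unlist(marker_genes, use.names = FALSE), bg_genes)
  groups <- names(design$group_phase_proportions)

  blocks <- vector("list", length(groups))
  labels <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    set.seed(substream_seed(design$seed, gi))
    n <- design$n_cells_per_group[[g]]
    f0 <- design$noncycling_fraction[[g]]
    states <- c(phases, "NC")
    probs <- c(design$group_phase_proportions[[g]] * (1 - f0), f0)
    if (design$stratified) {
      cnt <- stratified_counts(n, probs)
      lab <- sample(rep(states, cnt))
    } else {
      lab <- sample(states, n, replace = TRUE, prob = probs)
    }
    sf <- if (design$library_size_cv > 0) {
      sdlog <- sqrt(log(1 + design$library_size_cv^2))
      rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n)
    mu_gene <- matrix(design$base_mean, n, length(gene_ids))
    for (pi in seq_along(phases)) {
      in_phase <- lab == phases[pi]
      cols <- (pi - 1L) * nm + seq_len(nm)
      mu_gene[in_phase, cols] <- design$base_mean * design$marker_fold_change
    }
    mu <- mu_gene * sf
    cnts <- matrix(rnb_counts(length(mu), as.vector(mu), design$nb_dispersion),
                   nrow = n)
    rownames(cnts) <- sprintf("%s.c%05d", g, seq_len(n))
    blocks[[gi]] <- cnts
    labels[[gi]] <- lab
  }
  counts <- do.call(rbind, blocks)
  colnames(counts) <- gene_ids
  cm <- count_matrix(counts,
                     group = rep(groups, vapply(blocks, nrow, integer(1))))
  list(counts = cm,
       true_phase = setNames(unlist(labels), cm$cell_ids),
       gene_sets = phase_gene_sets(marker_genes))
}
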