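# Unit and property tests of the scoring classifier: correlation filter,
# average-expression scores, two-stage scaling, pattern assignment,
# proportions and their homogeneity test.

test_that("a single-gene phase always survives the correlation filter", {
  toy <- planted_phase_toy(good_per_phase = 1, bad_phases = character(0))
  kept <- filter_reference_genes(toy$expr, toy$sets, r_min = 0.2)
  expect_identical(lengths(kept), lengths(toy$sets))   # self-correlation 1
})

test_that("zero-variance genes are excluded even at r_min = 0", {
  toy <- planted_phase_toy(good_per_phase = 2, bad_phases = character(0))
  vals <- toy$expr$values
  vals <- cbind(vals, G2.flat = rep(1.5, nrow(vals)))
  sets <- unclass(toy$sets)
  sets[["G2"]] <- c(sets[["G2"]], "G2.flat")
  expr <- expr_matrix(vals)
  kept <- filter_reference_genes(expr, phase_gene_sets(sets), r_min = 0)
  expect_false("G2.flat" %in% kept[["G2"]])
})

test_that("planted 30x12 toy matches the brute-force Pearson oracle", {
  toy <- planted_phase_toy(n_cells = 30, good_per_phase = 2,
                           bad_phases = c("G1/S", "S"))
  expect_identical(ncol(toy$expr$values), 12L)
  kept <- filter_reference_genes(toy$expr, toy$sets, r_min = 0.2)
  # oracle: per-gene Pearson correlation with its phase's mean profile,
  # computed gene by gene from scratch
  oracle <- lapply(setNames(nm = cc_phases()), function(p) {
    genes <- toy$sets[[p]]
    score <- rowMeans(toy$expr$values[, genes, drop = FALSE])
    keep <- vapply(genes, function(g) {
      r <- suppressWarnings(cor(toy$expr$values[, g], score))
      !is.na(r) && r >= 0.2
    }, logical(1))
    genes[keep]
  })
  expect_identical(unclass(kept)[cc_phases()], oracle)
})

test_that("noise genes fall below threshold once phase sets are large enough", {
  # with few genes per set a noise gene still correlates with the score it
  # is itself part of (single-pass rule); ten informative genes dilute that
  # share well below r_min = 0.2
  toy <- planted_phase_toy(n_cells = 400, good_per_phase = 10,
                           bad_phases = cc_phases(), seed = 13)
  kept <- filter_reference_genes(toy$expr, toy$sets, r_min = 0.2)
  expect_false(any(grepl("bad", unlist(kept))))
  expect_true(all(grepl("good", unlist(kept))))
})

test_that("the retained set shrinks monotonically in r_min", {
  toy <- planted_phase_toy(n_cells = 40, good_per_phase = 3,
                           bad_phases = cc_phases())
  thresholds <- c(0, 0.1, 0.2, 0.4, 0.6)
  kept <- lapply(thresholds, function(r)
    unlist(filter_reference_genes(toy$expr, toy$sets, r_min = r)))
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
  # r_min = 0 keeps every finite-variance gene
  expect_identical(sort(kept[[1]]), sort(unlist(toy$sets)))
})

test_that("phase scores are exactly the per-phase expression means", {
  vals <- matrix(c(1, 2, 3,
                   4, 5, 6,
                   0, 1, 0,
                   2, 2, 2), nrow = 3,
                 dimnames = list(c("c1", "c2", "c3"),
                                 c("a1", "a2", "b1", "b2")))
  sets <- phase_gene_sets(list("G1/S" = c("a1", "a2"), "S" = "b1",
                               "G2" = "b2", "G2/M" = "a1x", "M/G1" = "a2x"))
  # two phases point at absent genes -> dropped with warning -> error
  expect_error(suppressWarnings(
    compute_phase_scores(expr_matrix(vals), sets)), "no genes present")
  sets2 <- phase_gene_sets(list("G1/S" = c("a1", "a2"), "S" = "b1",
                                "G2" = "b2", "G2/M" = "z1", "M/G1" = "z2"))
  vals2 <- cbind(vals, z1 = c(7, 8, 9), z2 = c(1, 1, 2))
  ps <- compute_phase_scores(expr_matrix(vals2), sets2)
  expect_equal(unname(ps$scores[, "G1/S"]), c((1 + 4) / 2, (2 + 5) / 2, (3 + 6) / 2))
  expect_equal(unname(ps$scores[, "S"]), c(0, 1, 0))     # mean of one gene
  expect_equal(unname(ps$scores[, "G2"]), c(2, 2, 2))
})

test_that("scaling satisfies its stage-wise invariants and the two-step oracle", {
  set.seed(88)
  scores <- matrix(rnorm(4 * 5, mean = 3, sd = 2), 4, 5,
                   dimnames = list(NULL, cc_phases()))
  sc <- scale_scores(scores)
  expect_true(all(abs(colMeans(sc$zscores)) < 1e-8))
  expect_true(all(abs(apply(sc$zscores, 2, sd) - 1) < 1e-8))
  expect_true(all(abs(rowMeans(sc$pattern)) < 1e-8))
  # independent sequential oracle
  z_oracle <- apply(scores, 2, function(x) (x - mean(x)) / sd(x))
  p_oracle <- t(apply(z_oracle, 1, function(x) x - mean(x)))
  expect_equal(unname(sc$zscores), unname(z_oracle))
  expect_equal(unname(sc$pattern), unname(p_oracle))
  expect_error(scale_scores(cbind(scores[, 1:4], const = 1)), "zero variance")
})

make_scaled <- function(zscores) {
  zscores <- as.matrix(zscores)
  colnames(zscores) <- cc_phases()
  rownames(zscores) <- sprintf("c%d", seq_len(nrow(zscores)))
  structure(list(zscores = zscores, pattern = zscores - rowMeans(zscores),
                 group = NULL),
            class = "scaled_scores")
}

test_that("assignment follows the declared decision sequence", {
  ideal <- ideal_phase_patterns()
  # cells built directly in z-score space around each ideal pattern
  z <- rbind(ideal["G1/S", ] + 1,          # exact G1/S pattern, high scores
             ideal["S", ] + 1,
             ideal["G2", ] + 1,            # peaks at G2 -> collapsed label
             ideal["G2/M", ] + 1,
             ideal["M/G1", ] + 1,
             ideal["G1/S", ] * 0.2 - 1,    # G1/S-shaped but all z < 0 -> G1
             cos(4 * pi * (0:4) / 5) + 1)  # freq-2 cycle: fits no pattern
  # sanity: the last row really is dissimilar to every idealized pattern
  stopifnot(max(cor(cos(4 * pi * (0:4) / 5), t(ideal))) < 0.3)
  lab <- assign_phase(make_scaled(z))
  expect_identical(as.character(lab$label[1:2]), c("G1/S", "S"))
  expect_identical(as.character(lab$label[3:5]), rep("G2/M/G1", 3))
  expect_identical(as.character(lab$label[6]), "G1")
  expect_identical(as.character(lab$label[7]), "unclassified")
  expect_equal(lab$similarity[1], 1)       # self-match
  # best_phase is never hidden by the collapsed label
  expect_identical(as.character(lab$best_phase[3:5]), c("G2", "G2/M", "M/G1"))
})

test_that("a late-phase peak never yields a bare G2/G2M/MG1 label", {
  set.seed(5)
  z <- matrix(rnorm(200 * 5), 200, 5)
  lab <- assign_phase(make_scaled(z))
  expect_true(all(as.character(lab$label) %in% cc_labels()))
  late_best <- lab$best_phase %in% c("G2", "G2/M", "M/G1")
  expect_false(any(as.character(lab$label[late_best]) %in%
                     c("G2", "G2/M", "M/G1")))
})

test_that("assignment is invariant to cell order and per-cell affine transforms", {
  sim <- simulate_counts(sim_design(n_cells_per_group = 300, seed = 61))
  expr <- lognormalize(sim$counts)
  fit <- cell_cycle_fit(expr, sim$gene_sets)
  # permutation invariance
  perm <- sample(nrow(expr$values))
  expr_p <- expr_matrix(expr$values[perm, ], group = expr$group[perm])
  fit_p <- cell_cycle_fit(expr_p, sim$gene_sets)
  expect_identical(
    as.character(fit_p$labels$label),
    as.character(fit$labels$label[perm]))
  # per-cell positive affine transform is absorbed by scaling only at the
  # pattern level if applied to the scores; apply it to the score matrix
  ps <- compute_phase_scores(expr, sim$gene_sets)
  a <- runif(nrow(ps$scores), 0.5, 2)
  # common positive rescale of all cells plus per-phase-preserving shift
  scores2 <- ps$scores * 1.7 + 3
  lab1 <- assign_phase(scale_scores(ps))
  ps2 <- ps; ps2$scores <- scores2
  lab2 <- assign_phase(scale_scores(ps2))
  expect_identical(as.character(lab1$label), as.character(lab2$label))
})

test_that("proportions match hand counts and sum to one", {
  labels <- factor(c(rep("G1", 4), rep("G1/S", 3), rep("S", 2), "G2/M/G1"),
                   levels = cc_labels())
  pp <- phase_proportions(labels, group = rep("g", 10))
  expect_equal(unname(pp$proportions["g", ]), c(0.4, 0.3, 0.2, 0.1, 0))
  expect_equal(sum(pp$proportions), 1, tolerance = 1e-12)
  # identical multisets give identical rows
  pp2 <- phase_proportions(rep(labels, 2), group = rep(c("a", "b"), each = 10))
  expect_equal(pp2$proportions["a", ], pp2$proportions["b", ])
  expect_error(phase_proportions(labels, group = factor(rep("g", 10),
                                                        levels = c("g", "h"))),
               "empty group")
})

test_that("homogeneity test matches the closed-form chi-square", {
  tab <- structure(list(
    counts = matrix(c(20, 80, 80, 20), 2, byrow = TRUE,
                    dimnames = list(c("a", "b"), c("x", "y"))),
    proportions = NULL), class = "phase_proportion_table")
  res <- compare_proportions(tab)
  # expected counts are all 50; chi2 = 4 * (30^2 / 50) = 72, df = 1
  expect_equal(res$statistic, 72)
  expect_equal(res$df, 1)
  # identical rows: statistic 0, p 1
  tab$counts <- matrix(c(30, 70, 30, 70), 2, byrow = TRUE)
  res0 <- compare_proportions(tab)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # an all-zero category is dropped and df shrinks accordingly
  tab$counts <- cbind(matrix(c(20, 80, 80, 20), 2, byrow = TRUE), z = c(0, 0))
  expect_equal(compare_proportions(tab)$df, 1)
})

test_that("the fitted classifier recovers planted phase structure", {
  sim <- simulate_counts(sim_design(
    n_cells_per_group = 1000,
    group_phase_proportions = list(g = rep(.2, 5)),
    n_markers_per_phase = 20, marker_fold_change = 2.5,
    nb_dispersion = 0.2, seed = 19))
  fit <- cell_cycle_fit(lognormalize(sim$counts), sim$gene_sets)
  lab <- as.character(fit$labels$label)
  truth <- unname(sim$true_phase)
  for (p in c("G1/S", "S")) {
    tp <- sum(lab == p & truth == p)
    expect_gte(tp / sum(lab == p), 0.9)     # precision
    expect_gte(tp / sum(truth == p), 0.9)   # recall
  }
  late <- truth %in% c("G2", "G2/M", "M/G1")
  classified <- lab != "unclassified"
  expect_gte(mean(lab[late & classified] == "G2/M/G1"), 0.95)
})

test_that("summary and plot methods run on a fitted object", {
  sim <- simulate_counts(sim_design(n_cells_per_group = 120,
    group_phase_proportions = list(a = rep(.2, 5), b = rep(.2, 5)),
    seed = 23))
  fit <- cell_cycle_fit(lognormalize(sim$counts), sim$gene_sets)
  expect_output(print(summary(fit)), "Retained reference genes")
  expect_s3_class(fit$proportions, "phase_proportion_table")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_identical(fitted(fit), fit$labels$label)
})
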