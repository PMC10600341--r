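# germcycle

Quantification tools for single-cell studies of meiotic entry in fetal
mouse germ cells. The package re-implements, as tested and reusable R
code, two bespoke analyses from this setting:

1. **Cell-cycle phase scoring and classification** for scRNA-seq count
   matrices. Germ cells entering meiosis pass through a pre-meiotic G1/S
   transition and S phase; whether that subpopulation is present, reduced,
   or missing in a mutant genotype is read off the per-genotype proportions
   of classified cells.
2. **Nuclear/cytoplasmic (N/C) fluorescence-ratio quantification** of a
   transcription factor (e.g. STRA8) from two-channel microscopy images,
   using local adaptive thresholding, binary morphology, and per-cell mask
   algebra.

Both analyses ship with synthetic-data generators carrying exact ground
truth (negative-binomial count matrices with planted phase structure;
two-channel disk/annulus cell images with a known true N/C ratio), so the
whole pipeline is validated end to end.

## The methods in brief

**Phase scoring.** Given a normalized expression matrix and reference gene
sets for the five phases G1/S, S, G2, G2/M, M/G1:

- Genes weakly correlated with their own phase score are excluded
  (Pearson *R* < 0.2 against the per-cell mean expression of the phase's
  genes).
- The score of cell *c* for phase *k* is the mean normalized expression of
  phase *k*'s retained genes.
- Scores are scaled in two stages: each phase column is z-scored across
  cells, then each cell's 5-vector is centered, yielding the cell's
  phase-specific *pattern*.
- Each pattern is compared (Pearson correlation) with five idealized phase
  patterns; cells resolving G1/S or S with a sufficient margin get that
  label, cells peaking anywhere in G2/G2-M/M-G1 get the collapsed
  **G2/M/G1** label (transcription changes little across those phases),
  cells with uniformly low phase z-scores get **G1**, and the remainder is
  **unclassified**.
- Per-genotype label proportions are compared by a chi-square test of
  homogeneity.

**N/C ratio.** The signal channel is binarized with the Bernsen local
threshold (disk neighborhood mid-range with a mid-gray rule for
low-contrast regions), refined by optional erode/dilate/fill-holes steps;
the DAPI channel with a local-mean threshold defines nuclei (8-connected
components). Per cell, the nuclear signal region is signal-mask ∩ nucleus,
the cytoplasmic region is the cell's signal component minus the nucleus,
and the record is mean(nuclear)/mean(cytoplasmic) intensity per pixel.
Group comparisons use two-sided Welch *t*-tests with Bonferroni
correction.

## Worked example

Two genotypes that differ only in their true G1/S proportion (20% in the
control, 2% in the mutant — a depleted pre-meiotic subpopulation):

```r
library(germcycle)

design <- sim_design(
  n_cells_per_group = 1000,
  group_phase_proportions = list(control = rep(0.20, 5),
                                 mutant  = c(0.02, rep(0.245, 4))),
  stratified = TRUE, seed = 1)
sim  <- simulate_counts(design)
expr <- lognormalize(sim$counts)
fit  <- cell_cycle_fit(expr, sim$gene_sets)
summary(fit)
#> Cell-cycle classification of 2000 cells
#> Retained reference genes per phase:
#> G1/S    S   G2 G2/M M/G1
#>   20   20   20   20   20
#> Cell-cycle label proportions by group:
#>          label
#> group     G1 G1/S     S G2/M/G1 unclassified
#>   control  0 0.20 0.195   0.599        0.006
#>   mutant   0 0.02 0.232   0.735        0.013

test <- compare_proportions(fit$proportions)
#> chi-square = 166.9, df = 3, p = 5.87e-36
```

The classifier recovers the planted G1/S proportions essentially exactly
(0.20 vs 0.02), and the homogeneity test rejects at any conventional
level: the missing subpopulation is detected. `plot(fit)` draws the
stacked-bar proportion chart.

For imaging:

```r
spec <- image_spec(n_cells = 8, true_nc_ratio = rep(c(0.5, 1, 2, 4), 2),
                   noise_sd = 2.5, illumination_gradient = 0.1,
                   image_size = c(220, 300), seed = 3)
img  <- simulate_cell_image(spec)
nc   <- quantify_nc(img$image,
                    nc_params(bernsen_radius = 4, contrast_min = 15,
                              midgray = 15, mean_radius = 15, mean_c = -10))
nc[nc$reason == "ok", c("cell_id", "ratio", "nuclear_px", "cytoplasmic_px")]
```

Recovered per-cell ratios land within a few percent of the designed
values across the 0.5–4 range.

A full run (counts → QC → classification → report, or image → N/C table)
is driven by one YAML config:

```sh
Rscript scripts/germcycle.R --config run.yaml --out results/run1
```

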