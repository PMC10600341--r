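# Reproducible end-to-end runs: one config (YAML or list) drives
# simulate -> qc -> cellcycle -> stats and image -> ncr, writing results,
# a checksum manifest and a small human-readable report into a run
# directory.

known_stage_keys <- list(
  simulate_counts = c("n_cells_per_group", "group_phase_proportions",
                      "n_markers_per_phase", "n_background_genes",
                      "marker_fold_change", "base_mean", "nb_dispersion",
                      "library_size_cv", "noncycling_fraction", "stratified"),
  counts_in = c("dir"),
  qc = c("min_genes", "strict"),
  cellcycle = c("r_min", "tau_low", "delta_margin", "sim_min", "similarity",
                "genesets_gmt"),
  simulate_image = c("image_size", "n_cells", "nucleus_radius",
                     "cytoplasm_radius", "true_nc_ratio", "cytoplasm_mean",
                     "background_mean", "dapi_mean", "noise_sd",
                     "illumination_gradient", "bit_depth"),
  image_in = c("path", "dapi_page", "signal_page", "bit_depth"),
  ncr = c("bernsen_radius", "contrast_min", "midgray", "mean_radius",
          "mean_c", "refine_ops", "dapi_refine_ops", "min_px", "bit_depth")
)

#' Validate a pipeline run configuration
#'
#' A config is a list (or YAML file) with a `seed` and a named `stages`
#' list. Unknown stages or stage keys are rejected outright so a typo never
#' silently falls back to a default.
#'
#' @param config List or path to a YAML file.
#' @return The validated config list (with the seed coerced to integer).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or YAML path")
  extra <- setdiff(names(config), c("seed", "stages"))
  if (length(extra)) stopf("unknown config key(s): %s",
                           paste(extra, collapse = ", "))
  config$seed <- check_count(config$seed %||% 1L, "seed", min = 0L)
  if (!length(config$stages)) stopf("config declares no stages")
  for (st in names(config$stages)) {
    if (!st %in% names(known_stage_keys)) stopf("unknown stage '%s'", st)
    bad <- setdiff(names(config$stages[[st]]), known_stage_keys[[st]])
    if (length(bad)) stopf("stage '%s': unknown key(s): %s",
                           st, paste(bad, collapse = ", "))
  }
  if ("cellcycle" %in% names(config$stages) &&
      !any(c("simulate_counts", "counts_in") %in% names(config$stages))) {
    stopf("stage 'cellcycle' needs a counts source ('simulate_counts' or 'counts_in')")
  }
  if ("cellcycle" %in% names(config$stages) &&
      "counts_in" %in% names(config$stages) &&
      !"simulate_counts" %in% names(config$stages) &&
      is.null(config$stages$cellcycle$genesets_gmt)) {
    stopf("stage 'cellcycle' on external counts needs 'genesets_gmt'")
  }
  config
}

write_result_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline described by a config
#'
#' Stages run in a fixed order (simulate/read counts, qc, cellcycle;
#' simulate/read image, ncr). Each stage's outputs are written under
#' `out_dir`, and a `manifest.json` records the seed, package version, all
#' stage parameters and the MD5 checksum of every result file. Any stage
#' error aborts the run, naming the stage and leaving a `FAILED` marker
#' next to the partial outputs.
#'
#' @param config List or YAML path (see [validate_run_config()]).
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the run results (`fit`, `proportions`,
#'   `homogeneity`, `nc`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  results <- list()
  outputs <- character(0)
  current <- ""
  run_stage <- function(name, fn) {
    current <<- name
    fn()
  }
  tryCatch({
    cm <- NULL; true_phase <- NULL; sets <- NULL
    if ("simulate_counts" %in% names(stages)) {
      run_stage("simulate_counts", function() {
        args <- stages$simulate_counts
        args$group_phase_proportions <-
          lapply(args$group_phase_proportions, unlist)
        design <- do.call(sim_design, c(args, list(seed = config$seed)))
        sim <- simulate_counts(design)
        cm <<- sim$counts; true_phase <<- sim$true_phase
        sets <<- sim$gene_sets
        d <- file.path(out_dir, "counts")
        write_counts_mtx(sim$counts, d, true_phase = sim$true_phase)
        write_gmt(sim$gene_sets, file.path(out_dir, "genesets.gmt"))
        outputs <<- c(outputs, file.path(d, c(
          "matrix.mtx", "features.tsv", "barcodes.tsv", "cell_metadata.csv")),
          file.path(out_dir, "genesets.gmt"))
      })
    } else if ("counts_in" %in% names(stages)) {
      run_stage("counts_in", function() {
        cm <<- read_counts_mtx(stages$counts_in$dir)
        true_phase <<- attr(cm, "true_phase")
      })
    }
    if (!is.null(cm) && "qc" %in% names(stages)) {
      run_stage("qc", function() {
        args <- stages$qc
        cm <<- do.call(filter_cells, c(list(cm), args))
        qc <- attr(cm, "qc")
        jsonlite::write_json(
          qc[c("cells_before", "cells_after", "min_genes", "strict")],
          file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)
        outputs <<- c(outputs, file.path(out_dir, "qc_report.json"))
      })
    }
    if ("cellcycle" %in% names(stages)) {
      run_stage("cellcycle", function() {
        ccfg <- stages$cellcycle
        if (!is.null(ccfg$genesets_gmt)) {
          sets <<- phase_gene_sets(read_gmt(ccfg$genesets_gmt))
        }
        params <- do.call(assign_params,
                          ccfg[setdiff(names(ccfg), "genesets_gmt")])
        expr <- lognormalize(cm)
        fit <- cell_cycle_fit(expr, sets, params)
        results$fit <<- fit
        lab <- fit$labels
        lab$group <- as.character(expr$group)
        raw <- fit$scores$scores; z <- fit$scaled$zscores
        colnames(raw) <- paste0("score.", phase_token(colnames(raw)))
        colnames(z) <- paste0("scaled.", phase_token(colnames(z)))
        out <- cbind(lab, as.data.frame(raw), as.data.frame(z))
        outputs <<- c(outputs,
          write_result_csv(out, file.path(out_dir, "cellcycle_labels.csv")))
        props <- fit$proportions
        ptab <- data.frame(group = rownames(props$proportions),
                           props$proportions, check.names = FALSE)
        outputs <<- c(outputs,
          write_result_csv(ptab, file.path(out_dir, "phase_proportions.csv")))
        if (nrow(props$counts) >= 2) {
          hom <- compare_proportions(props)
          results$homogeneity <<- hom
          jsonlite::write_json(hom[c("statistic", "df", "p_value")],
                               file.path(out_dir, "homogeneity_test.json"),
                               auto_unbox = TRUE, digits = NA)
          outputs <<- c(outputs, file.path(out_dir, "homogeneity_test.json"))
        }
        pdf(file.path(out_dir, "phase_proportions.pdf"), width = 6, height = 4)
        plot(props)
        dev.off()
        results$proportions <<- props
      })
    }
    img <- NULL
    if ("simulate_image" %in% names(stages)) {
      run_stage("simulate_image", function() {
        spec <- do.call(image_spec,
                        c(stages$simulate_image, list(seed = config$seed)))
        sim <- simulate_cell_image(spec)
        img <<- sim$image
        write_image_tiff(sim$image, file.path(out_dir, "image.tif"))
        outputs <<- c(outputs,
          write_result_csv(sim$truth, file.path(out_dir, "image_truth.csv")))
      })
    } else if ("image_in" %in% names(stages)) {
      run_stage("image_in", function() {
        img <<- do.call(read_image_tiff, stages$image_in)
      })
    }
    if (!is.null(img) && "ncr" %in% names(stages)) {
      run_stage("ncr", function() {
        params <- do.call(nc_params, stages$ncr)
        nc <- quantify_nc(img, params)
        results$nc <<- nc
        outputs <<- c(outputs,
          write_result_csv(as.data.frame(nc),
                           file.path(out_dir, "nc_ratios.csv")))
      })
    }
    current <- "manifest"
    manifest <- list(
      package = "germcycle",
      version = as.character(utils::packageVersion("germcycle")),
      seed = config$seed,
      stages = stages,
      outputs = lapply(setNames(nm = basename(outputs)), function(b) {
        p <- outputs[basename(outputs) == b][1]
        list(path = sub(paste0("^", out_dir, "/?"), "", p),
             md5 = unname(tools::md5sum(p)))
      })
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results$manifest <- manifest
    invisible(results)
  }, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", current, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", current, conditionMessage(e))
  })
}
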