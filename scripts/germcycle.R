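#!/usr/bin/env Rscript
# Thin command-line wrapper over germcycle::run_pipeline():
#   Rscript scripts/germcycle.R --config run.yaml --out results/run1 [--seed N]

suppressPackageStartupMessages({
  library(optparse)
  library(germcycle)
})

opts <- parse_args(OptionParser(
  option_list = list(
    make_option("--config", type = "character", help = "YAML run config"),
    make_option("--out", type = "character", help = "output directory"),
    make_option("--seed", type = "integer", default = NULL,
                help = "override the config seed"),
    make_option("--version", action = "store_true", default = FALSE)
  )))

if (isTRUE(opts$version)) {
  cat("germcycle", as.character(packageVersion("germcycle")), "\n")
  quit(status = 0)
}
if (is.null(opts$config) || is.null(opts$out)) {
  stop("usage: germcycle.R --config run.yaml --out DIR [--seed N]")
}
config <- validate_run_config(opts$config)
if (!is.null(opts$seed)) config$seed <- opts$seed
res <- run_pipeline(config, opts$out)
if (!is.null(res$proportions)) print(res$proportions)
if (!is.null(res$nc)) print(utils::head(as.data.frame(res$nc), 20))
cat("run complete:", opts$out, "\n")
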