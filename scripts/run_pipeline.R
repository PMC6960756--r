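#!/usr/bin/env Rscript
# Thin command-line wrapper around eegaffect::run_pipeline().
# Usage:
#   Rscript scripts/run_pipeline.R [--config run.yaml] [--seed 1] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(eegaffect)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON run configuration (defaults if omitted)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config seed"),
  make_option("--out", type = "character", default = NULL,
              help = "override the output directory")
)))

cfg <- validate_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed
if (!is.null(opts$out)) cfg$output_dir <- opts$out

out <- run_pipeline(cfg)
print(out$report)
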