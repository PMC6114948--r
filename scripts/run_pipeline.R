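#!/usr/bin/env Rscript
# Run the full analysis pipeline from a YAML config file.
#
# Usage: Rscript scripts/run_pipeline.R --config <run.yaml> [--out <dir>]

suppressPackageStartupMessages(library(somage))

args <- commandArgs(trailingOnly = TRUE)
arg_value <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) {
    if (is.null(default)) stop("missing required argument ", flag)
    return(default)
  }
  args[i + 1L]
}
config_path <- arg_value("--config")
cfg <- run_config(config_path)
out_override <- arg_value("--out", default = cfg$out_dir)
cfg$out_dir <- out_override

res <- run_pipeline(cfg)
message("pipeline complete; outputs in ", cfg$out_dir)
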