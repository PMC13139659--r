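#!/usr/bin/env Rscript
# Thin shell entry point over yieldstab::run_pipeline().
#
# Usage: Rscript scripts/yieldstab_pipeline.R --config <yaml> [--seed <int>]

suppressPackageStartupMessages({
  library(optparse)
  library(yieldstab)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--seed", type = "integer", default = NULL)
)))

if (is.null(opts$config)) {
  message("usage: Rscript scripts/yieldstab_pipeline.R --config <yaml> [--seed <int>]")
  quit(status = 2)
}

cfg <- read_run_config(opts$config, seed = opts$seed)
report <- run_pipeline(cfg)
print(report)
quit(status = if (pipeline_ok(report)) 0 else 1)
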