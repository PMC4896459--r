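#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's pipeline functions.
#
#   Rscript scripts/pipeline.R simulate --out-dir DIR --seed N
#   Rscript scripts/pipeline.R run --config cfg.json [--out-dir DIR --seed N]
#
# `simulate` writes a synthetic macro panel + microdata (with the generating
# config as JSON); `run` executes the full chain: classify -> prevalence ->
# fit/cross-validate/select -> project -> aggregate.

suppressPackageStartupMessages({
  library(optparse)
  library(ecdiglobal)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "run")) {
  stop("usage: pipeline.R <simulate|run> [--config FILE] [--out-dir DIR] [--seed N]")
}
cmd <- args[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out-dir", type = "character", default = "pipeline_out",
              dest = "out_dir"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--log-level", type = "character", default = "info",
              dest = "log_level")
)), args = args[-1])

if (cmd == "simulate") {
  cfg <- if (is.null(opts$config)) sim_config(seed = opts$seed) else {
    raw <- jsonlite::fromJSON(opts$config)
    raw$seed <- opts$seed
    do.call(sim_config, raw)
  }
  panel <- generate_country_panel(cfg)
  micro <- generate_microdata(panel, cfg)
  paths <- write_simulation(panel, micro, cfg, opts$out_dir)
  message("wrote ", paste(paths, collapse = ", "))
} else {
  cfg <- if (is.null(opts$config))
    pipeline_config(opts$out_dir, seed = opts$seed, log_level = opts$log_level)
  else read_pipeline_config(opts$config)
  cfg$out_dir <- opts$out_dir
  cfg$seed <- opts$seed
  run_pipeline(cfg)
}
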