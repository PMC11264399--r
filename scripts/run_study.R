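#!/usr/bin/env Rscript
# Thin shell entry point over panelgvar::run_study().
# Usage: Rscript scripts/run_study.R --config cfg.yaml [--seed 1] [--out dir]

suppressPackageStartupMessages({
  library(optparse)
  library(panelgvar)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML or JSON configuration file"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the configuration's seed"),
  make_option("--out", type = "character", default = NULL,
              help = "override the output directory")
)))

cfg <- if (is.null(opts$config)) list() else opts$config
status <- tryCatch({
  cfg <- panelgvar:::merge_config(cfg)
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  if (!is.null(opts$out)) cfg$out <- opts$out
  run_study(cfg)
  0L
}, panelgvar_stage_error = function(e) {
  message(conditionMessage(e))
  switch(e$stage,
         read = 2L, screen = 3L, descriptives = 4L, preprocess = 5L,
         fit_saturated = 6L, fit_indices = 7L, prune = 8L, search = 9L,
         networks = 10L, stability = 11L, write = 12L, 1L)
}, error = function(e) {
  message(conditionMessage(e))
  1L
})
quit(status = status)
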