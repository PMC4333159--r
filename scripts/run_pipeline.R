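#!/usr/bin/env Rscript
# Thin shell entry point for the two-tissue methylome comparison
# pipeline.
#
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml]
#                [--out-dir DIR] [--seed N] [--quiet]

suppressPackageStartupMessages(library(hmrkit))

args <- commandArgs(trailingOnly = TRUE)
cfg_path <- NULL
out_dir <- NULL
seed <- NULL
verbose <- TRUE
i <- 1L
while (i <= length(args)) {
  a <- args[i]
  if (a == "--config") {
    cfg_path <- args[i + 1L]; i <- i + 2L
  } else if (a == "--out-dir") {
    out_dir <- args[i + 1L]; i <- i + 2L
  } else if (a == "--seed") {
    seed <- as.integer(args[i + 1L]); i <- i + 2L
  } else if (a == "--quiet") {
    verbose <- FALSE; i <- i + 1L
  } else {
    stop("unknown argument: ", a)
  }
}

config <- if (is.null(cfg_path)) pipeline_config() else yaml::read_yaml(cfg_path)
if (!is.null(out_dir)) config$out_dir <- out_dir
if (!is.null(seed)) config$seed <- seed

res <- run_pipeline(config, verbose = verbose)
od <- if (is.null(config$out_dir)) pipeline_config()$out_dir else config$out_dir
cat(sprintf("%d output file(s) under %s\n", nrow(res$manifest), od))
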