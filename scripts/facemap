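#!/usr/bin/env Rscript
# facemap command-line front end.
#
# Usage:
#   facemap simulate --out DIR [--seed N] [--n-per-group N]
#                    [--width W] [--height H] [--chart]
#   facemap run      --manifest FILE --out DIR [--config FILE]
#                    [--alpha A] [--delta-e-threshold T]
#   facemap register --manifest FILE --out DIR [--config FILE]
#   facemap average  --in DIR [--out DIR]
#   facemap maps     --in DIR [--out DIR] [--config FILE] [--alpha A]
#   facemap roi      --in DIR [--out DIR] [--config FILE]
#
# `register` writes calibrated images and registered stacks; `average`,
# `maps` and `roi` consume a directory produced by `register` and
# together reproduce the outputs of `run`.

usage <- function() {
  lines <- readLines(sub("^--file=", "",
    grep("^--file=", commandArgs(FALSE), value = TRUE)[1]))
  writeLines(sub("^# ?", "", lines[3:17]))
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
  usage(); quit(status = 0)
}
cmd <- args[1]
rest <- args[-1]

opt <- list(seed = 1L, `n-per-group` = 12L, width = 256L, height = 256L,
            alpha = NULL, `delta-e-threshold` = NULL,
            manifest = NULL, out = NULL, `in` = NULL, config = NULL,
            chart = FALSE)
i <- 1
while (i <= length(rest)) {
  a <- rest[i]
  if (!startsWith(a, "--")) stop("unexpected argument: ", a)
  key <- substring(a, 3)
  if (key == "chart") { opt$chart <- TRUE; i <- i + 1; next }
  if (i == length(rest)) stop("missing value for --", key)
  opt[[key]] <- rest[i + 1]
  i <- i + 2
}

suppressPackageStartupMessages(library(facemap))
`%||%` <- function(a, b) if (is.null(a)) b else a

cfg <- if (!is.null(opt$config)) read_config(opt$config) else facemap_config()
if (!is.null(opt$alpha)) cfg$alpha <- as.numeric(opt$alpha)
if (!is.null(opt$`delta-e-threshold`))
  cfg$delta_e_threshold <- as.numeric(opt$`delta-e-threshold`)

need <- function(what) {
  if (is.null(opt[[what]])) stop("facemap ", cmd, " requires --", what)
  opt[[what]]
}

switch(cmd,
  simulate = {
    sc <- synthetic_config(n_per_group = as.integer(opt$`n-per-group`),
                           width = as.integer(opt$width),
                           height = as.integer(opt$height),
                           chart_distortion = isTRUE(opt$chart),
                           seed = as.integer(opt$seed))
    generate_study(sc, need("out"))
    cat("wrote synthetic study to", opt$out, "\n")
  },
  run = {
    run_pipeline(need("manifest"), need("out"), config = cfg)
    cat("pipeline complete:", opt$out, "\n")
  },
  register = {
    stage_register(need("manifest"), need("out"), config = cfg)
    cat("registered stacks in", file.path(opt$out, "registered"), "\n")
  },
  average = {
    stage_average(need("in"), opt$out %||% opt$`in`, config = cfg)
  },
  maps = {
    stage_maps(need("in"), opt$out %||% opt$`in`, config = cfg)
  },
  roi = {
    stage_roi(need("in"), opt$out %||% opt$`in`, config = cfg)
  },
  stop("unknown subcommand: ", cmd)
)
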