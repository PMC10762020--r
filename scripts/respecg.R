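#!/usr/bin/env Rscript
# Command-line interface to the respecg estimator.
#
#   Rscript scripts/respecg.R estimate --input rec.bin --format bin16 --fs 4000 ...
#   Rscript scripts/respecg.R synth    --duration 600 --hr 60 --rr 12 --seed 1 ...
#   Rscript scripts/respecg.R eval     --est rr.csv --ref truth.csv ...
#
# Each subcommand is a thin wrapper over run_estimate(), run_synth()
# and run_eval(); every effective parameter is recorded in the output
# directory's run_log.json.

suppressPackageStartupMessages({
  library(respecg)
  library(optparse)
})

usage <- function() {
  cat("usage: respecg.R <estimate|synth|eval> [options]\n",
      "run 'respecg.R <subcommand> --help' for the option list\n")
  quit(status = 2)
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) usage()
cmd <- args[[1L]]
rest <- args[-1L]

parse_band <- function(opt) c(opt$rr_min, opt$rr_max)

# "11,10,12,10,11x120" -> stepped protocol; plain number -> constant
parse_rr <- function(s) {
  if (grepl("x", s, fixed = TRUE)) {
    parts <- strsplit(s, "x", fixed = TRUE)[[1L]]
    levels <- as.numeric(strsplit(parts[1L], ",", fixed = TRUE)[[1L]])
    stepped_protocol(levels, as.numeric(parts[2L]))
  } else as.numeric(s)
}

run <- switch(cmd,
  estimate = {
    spec <- list(
      make_option("--input", type = "character"),
      make_option("--format", type = "character", default = "bin16",
                  help = "bin16, csv or wfdb [default %default]"),
      make_option("--fs", type = "double", default = NULL,
                  help = "sampling frequency (Hz); required for bin16/csv"),
      make_option("--encoding", type = "character", default = "int16-le"),
      make_option("--scale", type = "double", default = 1,
                  help = "mV per count for binary input [default %default]"),
      make_option("--column", type = "integer", default = 1L),
      make_option("--rr-min", type = "double", default = 1.8, dest = "rr_min"),
      make_option("--rr-max", type = "double", default = 18, dest = "rr_max",
                  help = "anticipated RR range (bpm); wide-range studies use 5-40"),
      make_option("--median-window", type = "integer", default = 16L,
                  dest = "median_window"),
      make_option("--spectral-window", type = "integer", default = 16L,
                  dest = "spectral_window"),
      make_option("--nfft", type = "integer", default = 512L),
      make_option("--qrs-window-ms", type = "double", default = 80,
                  dest = "qrs_window"),
      make_option("--out-dir", type = "character", default = ".",
                  dest = "out_dir"),
      make_option("--no-plot", action = "store_true", default = FALSE,
                  dest = "no_plot"))
    opt <- parse_args(OptionParser(option_list = spec,
                                   prog = "respecg.R estimate"), rest)
    if (is.null(opt$input)) stop("--input is required", call. = FALSE)
    function() run_estimate(list(
      input = opt$input, format = opt$format, fs = opt$fs,
      encoding = opt$encoding, scale = opt$scale, column = opt$column,
      rr_band = parse_band(opt), median_window = opt$median_window,
      spectral_window = opt$spectral_window, nfft = opt$nfft,
      qrs_window = opt$qrs_window, out_dir = opt$out_dir,
      plot = !opt$no_plot))
  },
  synth = {
    spec <- list(
      make_option("--duration", type = "double", default = 120),
      make_option("--fs", type = "double", default = 1000),
      make_option("--hr", type = "double", default = 60),
      make_option("--rr", type = "character", default = "12",
                  help = paste0("constant bpm, or a stepped protocol ",
                                "'11,10,12,10,11x120' [default %default]")),
      make_option("--mod-depth", type = "double", default = 0.1,
                  dest = "mod_depth"),
      make_option("--noise-sd", type = "double", default = 0.02,
                  dest = "noise_sd"),
      make_option("--st-shift", type = "double", default = 0,
                  dest = "st_shift"),
      make_option("--seed", type = "integer", default = NULL,
                  help = "omit to auto-choose (recorded in truth.csv)"),
      make_option("--out-dir", type = "character", default = ".",
                  dest = "out_dir"))
    opt <- parse_args(OptionParser(option_list = spec,
                                   prog = "respecg.R synth"), rest)
    function() run_synth(list(
      duration = opt$duration, fs = opt$fs, hr = opt$hr,
      rr = parse_rr(opt$rr), mod_depth = opt$mod_depth,
      noise_sd = opt$noise_sd, st_shift = opt$st_shift,
      seed = opt$seed, out_dir = opt$out_dir))
  },
  eval = {
    spec <- list(
      make_option("--est", type = "character"),
      make_option("--ref", type = "character"),
      make_option("--delta", type = "double", default = 2,
                  help = "TOST equivalence margin (bpm) [default %default]"),
      make_option("--out-dir", type = "character", default = ".",
                  dest = "out_dir"))
    opt <- parse_args(OptionParser(option_list = spec,
                                   prog = "respecg.R eval"), rest)
    if (is.null(opt$est) || is.null(opt$ref))
      stop("--est and --ref are required", call. = FALSE)
    function() run_eval(list(est = opt$est, ref = opt$ref,
                             delta = opt$delta, out_dir = opt$out_dir))
  },
  usage())

status <- tryCatch({ run(); 0L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
quit(status = status)
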