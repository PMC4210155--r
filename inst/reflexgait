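#!/usr/bin/env Rscript
# Thin command-line front end for the reflexgait package.
#
#   reflexgait generate --out DIR [--seed N] [--settings N] [--steps N]
#       write a synthetic recording + events + ground-truth sidecar
#   reflexgait analyze --in RECORDING.CSV --out PARAMS.CSV [--iterations N]
#       fit the four joint-action twitch parameters from a recording
#   reflexgait pipeline --out REPORT.JSON [--seed N] [--subjects N]
#       run the end-to-end synthetic-cohort pipeline and write a summary

suppressPackageStartupMessages(library(reflexgait))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: reflexgait <generate|analyze|pipeline> [--flag value ...]",
       call. = FALSE)
cmd <- args[1L]
flags <- args[-1L]
opt <- function(name, default = NULL) {
  i <- which(flags == paste0("--", name))
  if (length(i) == 1L && i < length(flags)) flags[i + 1L] else default
}

if (cmd == "generate") {
  out <- opt("out"); if (is.null(out)) stop("--out DIR required")
  seed <- as.integer(opt("seed", "1"))
  cfg <- synth_config(seed = seed)
  prof <- generate_speed_sequence(
    n_settings = as.integer(opt("settings", "8")),
    steps_per_setting = as.integer(opt("steps", "15")), config = cfg)
  ev <- generate_gait_events(prof, cfg)
  kern <- default_kernels(cfg, stride_s = ev$mean_stride)
  fsr <- generate_fsr_signals(ev, cfg)
  emg <- generate_emg(ev, kern, cfg, fsr = fsr)
  paths <- write_fixture(emg, fsr, ev, kern, out)
  cat(sprintf("wrote %s\n", paths))
} else if (cmd == "analyze") {
  inp <- opt("in"); out <- opt("out")
  if (is.null(inp) || is.null(out)) stop("--in and --out required")
  rec <- read_recording(inp)
  res <- analyze_subject(rec,
                         iterations = as.integer(opt("iterations", "100")))
  write.csv(res$params, out, row.names = FALSE)
  cat(sprintf("wrote %s (%d functions)\n", out, nrow(res$params)))
} else if (cmd == "pipeline") {
  out <- opt("out"); if (is.null(out)) stop("--out FILE required")
  rep <- run_pipeline(n_subjects = as.integer(opt("subjects", "2")),
                      seed = as.integer(opt("seed", "1")),
                      policy = opt("policy", "mean-all"))
  jsonlite::write_json(
    list(provenance = rep$provenance, aggregate = rep$aggregate,
         strides = rep$sim$strides, fell = rep$sim$fell,
         metrics = rep$metrics,
         stability = rep$stability),
    out, auto_unbox = TRUE, digits = NA)
  cat(sprintf("wrote %s\n", out))
} else {
  stop("unknown subcommand '", cmd, "'", call. = FALSE)
}
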