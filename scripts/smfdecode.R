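#!/usr/bin/env Rscript
# Thin command-line wrapper over the smfdecode package.
#
#   Rscript scripts/smfdecode.R simulate --kind open-loop --seed 1 --out prefix
#   Rscript scripts/smfdecode.R fisher --table 4,1,1,6
#   Rscript scripts/smfdecode.R run-all --seed 1 --trials 12 --out report.json

suppressMessages(library(smfdecode))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) {
  stop("usage: smfdecode.R <simulate|fisher|run-all> [options]", call. = FALSE)
}
verb <- argv[1]
opt <- function(flag, default) {
  i <- which(argv == flag)
  if (length(i) && i < length(argv)) argv[i + 1] else default
}

if (verb == "simulate") {
  kind <- opt("--kind", "open-loop")
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "session")
  trials <- as.integer(opt("--trials", "40"))
  arr <- make_sensor_array(as.integer(opt("--sensors", "160")), seed = 7)
  cfg <- sim_config(n_trials_per_type = trials, seed = seed)
  ses <- if (kind == "open-loop") {
    simulate_open_loop(cfg, arr)
  } else {
    simulate_closed_loop_stream(cfg, arr)
  }
  write_meg_session(ses, out)
  cat("wrote session", out, "\n")
} else if (verb == "fisher") {
  cells <- as.numeric(strsplit(opt("--table", ""), ",")[[1]])
  tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
  cat(sprintf("accuracy %.1f%%  one-tailed p %.6f\n",
              contingency_accuracy(tab), fisher_exact_one_tailed(tab)))
} else if (verb == "run-all") {
  seed <- as.integer(opt("--seed", "1"))
  trials <- as.integer(opt("--trials", "12"))
  out <- opt("--out", "report.json")
  cfg <- run_config(
    sim = sim_config(n_trials_per_type = trials),
    spec = decoder_spec(gamma = 2^c(-13, -9, -5), cost = 2^c(-1, 3, 7),
                        outer_folds = 4, inner_folds = 3,
                        windows = seq(0, 1000, by = 200)),
    n_sensors = as.integer(opt("--sensors", "84")),
    onset = list(folds = 10, target_fp_per_min = 1),
    closed_loop = list(n_instructions = 22, target_fp_per_min = 1,
                       gamma = 0.01, cost = 1),
    seed = seed
  )
  bundle <- run_pipeline(cfg)
  print(bundle)
  jsonlite::write_json(list(
    config_hash = bundle$config_hash,
    seed = bundle$seed,
    type_accuracy_pct = bundle$type_accuracy$accuracy,
    intention_accuracy_pct = bundle$intention_accuracy$accuracy,
    onset_nd_pct = bundle$onset_histogram$nd_percent,
    onset_histogram = bundle$onset_histogram$bins,
    closed_loop_type = bundle$report$type,
    closed_loop_onset = bundle$report$onset
  ), out, auto_unbox = TRUE, digits = NA)
  cat("wrote", out, "\n")
} else {
  stop("unknown verb: ", verb, call. = FALSE)
}
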