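#' Assemble a full pipeline configuration
#'
#' One flat, serializable configuration driving every stage of the
#' open-loop analysis and closed-loop simulation. Unknown stage names are
#' rejected. Every random operation downstream derives its seed from
#' `seed`.
#'
#' @param sim A [sim_config()] for the open-loop (training) session; the
#'   closed-loop stream reuses it with `seed + 1`.
#' @param spec A [decoder_spec()] for the nested-CV decoding stages.
#' @param n_sensors,array_seed Sensor-array geometry.
#' @param kinds Feature kinds to decode (default `"smf"`).
#' @param onset List: `folds`, `target_fp_per_min` for the first-onset
#'   evaluation.
#' @param closed_loop List: `n_instructions`, `target_fp_per_min`,
#'   `gamma`, `cost` for the real-time decoder.
#' @param seed Master seed.
#' @param ... Rejected; present to catch misspelled stage names.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       spec = decoder_spec(),
                       n_sensors = 160, array_seed = 7,
                       kinds = "smf",
                       onset = list(folds = 10, target_fp_per_min = 1),
                       closed_loop = list(n_instructions = 22,
                                          target_fp_per_min = 1,
                                          gamma = 0.01, cost = 1),
                       seed = 1, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop_smf("invalid_config", "unknown run_config entries: %s",
             paste(names(extra), collapse = ", "))
  }
  cfg <- list(sim = sim, spec = spec, n_sensors = n_sensors,
              array_seed = array_seed, kinds = kinds, onset = onset,
              closed_loop = closed_loop, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: simulate the open-loop session,
#' estimate baseline statistics, extract features, nested-CV type and
#' intention decoding, offline first-onset evaluation, real-time decoder
#' training, closed-loop stream simulation and run, section classification
#' and exact statistics. Deterministic for a fixed configuration; every
#' output carries the configuration hash and master seed.
#'
#' @param config A [run_config()].
#' @return List of class `report_bundle`: `type_accuracy` (accuracy curve),
#'   `intention_accuracy`, `onset_histogram`, `closed_loop` (summary), and
#'   `report` (type/onset tables), plus `config_hash` and `seed`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_smf("pipeline_error", "stage '%s' failed: %s",
               name, conditionMessage(e))
    })
  }
  sim <- config$sim
  sim$seed <- config$seed
  array <- stage("sensor_array",
                 make_sensor_array(config$n_sensors, seed = config$array_seed))
  open <- stage("simulate_open_loop", simulate_open_loop(sim, array))
  stats <- stage("baseline_stats", compute_baseline_stats(
    open, bands = setdiff(config$kinds, "smf")))
  feats <- stage("extract_features", extract_features(
    open, stats, window_grid(-2000, 1000, 100), kinds = config$kinds))

  spec <- config$spec
  spec$seed <- config$seed
  type_acc <- stage("decode_type", nested_cv_type_accuracy(feats, spec))
  int_acc <- stage("decode_intention",
                   nested_cv_intention_accuracy(feats, spec))
  hist <- stage("onset_evaluation", evaluate_first_onset(
    open, stats, folds = config$onset$folds,
    target_fp_per_min = config$onset$target_fp_per_min,
    seed = config$seed))

  decoder <- stage("train_realtime_decoder", train_realtime_decoder(
    open, stats, gamma = config$closed_loop$gamma,
    cost = config$closed_loop$cost,
    target_fp_per_min = config$closed_loop$target_fp_per_min,
    seed = config$seed))
  sim_cl <- sim
  sim_cl$seed <- config$seed + 1L
  k <- config$closed_loop$n_instructions
  stream <- stage("simulate_closed_loop", simulate_closed_loop_stream(
    sim_cl, array, rep(c("grasp", "open"), length.out = k)))
  log <- stage("run_closed_loop", run_closed_loop(stream, decoder))
  summ <- stage("score_closed_loop", closed_loop_summary(log))
  report <- stage("build_report", build_report(list(s1 = log)))

  structure(
    list(type_accuracy = type_acc, intention_accuracy = int_acc,
         onset_histogram = hist, closed_loop = summ, report = report,
         config_hash = rlang::hash(config), seed = config$seed),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    paste0("<report_bundle> type %.1f%%, intention %.1f%%, N.D. %.1f%%, ",
           "closed-loop section accuracy %.1f%% (hash %s)\n"),
    x$type_accuracy$accuracy, x$intention_accuracy$accuracy,
    x$onset_histogram$nd_percent, x$closed_loop$section_accuracy,
    substr(x$config_hash, 1, 8)
  ))
  invisible(x)
}
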