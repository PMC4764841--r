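#' Feedback-chain delay model
#'
#' Component delays of the real-time path, in ms. The total is their sum
#' (about 830 ms under defaults: acquisition ~0.02, processing ~70, the
#' 500-ms SMF window itself, hand control ~150, screen projection ~110).
#' Detected onset times are corrected downstream by subtracting the
#' processing delay.
#'
#' @param acquisition_ms,processing_ms,window_ms,hand_ms,projection_ms
#'   Component delays in milliseconds.
#' @return List of class `delay_model` with a `total_ms` field.
#' @export
delay_model <- function(acquisition_ms = 0.02, processing_ms = 70,
                        window_ms = 500, hand_ms = 150, projection_ms = 110) {
  d <- list(acquisition_ms = acquisition_ms, processing_ms = processing_ms,
            window_ms = window_ms, hand_ms = hand_ms,
            projection_ms = projection_ms)
  d$total_ms <- sum(unlist(d))
  class(d) <- "delay_model"
  d
}

#' Train the real-time decoder from an open-loop session
#'
#' Fits everything the closed-loop path needs, using only the open-loop
#' (training) session: the dual intention-confidence models (SVM + GPR) on
#' single SMF windows, a movement-type RBF SVM at the training-set
#' peak-accuracy window, and detection thresholds calibrated to a rest
#' false-detection target.
#'
#' @param session Open-loop `meg_session`.
#' @param stats Its baseline statistics ([compute_baseline_stats()]).
#' @param rest_ends,intent_ends Training epoch window ends (ms, cue-relative).
#' @param type_windows Candidate window ends for the type classifier.
#' @param gamma,cost SVM hyperparameters.
#' @param target_fp_per_min Threshold calibration target.
#' @param seed Seed for internal fold assignment.
#' @return Object of class `realtime_decoder`.
#' @export
train_realtime_decoder <- function(session, stats,
                                   rest_ends = seq(-2000, -1000, by = 200),
                                   intent_ends = seq(0, 1000, by = 200),
                                   type_windows = seq(0, 1000, by = 100),
                                   gamma = 0.01, cost = 1,
                                   target_fp_per_min = 1, seed = 1) {
  cues <- cue_events(session)
  all_ends <- sort(unique(c(rest_ends, intent_ends, type_windows)))
  feats <- extract_features(session, stats, all_ends, kinds = "smf")
  X <- feats$features$smf
  ridx <- match(rest_ends, all_ends)
  iidx <- match(intent_ends, all_ends)
  tidx <- match(type_windows, all_ends)

  xr <- do.call(rbind, lapply(ridx, function(j) X[, j, , drop = TRUE]))
  xi <- do.call(rbind, lapply(iidx, function(j) X[, j, , drop = TRUE]))
  models <- train_confidence_models(
    rbind(xr, xi), rep(c("rest", "intention"), c(nrow(xr), nrow(xi))),
    gamma = gamma, cost = cost
  )

  t_star <- peak_type_window(X[, tidx, , drop = FALSE], cues$label,
                             type_windows, gamma, cost, seed)
  # train the type classifier on every intention-epoch window (not only the
  # peak one): at a detected onset the MRCF is still ramping, so the
  # classifier must cover the whole amplitude range of the epoch
  x_type <- do.call(rbind, lapply(iidx, function(j) X[, j, , drop = TRUE]))
  y_type <- rep(cues$label, length(iidx))
  type_svm <- e1071::svm(x_type, factor(y_type), kernel = "radial",
                         gamma = gamma, cost = cost,
                         scale = apply(x_type, 2, sd) > 0)

  # thresholds from cross-validated (out-of-sample) rest confidences
  rest_stream <- cv_rest_confidences(X, ridx, iidx, cues$label,
                                     gamma, cost, seed + 300L)
  detector <- tryCatch(
    calibrate_thresholds(rest_stream, target_fp_per_min),
    smfdecode_error = function(e) onset_detector(
      max(rest_stream$c_svm), max(rest_stream$c_gpr))
  )

  structure(
    list(confidence = models, type_svm = type_svm, peak_window_ms = t_star,
         detector = detector, gamma = gamma, cost = cost, seed = seed),
    class = "realtime_decoder"
  )
}

#' Run the simulated closed-loop session
#'
#' Emulates the real-time path on a closed-loop stream: every 200 ms of
#' stream time the latest causal SMF (window ending `processing_ms` before
#' the current wall time) is computed from the stream's own 50-s baseline
#' statistics, both confidences are updated, and the onset rule (dual
#' thresholds + 1.5-s refractory) is applied incrementally. At each detected
#' onset the movement type is inferred by the type SVM from the same SMF and
#' the two-state prosthetic hand transitions to the inferred posture after
#' the hand-control delay. Decoder and detector must come from a separate
#' open-loop session; the stream is never used for training.
#'
#' @param stream A closed-loop `meg_session`.
#' @param decoder A [train_realtime_decoder()] result.
#' @param detector Optional [onset_detector()] override.
#' @param recalibrate If `TRUE` (default) and no `detector` is given, the
#'   thresholds are recalibrated on the stream's task-free head segment
#'   before control starts — the automated counterpart of the experimenter
#'   adjusting the thresholds at the beginning of each feedback session.
#'   With `FALSE` the decoder's open-loop thresholds are used unchanged.
#' @param target_fp_per_min Recalibration target (false detections per
#'   minute of head-segment rest).
#' @param delays A [delay_model()].
#' @param initial_posture Hand posture before the first detection.
#' @return Object of class `closed_loop_log`: `instructions` (time_ms, type),
#'   `detections` (time_ms, corrected_ms, inferred), `hand` (transition
#'   time_ms, posture), `initial_posture`, `end_ms`, and the evaluated
#'   SMF stream (`smf_time_ms`, `smf`) for the real-time/offline
#'   equivalence check.
#' @export
run_closed_loop <- function(stream, decoder, detector = NULL,
                            recalibrate = TRUE, target_fp_per_min = 1,
                            delays = delay_model(),
                            initial_posture = "open") {
  if (!inherits(decoder, "realtime_decoder")) {
    stop_smf("usage_error", "decoder must be a trained realtime_decoder")
  }
  stats <- compute_baseline_stats(stream, bands = character(0))
  n_ms <- 1000 * ncol(stream$data) / stream$rate
  lag <- delays$processing_ms + delays$acquisition_ms
  # first wall time at which a full causal window is available
  t0 <- 200 * ceiling((delays$window_ms + lag) / 200)
  eval_times <- seq(t0, n_ms, by = 200)
  win_ends <- eval_times - delays$processing_ms

  par_n <- length(stats$parietal)
  smf <- t(vapply(win_ends, function(w) compute_smf(stream, stats, w)$values,
                  numeric(par_n)))
  conf <- predict_confidences(decoder$confidence, smf, time_ms = eval_times)

  if (is.null(detector) && recalibrate) {
    head_ms <- 1000 * stats$baseline_s
    head_conf <- conf[eval_times <= head_ms, , drop = FALSE]
    detector <- tryCatch(
      calibrate_thresholds(head_conf, target_fp_per_min),
      smfdecode_error = function(e) onset_detector(
        max(head_conf$c_svm), max(head_conf$c_gpr))
    )
  }
  detector <- detector %||% decoder$detector

  instr <- stream$schedule[grepl("^instruction_", stream$schedule$event), ]
  control_start <- if (nrow(instr)) 1000 * instr$time_s[1] else 0

  hit <- conf$c_svm > detector$threshold_svm &
    conf$c_gpr > detector$threshold_gpr &
    eval_times >= control_start
  posture <- initial_posture
  last_onset <- -Inf
  det_time <- numeric(0)
  det_type <- character(0)
  hand_time <- numeric(0)
  hand_state <- character(0)
  for (i in seq_along(eval_times)) {
    t <- eval_times[i]
    if (hit[i] && t - last_onset >= detector$refractory_ms) {
      last_onset <- t
      inferred <- as.character(predict(decoder$type_svm,
                                       smf[i, , drop = FALSE]))
      det_time <- c(det_time, t)
      det_type <- c(det_type, inferred)
      if (inferred != posture) {
        posture <- inferred
        hand_time <- c(hand_time, t + delays$hand_ms)
        hand_state <- c(hand_state, inferred)
      }
    }
  }

  structure(
    list(
      instructions = data.frame(time_ms = instr$time_s * 1000,
                                type = instr$label),
      detections = data.frame(time_ms = det_time,
                              corrected_ms = det_time - delays$processing_ms,
                              inferred = det_type),
      hand = data.frame(time_ms = hand_time, posture = hand_state),
      initial_posture = initial_posture,
      end_ms = n_ms,
      smf_time_ms = win_ends,
      smf = smf,
      delays = delays,
      detector = detector
    ),
    class = "closed_loop_log"
  )
}

#' @export
print.closed_loop_log <- function(x, ...) {
  cat(sprintf(
    "<closed_loop_log> %d instructions, %d detections, %d hand transitions, %.0f s\n",
    nrow(x$instructions), nrow(x$detections), nrow(x$hand), x$end_ms / 1000
  ))
  invisible(x)
}

# Piecewise-constant lookups over a log.
state_at <- function(times, values, t, initial) {
  if (!length(times)) return(rep(initial, length(t)))
  idx <- findInterval(t, times)
  out <- c(initial, values)[idx + 1]
  out
}

#' Divide a closed-loop log into evaluation sections
#'
#' The session (from the first instruction onward) is split at every
#' instruction change and at every hand-state change; sections are half-open
#' `[start, end)`. Each section is same-state if the active instruction
#' matches the hand posture at the section start, different-state otherwise,
#' and is classified by whether at least one delay-corrected onset falls
#' inside it: TP = different-state with onset, FP = same-state with onset,
#' FN = different-state without onset, TN = same-state without onset.
#' Because hand-state changes subdivide instructions, counts can exceed the
#' number of instructions.
#'
#' @param log A `closed_loop_log`.
#' @return List of class `section_table`: `table` (named integer vector TP,
#'   FP, FN, TN), `sections` (data frame), `n_sections`.
#' @export
classify_sections <- function(log) {
  if (!nrow(log$instructions)) {
    stop_smf("empty_log", "log contains no instructions")
  }
  t_first <- log$instructions$time_ms[1]
  hand_t <- log$hand$time_ms
  bounds <- sort(unique(c(
    log$instructions$time_ms,
    hand_t[hand_t >= t_first & hand_t < log$end_ms]
  )))
  starts <- bounds
  ends <- c(bounds[-1], log$end_ms)
  instr <- state_at(log$instructions$time_ms, log$instructions$type,
                    starts, NA_character_)
  posture <- state_at(log$hand$time_ms, log$hand$posture, starts,
                      log$initial_posture)
  onset_in <- vapply(seq_along(starts), function(i) {
    any(log$detections$corrected_ms >= starts[i] &
          log$detections$corrected_ms < ends[i])
  }, logical(1))
  same <- instr == posture
  tab <- c(
    TP = sum(!same & onset_in), FP = sum(same & onset_in),
    FN = sum(!same & !onset_in), TN = sum(same & !onset_in)
  )
  structure(
    list(table = tab, n_sections = length(starts),
         sections = data.frame(start_ms = starts, end_ms = ends,
                               instruction = instr, posture = posture,
                               same_state = same, onset = onset_in)),
    class = "section_table"
  )
}

#' @export
print.section_table <- function(x, ...) {
  cat(sprintf("<section_table> TP %d  FP %d  FN %d  TN %d (%d sections)\n",
              x$table["TP"], x$table["FP"], x$table["FN"], x$table["TN"],
              x$n_sections))
  invisible(x)
}

#' Movement-type accuracy over different-state detections
#'
#' Restricts to onsets whose delay-corrected time falls inside a
#' different-state section (the patient intended to move), cross-tabulates
#' instructed vs inferred type, and reports the percent of correct
#' inferences. With zero qualifying onsets the accuracy is undefined and
#' reported as `NA`, never as 0.
#'
#' @param log A `closed_loop_log`.
#' @return List: `contingency` (2x2 matrix, rows = instruction grasp/open,
#'   columns = inferred grasp/open), `accuracy` (percent or `NA`), `n`.
#' @export
movement_type_accuracy <- function(log) {
  sec <- classify_sections(log)$sections
  d <- log$detections
  keep <- logical(nrow(d))
  instr_at <- character(nrow(d))
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      j <- which(d$corrected_ms[i] >= sec$start_ms &
                   d$corrected_ms[i] < sec$end_ms)
      if (length(j) && !sec$same_state[j[1]]) {
        keep[i] <- TRUE
        instr_at[i] <- sec$instruction[j[1]]
      }
    }
  }
  lv <- c("grasp", "open")
  cont <- table(factor(instr_at[keep], levels = lv),
                factor(d$inferred[keep], levels = lv))
  cont <- matrix(as.integer(cont), 2, 2,
                 dimnames = list(instruction = lv, inferred = lv))
  n <- sum(cont)
  acc <- if (n == 0) NA_real_ else 100 * sum(diag(cont)) / n
  list(contingency = cont, accuracy = acc, n = n)
}

#' Closed-loop performance summary
#'
#' @param log A `closed_loop_log`.
#' @return List with the section table, the type-accuracy contingency, the
#'   one-tailed Fisher p-values for both, and the mean number of onset
#'   detections per achieved hand transition.
#' @export
closed_loop_summary <- function(log) {
  sec <- classify_sections(log)
  mt <- movement_type_accuracy(log)
  tab <- sec$table
  det_per_transition <- if (nrow(log$hand)) {
    nrow(log$detections) / nrow(log$hand)
  } else NA_real_
  list(
    sections = sec,
    section_accuracy = contingency_accuracy(
      contingency_2x2(tab["TP"], tab["FP"], tab["FN"], tab["TN"])),
    section_p = fisher_exact_one_tailed(
      contingency_2x2(tab["TP"], tab["FP"], tab["FN"], tab["TN"])),
    type = mt,
    type_accuracy = mt$accuracy,
    type_p = if (mt$n > 0) fisher_exact_one_tailed(
      contingency_2x2(mt$contingency[1, 1], mt$contingency[1, 2],
                      mt$contingency[2, 1], mt$contingency[2, 2])) else NA_real_,
    detections_per_transition = det_per_transition
  )
}
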