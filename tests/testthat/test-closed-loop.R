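# Hand-built log for sectioning-rule oracles.
fake_log <- function(instructions, detections, hand, end_ms,
                     initial_posture = "open") {
  structure(
    list(instructions = instructions, detections = detections, hand = hand,
         initial_posture = initial_posture, end_ms = end_ms),
    class = "closed_loop_log"
  )
}

no_det <- data.frame(time_ms = numeric(0), corrected_ms = numeric(0),
                     inferred = character(0))
no_hand <- data.frame(time_ms = numeric(0), posture = character(0))

test_that("the delay model sums its components", {
  d <- delay_model()
  expect_equal(d$total_ms, 0.02 + 70 + 500 + 150 + 110)
  expect_equal(d$total_ms, 830, tolerance = 0.001)
})

test_that("section classification walks the instruction/hand timeline", {
  instr2 <- data.frame(time_ms = c(0, 7000), type = c("grasp", "open"))

  # hand always matching, no detections: every section is a true negative
  matching <- fake_log(instr2, no_det, no_hand, 14000,
                       initial_posture = "grasp")
  # instruction 2 is open vs grasp hand -> one different-state section
  s <- classify_sections(matching)
  expect_equal(s$table, c(TP = 0L, FP = 0L, FN = 1L, TN = 1L))

  # one detection flips the hand to grasp during instruction 1:
  # [0, flip) different-state with onset (TP), [flip, 7000) same-state
  # without onset (TN), [7000, end) open vs grasp hand without onset (FN)
  log1 <- fake_log(
    instr2,
    data.frame(time_ms = 3070, corrected_ms = 3000, inferred = "grasp"),
    data.frame(time_ms = 3150, posture = "grasp"),
    14000
  )
  s1 <- classify_sections(log1)
  expect_equal(s1$table, c(TP = 1L, FP = 0L, FN = 1L, TN = 1L))
  expect_equal(s1$n_sections, 3L)
  expect_equal(sum(s1$table), s1$n_sections)

  # without hand-state changes, sections = instruction count
  many <- data.frame(time_ms = seq(0, 63000, 7000),
                     type = rep(c("grasp", "open"), 5))
  s2 <- classify_sections(fake_log(many, no_det, no_hand, 70000))
  expect_equal(s2$n_sections, 10L)
  expect_equal(sum(s2$table), 10L)

  expect_error(
    classify_sections(fake_log(many[0, ], no_det, no_hand, 1000)),
    class = "empty_log")
})

test_that("an onset on a section boundary belongs to the later section", {
  instr2 <- data.frame(time_ms = c(0, 7000), type = c("grasp", "open"))
  # hand grasp throughout; onset exactly at the instruction change
  log <- fake_log(instr2,
                  data.frame(time_ms = 7070, corrected_ms = 7000,
                             inferred = "open"),
                  no_hand, 14000, initial_posture = "grasp")
  s <- classify_sections(log)
  # [0,7000) grasp/grasp without onset (TN); [7000,14000) open/grasp with
  # the boundary onset (TP)
  expect_equal(s$table, c(TP = 1L, FP = 0L, FN = 0L, TN = 1L))
})

test_that("type accuracy counts only different-state onsets", {
  instr <- data.frame(time_ms = c(0, 7000, 14000, 21000),
                      type = c("grasp", "open", "grasp", "open"))
  det <- data.frame(
    time_ms = c(2070, 9070, 16070),
    corrected_ms = c(2000, 9000, 16000),
    inferred = c("grasp", "grasp", "grasp")
  )
  # hand stays open: grasp instructions are different-state,
  # open instructions same-state
  log <- fake_log(instr, det, no_hand, 28000)
  mt <- movement_type_accuracy(log)
  # detections at 2000 and 16000 are in grasp (different-state) sections,
  # both inferred grasp (correct); 9000 is same-state and excluded
  expect_equal(mt$n, 2)
  expect_equal(mt$accuracy, 100)
  expect_equal(mt$contingency["grasp", "grasp"], 2L)

  # zero qualifying onsets: undefined, never zero
  mt0 <- movement_type_accuracy(fake_log(instr, no_det, no_hand, 28000))
  expect_true(is.na(mt0$accuracy))
  expect_identical(
    closed_loop_summary(fake_log(instr, no_det, no_hand, 28000))$type_p,
    NA_real_)
})

test_that("the closed-loop path reproduces offline SMFs bitwise", {
  ses <- small_session()
  st <- small_stats()
  dec <- cached("decoder_3", function() {
    train_realtime_decoder(ses, st, seed = 3)
  })
  stream <- cached("stream_4", function() {
    cfg <- sim_config(n_trials_per_type = 8, seed = 4)
    simulate_closed_loop_stream(cfg, tiny_array(),
                                rep(c("grasp", "open"), 6))
  })
  log <- run_closed_loop(stream, dec)
  st_stream <- compute_baseline_stats(stream, bands = character(0))
  idx <- round(seq(1, length(log$smf_time_ms), length.out = 12))
  for (i in idx) {
    offline <- compute_smf(stream, st_stream, log$smf_time_ms[i])$values
    expect_identical(log$smf[i, ], offline)
  }
  # detections and sections are internally consistent
  s <- classify_sections(log)
  expect_equal(sum(s$table), s$n_sections)
  expect_error(run_closed_loop(stream, list()), class = "usage_error")
})

test_that("a near-noiseless loop follows the instructions", {
  cfg <- sim_config(n_trials_per_type = 8, seed = 5, noise_pink_sd = 0,
                    noise_white_sd = 0.01, amplitude_jitter_sd = 0,
                    latency_jitter_sd_ms = 0, burst_prob = 1,
                    erd_depth = c(alpha = 0, beta = 0),
                    osc_amplitude = c(alpha = 0, beta = 0))
  open <- simulate_open_loop(cfg, tiny_array())
  st <- compute_baseline_stats(open, bands = character(0))
  dec <- train_realtime_decoder(open, st, seed = 5)
  cfg2 <- cfg
  cfg2$seed <- 6
  stream <- simulate_closed_loop_stream(cfg2, tiny_array(),
                                        rep(c("grasp", "open"), 5))
  log <- run_closed_loop(stream, dec)
  # every instruction is achieved: the hand reaches the instructed posture
  # before the next instruction
  achieved <- vapply(seq_len(nrow(log$instructions)), function(i) {
    t0 <- log$instructions$time_ms[i]
    t1 <- if (i < nrow(log$instructions)) log$instructions$time_ms[i + 1]
          else log$end_ms
    k <- log$hand$time_ms >= t0 & log$hand$time_ms < t1
    any(k) && tail(log$hand$posture[k], 1) == log$instructions$type[i]
  }, TRUE)
  expect_true(all(achieved))
  # hand transitions trail detections by the hand-control delay
  expect_true(all(log$hand$time_ms %in% (log$detections$time_ms + 150)))
})
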