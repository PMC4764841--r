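test_that("sensor array satisfies its geometric contracts", {
  arr <- make_sensor_array(160, seed = 7)
  expect_equal(arr$n_sensors, 160L)
  expect_equal(sum(arr$parietal_mask), 84L)
  # orientations unit, positions outside the conductor sphere
  expect_true(all(abs(sqrt(rowSums(arr$orientations^2)) - 1) < 1e-9))
  expect_true(all(sqrt(rowSums(arr$positions^2)) > arr$head_radius))
  # same seed reproduces the array exactly; boundary case all-parietal
  expect_identical(arr, make_sensor_array(160, seed = 7))
  expect_true(all(make_sensor_array(84, seed = 1)$parietal_mask))
  expect_error(make_sensor_array(83), class = "invalid_config")
})

test_that("open-loop schedule follows the block-cue task structure", {
  ses <- small_session()
  cues <- cue_events(ses)
  expect_equal(nrow(cues), 16L)
  expect_equal(as.vector(table(cues$label)), c(8L, 8L))
  expect_equal(unique(round(diff(cues$time_s), 10)), 5.5)
  # head segment is task-free: first cue after 50 s of baseline
  expect_gte(min(ses$schedule$time_s), 48)
  # blocks of four: type constant within each block of consecutive cues
  blocks <- split(cues$label, rep(seq_len(4), each = 4))
  expect_true(all(vapply(blocks, function(b) length(unique(b)) == 1, TRUE)))
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  cfg <- sim_config(n_trials_per_type = 4, seed = 99)
  a <- simulate_open_loop(cfg, tiny_array())
  b <- simulate_open_loop(cfg, tiny_array())
  expect_identical(a$data, b$data)
  expect_identical(a$schedule, b$schedule)
  s1 <- simulate_closed_loop_stream(cfg, tiny_array(),
                                    rep(c("grasp", "open"), 3))
  s2 <- simulate_closed_loop_stream(cfg, tiny_array(),
                                    rep(c("grasp", "open"), 3))
  expect_identical(s1$data, s2$data)
})

test_that("null generator has no cue-locked deflection", {
  cfg <- sim_config(n_trials_per_type = 8,
                    mrcf_amplitude = c(grasp = 0, open = 0),
                    erd_depth = c(alpha = 0, beta = 0), seed = 17)
  ses <- simulate_open_loop(cfg, tiny_array())
  cues <- cue_events(ses)
  # 500-ms mean around the template peak, averaged over trials, at the
  # sensor where the grasp pattern would have been strongest
  par <- which(ses$array$parietal_mask)
  ch <- par[which.max(abs(ses$truth$patterns$grasp[par]))]
  trial_means <- vapply(cues$time_s, function(tc) {
    idx <- round(tc * 1000) + 50:549
    mean(ses$data[ch, idx])
  }, 0)
  se <- sd(trial_means) / sqrt(length(trial_means))
  expect_lt(abs(mean(trial_means)), 3 * se)
})

test_that("cue-locked averaging over 40 trials recovers the injected MRCF", {
  # full task-scale session: 40 cues per movement type at default SNR
  ses <- cached("full_session", function() {
    simulate_open_loop(sim_config(seed = 3), tiny_array())
  })
  cues <- cue_events(ses)
  pat <- ses$truth$patterns$grasp
  tpl_ms <- ses$truth$template_ms
  grasp_cues <- cues$time_s[cues$label == "grasp"]
  avg <- matrix(0, nrow(ses$data), length(tpl_ms))
  for (tc in grasp_cues) {
    avg <- avg + ses$data[, round(tc * 1000) + tpl_ms]
  }
  avg <- avg / length(grasp_cues)
  # recovered time course: matched-filter projection onto the known pattern
  course <- as.vector(pat %*% avg) / sum(pat^2)
  expect_gt(cor(course, ses$truth$template), 0.9)

  # the higher-amplitude type deflects the parietal field more at the peak
  proj_win <- function(tc, pat) {
    mean(pat %*% ses$data[, round(tc * 1000) + 50:549]) / sum(pat^2)
  }
  m_grasp <- mean(vapply(grasp_cues, proj_win, 0, pat = pat))
  open_cues <- cues$time_s[cues$label == "open"]
  m_open <- mean(vapply(open_cues, proj_win, 0,
                        pat = ses$truth$patterns$open))
  expect_gt(m_grasp, m_open)
})

test_that("noiseless single-trial trace equals the projected template", {
  cfg <- sim_config(n_trials_per_type = 4, noise_pink_sd = 0,
                    noise_white_sd = 0, amplitude_jitter_sd = 0,
                    erd_depth = c(alpha = 0, beta = 0),
                    osc_amplitude = c(alpha = 0, beta = 0), seed = 2)
  ses <- simulate_open_loop(cfg, tiny_array())
  cues <- cue_events(ses)
  tc <- cues$time_s[1]
  ty <- cues$label[1]
  idx <- round(tc * 1000) + ses$truth$template_ms
  expected <- cfg$mrcf_amplitude[[ty]] *
    ses$truth$patterns[[ty]] %o% ses$truth$template
  expect_equal(ses$data[, idx], expected, tolerance = 1e-12)
})

test_that("movement-epoch alpha power is suppressed by the ERD depth", {
  depth <- 0.6
  cfg <- sim_config(n_trials_per_type = 20,
                    mrcf_amplitude = c(grasp = 0, open = 0),
                    erd_depth = c(alpha = depth, beta = 0),
                    osc_amplitude = c(alpha = 1, beta = 0),
                    noise_pink_sd = 0.05, noise_white_sd = 0.05, seed = 23)
  ses <- simulate_open_loop(cfg, tiny_array())
  ch <- which.max(abs(ses$truth$osc_pattern))
  cues <- round(cue_events(ses)$time_s * 1000)
  bp <- function(idx) {
    x <- ses$data[ch, idx]
    p <- Mod(fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) * 1000 / length(x)
    sum(p[f >= 8 & f < 13])
  }
  move <- mean(vapply(cues, function(cs) bp(cs + 0:499), 0))
  rest <- mean(vapply(cues, function(cs) bp(cs - 2500:2001), 0))
  # a 500-ms window of a 5-Hz-wide rhythm has ~5 spectral dof, so the mean
  # over 40 epochs carries ~10% relative error; 0.12 is a 3-sigma band
  expect_lt(abs(move / rest - (1 - depth)), 0.12)
})

test_that("closed-loop stream honours schedule, latency and guards", {
  cfg <- sim_config(seed = 4, latency_jitter_sd_ms = 0, burst_prob = 1,
                    noise_pink_sd = 0, noise_white_sd = 0,
                    amplitude_jitter_sd = 0,
                    erd_depth = c(alpha = 0, beta = 0),
                    osc_amplitude = c(alpha = 0, beta = 0))
  instr <- rep(c("grasp", "open"), 11)
  ses <- simulate_closed_loop_stream(cfg, tiny_array(), instr)
  # 22 instructions at 7 s on top of the 50-s head segment
  expect_gte(ncol(ses$data) / 1000, 50 + 154)
  expect_equal(nrow(ses$schedule), 22L)
  # with zero jitter and zero noise, bursts sit exactly at
  # instruction + latency
  expect_equal(ses$truth$burst$time_s,
               ses$schedule$time_s + cfg$reaction_latency_ms / 1000)
  expect_error(simulate_closed_loop_stream(cfg, tiny_array(), character(0)),
               class = "invalid_config")
  expect_error(
    simulate_closed_loop_stream(cfg, tiny_array(), c("grasp", "grasp")),
    class = "invalid_config")
  # burst probability 0 leaves a pure-noise stream
  cfg0 <- sim_config(seed = 4, burst_prob = 0)
  ses0 <- simulate_closed_loop_stream(cfg0, tiny_array(), instr)
  expect_false(any(ses0$truth$burst$elicited))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(erd_depth = c(alpha = 1.2, beta = 0)),
               class = "invalid_config")
  expect_error(sim_config(mrcf_amplitude = c(grasp = -1, open = 1)),
               class = "invalid_config")
  expect_error(sim_config(n_trials_per_type = 6), class = "invalid_config")
  # identical patches and amplitudes would make decoding chance by design
  expect_error(sim_config(mrcf_amplitude = c(grasp = 1, open = 1),
                          patch_dirs = list(grasp = c(-0.5, -0.15, 0.85),
                                            open = c(-0.5, -0.15, 0.85))),
               class = "invalid_config")
  expect_error(
    simulate_open_loop(sim_config(n_trials_per_type = 8, duration_s = 60),
                       tiny_array()),
    class = "invalid_config")
})
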