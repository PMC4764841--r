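#' Simulation configuration for synthetic MEG sessions
#'
#' Bundles every tunable of the synthetic generator. Defaults reproduce the
#' open-loop task structure the decoding analysis assumes: execution cues
#' every 5.5 s, 40 trials per movement type in blocks of four, a task-free
#' 50-s head segment for baseline statistics, movement-related cortical
#' fields (MRCF) that ramp up from 1 s before the cue and peak 300 ms after
#' it with movement-type-dependent amplitude and dipole patch, alpha/beta
#' event-related desynchronization, and 1/f plus white sensor noise.
#'
#' @param n_trials_per_type Execution cues per movement type (default 40).
#' @param iti_s Inter-cue interval in seconds (default 5.5).
#' @param baseline_s Task-free head segment in seconds (default 50); baseline
#'   z-scoring statistics are estimated from it downstream.
#' @param mrcf_amplitude Named numeric, peak parietal-sensor amplitude (a.u.)
#'   of the MRCF for each movement type. Types must differ in amplitude
#'   and/or dipole patch or decoding is at chance by construction.
#' @param mrcf_ramp_start_ms,mrcf_peak_ms,mrcf_end_ms Raised-cosine MRCF
#'   template: zero before `mrcf_ramp_start_ms` (default -1000, i.e. 1 s
#'   before the cue), 1 at `mrcf_peak_ms` (default +300), back to zero at
#'   `mrcf_end_ms` (default +1000).
#' @param amplitude_jitter_sd Multiplicative trial-to-trial SD of the MRCF
#'   amplitude (Gaussian gain about 1, truncated at 0); models attempt-to-
#'   attempt variability.
#' @param patch_dirs Named list of unit-ish 3-vectors: centre directions of
#'   the dipole patch for each movement type (default: two nearby
#'   contralateral sensorimotor locations).
#' @param patch_size Vertices per dipole patch (default 6).
#' @param erd_depth Named numeric in `[0, 1]`: fractional power suppression of
#'   the alpha and beta rhythms during the movement epoch.
#' @param osc_amplitude Named numeric: baseline standard deviation (a.u.) of
#'   the alpha and beta rhythms at their peak sensor.
#' @param noise_pink_sd,noise_white_sd Per-sensor standard deviations of the
#'   1/f^alpha background and the spatially white noise (a.u.).
#' @param one_over_f_exponent Spectral exponent alpha of the background.
#' @param n_vertices Vertices of the internal toy cortical mesh.
#' @param mesh_seed Seed of the toy cortical mesh. Distinct from `seed` so
#'   that the head geometry (and hence the spatial patterns a decoder
#'   learns) stays fixed across a subject's sessions while the
#'   noise/schedule realization varies.
#' @param reaction_latency_ms Closed-loop only: mean latency from instruction
#'   change to MRCF burst (default 500 ms).
#' @param latency_jitter_sd_ms Closed-loop only: SD of the latency jitter.
#' @param burst_prob Closed-loop only: probability that an instruction
#'   actually elicits an MRCF burst (models attentional lapses).
#' @param instruction_period_s Closed-loop only: instruction period (7 s).
#' @param duration_s Total session duration; `NULL` (default) sizes the
#'   session automatically from the schedule.
#' @param seed Integer seed; every random draw in the generator derives from
#'   it, so sessions are bitwise reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials_per_type = 40,
                       iti_s = 5.5,
                       baseline_s = 50,
                       mrcf_amplitude = c(grasp = 1.25, open = 1.0),
                       mrcf_ramp_start_ms = -1000,
                       mrcf_peak_ms = 300,
                       mrcf_end_ms = 1000,
                       amplitude_jitter_sd = 0.2,
                       patch_dirs = list(
                         grasp = c(-0.50, -0.15, 0.85),
                         open  = c(-0.45, -0.23, 0.86)
                       ),
                       patch_size = 6,
                       erd_depth = c(alpha = 0.5, beta = 0.4),
                       osc_amplitude = c(alpha = 1.0, beta = 0.6),
                       noise_pink_sd = 1.0,
                       noise_white_sd = 0.5,
                       one_over_f_exponent = 1,
                       n_vertices = 200,
                       mesh_seed = 42,
                       reaction_latency_ms = 500,
                       latency_jitter_sd_ms = 50,
                       burst_prob = 0.95,
                       instruction_period_s = 7,
                       duration_s = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(cfg$erd_depth < 0 | cfg$erd_depth > 1)) {
    stop_smf("invalid_config", "erd_depth must lie in [0, 1]")
  }
  if (any(cfg$mrcf_amplitude < 0)) {
    stop_smf("invalid_config", "mrcf_amplitude must be >= 0")
  }
  if (cfg$n_trials_per_type %% 4 != 0) {
    stop_smf("invalid_config",
             "n_trials_per_type must be a multiple of 4 (blocks of four cues, balanced block order)")
  }
  if (!all(c("grasp", "open") %in% names(cfg$mrcf_amplitude))) {
    stop_smf("invalid_config", "mrcf_amplitude needs 'grasp' and 'open' entries")
  }
  if (cfg$mrcf_ramp_start_ms >= cfg$mrcf_peak_ms ||
      cfg$mrcf_peak_ms >= cfg$mrcf_end_ms) {
    stop_smf("invalid_config", "MRCF template must satisfy ramp_start < peak < end")
  }
  same_patch <- isTRUE(all.equal(cfg$patch_dirs$grasp, cfg$patch_dirs$open))
  if (same_patch && cfg$mrcf_amplitude["grasp"] == cfg$mrcf_amplitude["open"]) {
    stop_smf("invalid_config",
             "movement types must differ in dipole patch and/or amplitude")
  }
  invisible(cfg)
}

# Raised-cosine MRCF temporal template evaluated at t_ms relative to the cue.
mrcf_template <- function(t_ms, ramp_start = -1000, peak = 300, end = 1000) {
  y <- numeric(length(t_ms))
  up <- t_ms >= ramp_start & t_ms <= peak
  dn <- t_ms > peak & t_ms <= end
  y[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - ramp_start) / (peak - ramp_start)))
  y[dn] <- 0.5 * (1 + cos(pi * (t_ms[dn] - peak) / (end - peak)))
  y
}

# 1/f^alpha noise via spectral shaping; one column per sensor.
gen_pink_noise <- function(n, n_ch, sd, alpha) {
  if (sd <= 0) return(matrix(0, n, n_ch))
  nfft <- stats::nextn(n)
  freqs <- c(1, seq_len(nfft - 1))             # avoid DC blow-up
  shape <- freqs^(-alpha / 2)
  shape[1] <- 0
  out <- matrix(0, n, n_ch)
  for (ch in seq_len(n_ch)) {
    w <- rnorm(nfft)
    x <- Re(fft(fft(w) * shape, inverse = TRUE)) / nfft
    x <- x[seq_len(n)]
    out[, ch] <- x / sd(x) * sd
  }
  out
}

# Narrow-band Gaussian process: white noise band-passed in the frequency
# domain with raised-cosine band edges, unit SD.
gen_band_oscillation <- function(n, f_lo, f_hi, rate, edge_hz = 1) {
  nfft <- stats::nextn(n)
  w <- rnorm(nfft)
  W <- fft(w)
  f <- (seq_len(nfft) - 1) * rate / nfft
  f <- pmin(f, rate - f)                       # two-sided spectrum
  g <- numeric(nfft)
  core <- f >= f_lo & f <= f_hi
  g[core] <- 1
  lo_edge <- f >= f_lo - edge_hz & f < f_lo
  hi_edge <- f > f_hi & f <= f_hi + edge_hz
  g[lo_edge] <- 0.5 * (1 - cos(pi * (f[lo_edge] - (f_lo - edge_hz)) / edge_hz))
  g[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - f_hi) / edge_hz))
  x <- Re(fft(W * g, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / sd(x)
}

# Sensor-space spatial pattern of a dipole patch: lead-field columns of the
# `patch_size` vertices nearest `dir`, Gaussian-weighted, peak-normalized
# over the parietal subset.
patch_pattern <- function(lf, dir, patch_size) {
  mesh <- lf$mesh
  dir <- dir / vnorm(dir)
  vdir <- mesh$positions / row_norms(mesh$positions)
  ang <- acos(pmin(1, pmax(-1, vdir %*% dir)))
  idx <- order(ang)[seq_len(patch_size)]
  w <- exp(-(ang[idx] / (ang[idx][patch_size] + 1e-9))^2)
  pat <- as.vector(lf$L[, idx, drop = FALSE] %*% w)
  peak <- max(abs(pat[lf$array$parietal_mask]))
  if (peak < .Machine$double.eps) {
    stop_smf("invalid_config", "dipole patch is magnetically silent at the parietal sensors")
  }
  list(pattern = pat / peak, vertices = idx, weights = w)
}

# Multiplicative ERD gain: 1 at rest, dropping to sqrt(1 - depth) during each
# movement epoch [t_cue - 250, t_cue + 750] ms with 200-ms raised-cosine edges.
erd_gain <- function(n, rate, cue_samples, depth,
                     epoch = c(-250, 750), edge_ms = 200) {
  g <- rep(1, n)
  if (depth <= 0 || !length(cue_samples)) return(g)
  lo_gain <- sqrt(1 - depth)
  edge <- round(edge_ms * rate / 1000)
  e0 <- round(epoch[1] * rate / 1000)
  e1 <- round(epoch[2] * rate / 1000)
  for (cs in cue_samples) {
    a <- cs + e0
    b <- cs + e1
    idx <- max(1, a):min(n, b)
    g[idx] <- lo_gain
    ramp_in <- max(1, a - edge):max(1, a - 1)
    if (length(ramp_in) && a - edge >= 1) {
      tt <- seq_along(ramp_in) / (length(ramp_in) + 1)
      g[ramp_in] <- pmin(g[ramp_in], 1 + (lo_gain - 1) * 0.5 * (1 - cos(pi * tt)))
    }
    ramp_out <- min(n, b + 1):min(n, b + edge)
    if (length(ramp_out) && b + 1 <= n) {
      tt <- seq_along(ramp_out) / (length(ramp_out) + 1)
      g[ramp_out] <- pmin(g[ramp_out], lo_gain + (1 - lo_gain) * 0.5 * (1 - cos(pi * tt)))
    }
  }
  g
}

# Shared scaffolding: mesh, lead field, per-type spatial patterns,
# oscillation pattern.
build_forward <- function(cfg, array, forward = NULL) {
  if (is.null(forward)) {
    mesh <- make_cortical_mesh(n_vertices = cfg$n_vertices,
                               head_radius = array$head_radius,
                               seed = cfg$mesh_seed %||% 42)
    forward <- compute_lead_field(mesh, array)
  }
  patches <- lapply(cfg$patch_dirs, patch_pattern,
                    lf = forward, patch_size = cfg$patch_size)
  osc_dir <- (cfg$patch_dirs$grasp + cfg$patch_dirs$open) / 2
  osc <- patch_pattern(forward, osc_dir, cfg$patch_size)
  list(lf = forward, patches = patches, osc = osc)
}

new_meg_session <- function(data, schedule, array, cfg, truth, kind) {
  structure(
    list(
      data = data,
      rate = 1000,
      lowpass = 200,
      schedule = schedule,
      array = array,
      config = cfg,
      truth = truth,
      kind = kind,
      seed = cfg$seed
    ),
    class = "meg_session"
  )
}

#' @export
print.meg_session <- function(x, ...) {
  cat(sprintf(
    "<meg_session:%s> %d sensors x %d samples @ %d Hz (%.1f s), %d events, seed %s\n",
    x$kind, nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
    nrow(x$schedule), format(x$seed)
  ))
  invisible(x)
}

#' Execution-cue table of a session
#'
#' @param session A `meg_session`.
#' @return Data frame with `time_s` and movement-type `label` for each
#'   execution cue.
#' @export
cue_events <- function(session) {
  sc <- session$schedule
  sc[sc$event == "cue", c("time_s", "label")]
}

#' Simulate an open-loop MEG session
#'
#' Generates the training-session structure the decoder assumes: a 50-s
#' task-free head segment, then blocks of four execution cues of one movement
#' type every `iti_s` seconds, balanced across types in randomized block
#' order. At each cue the generator adds (i) the movement type's MRCF
#' waveform projected through the single-sphere lead field from its dipole
#' patch, (ii) multiplicative alpha/beta power suppression over the movement
#' epoch, on top of (iii) 1/f plus white sensor noise. Bitwise reproducible
#' for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @param array A [make_sensor_array()] result.
#' @param forward Optional precomputed [compute_lead_field()] object, to
#'   share geometry across sessions.
#' @return A `meg_session` with `data` (sensors x samples), event `schedule`,
#'   and a `truth` element holding the noiseless templates and patch
#'   geometry for validation.
#' @export
simulate_open_loop <- function(config, array, forward = NULL) {
  validate_sim_config(config)
  rate <- 1000
  n_cues <- 2L * config$n_trials_per_type
  need_s <- config$baseline_s + config$iti_s * n_cues + 2
  duration <- config$duration_s %||% need_s
  if (duration < need_s) {
    stop_smf("invalid_config",
             "duration_s = %.1f too short: schedule needs %.1f s", duration, need_s)
  }

  with_seed(config$seed, {
    fwd <- build_forward(config, array, forward)
    n <- round(duration * rate)

    # block schedule: 4 same-type cues per block, balanced randomized order
    n_blocks <- n_cues / 4
    types <- sample(rep(c("grasp", "open"), each = n_blocks / 2))
    cue_type <- rep(types, each = 4)
    cue_time <- config$baseline_s + config$iti_s * seq_len(n_cues)
    instr_time <- cue_time[seq(1, n_cues, by = 4)] - 2
    schedule <- rbind(
      data.frame(time_s = instr_time,
                 event = paste0("instruction_", types),
                 label = types),
      data.frame(time_s = cue_time, event = "cue", label = cue_type)
    )
    schedule <- schedule[order(schedule$time_s), ]
    rownames(schedule) <- NULL

    data <- t(gen_pink_noise(n, array$n_sensors, config$noise_pink_sd,
                             config$one_over_f_exponent))
    if (config$noise_white_sd > 0) {
      data <- data + matrix(rnorm(length(data), sd = config$noise_white_sd),
                            nrow = array$n_sensors)
    }

    # MRCF: type-specific spatial pattern (x) raised-cosine time course
    tpl_ms <- seq(config$mrcf_ramp_start_ms, config$mrcf_end_ms)
    tpl <- mrcf_template(tpl_ms, config$mrcf_ramp_start_ms,
                         config$mrcf_peak_ms, config$mrcf_end_ms)
    cue_samp <- round(cue_time * rate)
    for (k in seq_len(n_cues)) {
      ty <- cue_type[k]
      amp <- config$mrcf_amplitude[[ty]]
      if (amp <= 0) next
      if (config$amplitude_jitter_sd > 0) {
        amp <- amp * max(0, 1 + rnorm(1, sd = config$amplitude_jitter_sd))
      }
      idx <- cue_samp[k] + tpl_ms
      keep <- idx >= 1 & idx <= n
      data[, idx[keep]] <- data[, idx[keep]] +
        amp * fwd$patches[[ty]]$pattern %o% tpl[keep]
    }

    # alpha/beta rhythms with movement-locked desynchronization
    bands <- list(alpha = c(8, 13), beta = c(13, 30))
    for (b in names(bands)) {
      oa <- config$osc_amplitude[[b]]
      if (is.null(oa) || oa <= 0) next
      s <- gen_band_oscillation(n, bands[[b]][1], bands[[b]][2], rate)
      g <- erd_gain(n, rate, cue_samp, config$erd_depth[[b]])
      data <- data + oa * fwd$osc$pattern %o% (g * s)
    }

    truth <- list(
      template_ms = tpl_ms,
      template = tpl,
      patterns = lapply(fwd$patches, `[[`, "pattern"),
      patch_vertices = lapply(fwd$patches, `[[`, "vertices"),
      osc_pattern = fwd$osc$pattern,
      lead_field = fwd$lf,
      cue_samples = cue_samp
    )
    new_meg_session(data, schedule, array, config, truth, "open_loop")
  })
}

#' Simulate a closed-loop MEG stream
#'
#' Generates the feedback-session structure: the task-free head segment, then
#' one instruction every `instruction_period_s` seconds. After each
#' instruction change the instructed type's MRCF burst is injected with a
#' configurable reaction latency (default 500 ms, Gaussian jitter), with
#' probability `burst_prob`; ERD accompanies each burst.
#'
#' @inheritParams simulate_open_loop
#' @param instructions Character vector over `{grasp, open}`; must alternate
#'   (default 22 alternating instructions).
#' @return A `meg_session` whose schedule holds the instruction events;
#'   `truth$burst` records which instructions elicited a burst and when.
#' @export
simulate_closed_loop_stream <- function(config, array,
                                        instructions = rep(c("grasp", "open"), 11),
                                        forward = NULL) {
  validate_sim_config(config)
  if (!length(instructions)) {
    stop_smf("invalid_config", "instruction list must be non-empty")
  }
  if (!all(instructions %in% c("grasp", "open"))) {
    stop_smf("invalid_config", "instructions must be 'grasp' or 'open'")
  }
  if (length(instructions) > 1 &&
      any(instructions[-1] == instructions[-length(instructions)])) {
    stop_smf("invalid_config", "instructions must alternate")
  }
  rate <- 1000
  k <- length(instructions)
  need_s <- config$baseline_s + config$instruction_period_s * k + 2
  duration <- config$duration_s %||% need_s
  if (duration < need_s) {
    stop_smf("invalid_config",
             "duration_s = %.1f too short: schedule needs %.1f s", duration, need_s)
  }

  with_seed(config$seed, {
    fwd <- build_forward(config, array, forward)
    n <- round(duration * rate)
    instr_time <- config$baseline_s + config$instruction_period_s * (seq_len(k) - 1)
    schedule <- data.frame(
      time_s = instr_time,
      event = paste0("instruction_", instructions),
      label = instructions
    )

    data <- t(gen_pink_noise(n, array$n_sensors, config$noise_pink_sd,
                             config$one_over_f_exponent))
    if (config$noise_white_sd > 0) {
      data <- data + matrix(rnorm(length(data), sd = config$noise_white_sd),
                            nrow = array$n_sensors)
    }

    tpl_ms <- seq(config$mrcf_ramp_start_ms, config$mrcf_end_ms)
    tpl <- mrcf_template(tpl_ms, config$mrcf_ramp_start_ms,
                         config$mrcf_peak_ms, config$mrcf_end_ms)

    burst <- data.frame(instruction = seq_len(k), type = instructions,
                        time_s = NA_real_, elicited = FALSE)
    burst_samp <- integer(0)
    for (j in seq_len(k)) {
      if (runif(1) > config$burst_prob) next
      lat <- config$reaction_latency_ms +
        if (config$latency_jitter_sd_ms > 0)
          rnorm(1, sd = config$latency_jitter_sd_ms) else 0
      t_b <- instr_time[j] + lat / 1000
      ty <- instructions[j]
      amp <- config$mrcf_amplitude[[ty]]
      if (config$amplitude_jitter_sd > 0) {
        amp <- amp * max(0, 1 + rnorm(1, sd = config$amplitude_jitter_sd))
      }
      bs <- round(t_b * rate)
      idx <- bs + tpl_ms
      keep <- idx >= 1 & idx <= n
      if (amp > 0) {
        data[, idx[keep]] <- data[, idx[keep]] +
          amp * fwd$patches[[ty]]$pattern %o% tpl[keep]
      }
      burst$time_s[j] <- t_b
      burst$elicited[j] <- TRUE
      burst_samp <- c(burst_samp, bs)
    }

    bands <- list(alpha = c(8, 13), beta = c(13, 30))
    for (b in names(bands)) {
      oa <- config$osc_amplitude[[b]]
      if (is.null(oa) || oa <= 0) next
      s <- gen_band_oscillation(n, bands[[b]][1], bands[[b]][2], rate)
      g <- erd_gain(n, rate, burst_samp, config$erd_depth[[b]])
      data <- data + oa * fwd$osc$pattern %o% (g * s)
    }

    truth <- list(
      template_ms = tpl_ms, template = tpl,
      patterns = lapply(fwd$patches, `[[`, "pattern"),
      patch_vertices = lapply(fwd$patches, `[[`, "vertices"),
      osc_pattern = fwd$osc$pattern,
      lead_field = fwd$lf,
      burst = burst
    )
    new_meg_session(data, schedule, array, config, truth, "closed_loop")
  })
}
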