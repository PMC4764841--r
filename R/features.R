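#' Baseline statistics from the head segment of a session
#'
#' Estimates the per-channel mean and standard deviation of the raw signal
#' over exactly the initial 50 s of the session, plus the per-channel mean/SD
#' of 500-ms-window band powers (sliding by `hop_ms`) over the same segment.
#' These are the normalizers for the slow movement field (SMF) and the
#' band-power features respectively.
#'
#' @param session A `meg_session` of duration >= `baseline_s`.
#' @param baseline_s Length of the head segment in seconds (default 50).
#' @param bands Character vector of band names to pre-compute baselines for.
#' @param hop_ms Hop of the sliding baseline band-power windows (default 100).
#' @param taper `"none"` (default) or `"hann"`; must match the taper used in
#'   [compute_band_power()].
#' @return Object of class `baseline_stats`: `mean`, `sd` (length n_sensors),
#'   and `band` — a named list with `mean`/`sd` vectors of length 84 (the
#'   parietal subset) per band.
#' @export
compute_baseline_stats <- function(session, baseline_s = 50,
                                   bands = c("alpha", "beta", "high_gamma"),
                                   hop_ms = 100, taper = "none") {
  stopifnot(inherits(session, "meg_session"))
  n <- ncol(session$data)
  n_base <- round(baseline_s * session$rate)
  if (n < n_base) {
    stop_smf("insufficient_baseline",
             "session lasts %.1f s; %.0f s of baseline required",
             n / session$rate, baseline_s)
  }
  seg <- session$data[, seq_len(n_base), drop = FALSE]
  mu <- rowMeans(seg)
  sigma <- apply(seg, 1, sd)
  par_idx <- which(session$array$parietal_mask)
  degen <- par_idx[sigma[par_idx] == 0]
  if (length(degen)) {
    stop_smf("degenerate_channel",
             "zero baseline SD in channel(s): %s",
             paste(degen, collapse = ", "))
  }

  band_stats <- list()
  if (length(bands)) {
    win <- 500L
    ends <- seq(win, n_base, by = hop_ms)
    pw <- lapply(bands, function(b) matrix(0, length(ends), length(par_idx)))
    names(pw) <- bands
    for (i in seq_along(ends)) {
      idx <- (ends[i] - win + 1L):ends[i]
      p <- window_band_powers(seg[par_idx, idx, drop = FALSE],
                              mu[par_idx], session$rate, bands, taper)
      for (b in bands) pw[[b]][i, ] <- p[[b]]
    }
    band_stats <- lapply(pw, function(m) {
      list(mean = colMeans(m), sd = apply(m, 2, sd))
    })
  }

  structure(
    list(mean = mu, sd = sigma, band = band_stats,
         baseline_s = baseline_s, hop_ms = hop_ms, taper = taper,
         parietal = par_idx),
    class = "baseline_stats"
  )
}

band_limits <- function(band) {
  switch(band,
    alpha = c(8, 13),
    beta = c(13, 30),
    high_gamma = c(80, 150),
    stop_smf("invalid_config", "unknown band '%s'", band)
  )
}

# Raw band powers of one 500-ms window (channels x samples). Demeans each
# channel by its baseline mean, FFTs, and sums |X_k|^2 over positive-frequency
# bins with f in [lo, hi).
window_band_powers <- function(win_data, base_mean, rate, bands, taper = "none") {
  nt <- ncol(win_data)
  x <- t(win_data - base_mean)                 # samples x channels
  if (taper == "hann") {
    h <- 0.5 * (1 - cos(2 * pi * (seq_len(nt) - 1) / (nt - 1)))
    x <- x * h
  }
  X <- stats::mvfft(x)
  P <- Mod(X)^2
  freqs <- (seq_len(nt) - 1) * rate / nt
  out <- lapply(bands, function(b) {
    lim <- band_limits(b)
    bins <- which(freqs >= lim[1] & freqs < lim[2] & freqs <= rate / 2)
    colSums(P[bins, , drop = FALSE])
  })
  names(out) <- bands
  out
}

window_sample_idx <- function(session, window_end_ms, win_ms = 500) {
  rate <- session$rate
  i1 <- round((window_end_ms - win_ms) * rate / 1000) + 1L
  i2 <- round(window_end_ms * rate / 1000)
  if (i1 < 1 || i2 > ncol(session$data)) {
    stop_smf("window_bounds",
             "window [%.0f, %.0f) ms lies outside the session (%.0f ms)",
             window_end_ms - win_ms, window_end_ms,
             1000 * ncol(session$data) / rate)
  }
  i1:i2
}

new_feature_window <- function(kind, values, window_end_ms) {
  structure(
    list(kind = kind, values = as.numeric(values),
         window_end_ms = window_end_ms, window_ms = 500),
    class = "feature_window"
  )
}

#' Slow movement field of one 500-ms window
#'
#' The SMF at time `t` is the per-channel mean of the raw parietal signal
#' over the causal window `[t - 500, t)` ms, z-scored with the baseline mean
#' and SD. A feature labelled `t` therefore uses no samples at or after `t`,
#' which is what the real-time decoding path requires.
#'
#' @param session A `meg_session`.
#' @param stats A [compute_baseline_stats()] result.
#' @param window_end_ms Window end in ms from session start.
#' @return A `feature_window` with `kind = "smf"` and 84 z-score values.
#' @export
compute_smf <- function(session, stats, window_end_ms) {
  idx <- window_sample_idx(session, window_end_ms)
  par <- stats$parietal
  m <- rowMeans(session$data[par, idx, drop = FALSE])
  new_feature_window("smf", (m - stats$mean[par]) / stats$sd[par], window_end_ms)
}

#' Band power of one 500-ms window
#'
#' Computes the discrete-Fourier power of the same causal 500-ms window used
#' for the SMF, summed over frequency bins in the band (alpha 8-13 Hz, beta
#' 13-30 Hz, high gamma 80-150 Hz; half-open intervals), then z-scores each
#' channel against the band-power distribution of the 50-s baseline segment.
#'
#' @inheritParams compute_smf
#' @param band One of `"alpha"`, `"beta"`, `"high_gamma"`.
#' @param raw If `TRUE`, return the non-normalized band powers (all >= 0)
#'   instead of baseline z-scores.
#' @return A `feature_window` with 84 values.
#' @export
compute_band_power <- function(session, stats, window_end_ms, band, raw = FALSE) {
  idx <- window_sample_idx(session, window_end_ms)
  par <- stats$parietal
  p <- window_band_powers(session$data[par, idx, drop = FALSE],
                          stats$mean[par], session$rate, band, stats$taper)[[band]]
  if (raw) return(new_feature_window(band, p, window_end_ms))
  bs <- stats$band[[band]]
  if (is.null(bs)) {
    stop_smf("invalid_config",
             "baseline stats lack band '%s'; recompute with it included", band)
  }
  new_feature_window(band, (p - bs$mean) / bs$sd, window_end_ms)
}

#' Sliding window grid
#'
#' @param start,end,step Window-end times in ms (relative to a cue when used
#'   for trial extraction). Defaults cover -2000..1000 ms in 100-ms steps.
#' @return Numeric vector of window ends with class `window_grid`.
#' @export
window_grid <- function(start = -2000, end = 1000, step = 100) {
  if (step <= 0 || start >= end) {
    stop_smf("invalid_config", "window grid needs step > 0 and start < end")
  }
  structure(seq(start, end, by = step), class = "window_grid",
            start = start, end = end, step = step)
}

#' Extract cue-locked feature sets for decoding
#'
#' For every execution cue and every window end on `grid` (ms relative to the
#' cue), computes the requested feature kinds over the causal 500-ms window.
#'
#' @inheritParams compute_smf
#' @param grid A [window_grid()] or numeric vector of window ends (ms,
#'   cue-relative).
#' @param kinds Any of `"smf"`, `"alpha"`, `"beta"`, `"high_gamma"`.
#' @return Object of class `labeled_feature_set`: `features` is a named list
#'   of arrays `[n_trials x n_windows x 84]`, with `labels` (movement type
#'   per trial), `trial_id`, `cue_time_s`, and `window_end_ms`.
#' @export
extract_features <- function(session, stats, grid = window_grid(),
                             kinds = "smf") {
  cues <- cue_events(session)
  n_tr <- nrow(cues)
  grid <- as.numeric(grid)
  n_w <- length(grid)
  par <- stats$parietal
  feats <- lapply(kinds, function(k) array(NA_real_, c(n_tr, n_w, length(par))))
  names(feats) <- kinds
  for (i in seq_len(n_tr)) {
    cue_ms <- cues$time_s[i] * 1000
    for (j in seq_len(n_w)) {
      for (k in kinds) {
        fw <- if (k == "smf") {
          compute_smf(session, stats, cue_ms + grid[j])
        } else {
          compute_band_power(session, stats, cue_ms + grid[j], k)
        }
        feats[[k]][i, j, ] <- fw$values
      }
    }
  }
  structure(
    list(features = feats, labels = cues$label, trial_id = seq_len(n_tr),
         cue_time_s = cues$time_s, window_end_ms = grid, kinds = kinds),
    class = "labeled_feature_set"
  )
}

#' @export
print.labeled_feature_set <- function(x, ...) {
  cat(sprintf(
    "<labeled_feature_set> %d trials (%s), %d windows [%g..%g ms], kinds: %s\n",
    length(x$labels), paste(names(table(x$labels)), table(x$labels),
                            sep = "=", collapse = ", "),
    length(x$window_end_ms), min(x$window_end_ms), max(x$window_end_ms),
    paste(x$kinds, collapse = ", ")
  ))
  invisible(x)
}
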