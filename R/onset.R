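# libsvm's decision-value sign depends on class encounter order; flip so
# that larger always means "intention".
svm_flip <- function(fit, x_probe) {
  dv <- attr(predict(fit, x_probe, decision.values = TRUE), "decision.values")
  if (colnames(dv)[1] == "rest/intention") -1 else 1
}

#' Train the dual confidence models for movement-intention timing
#'
#' Fits the two models whose joint threshold crossing defines an onset:
#' an RBF-kernel SVM classifier of rest vs intention whose decision values
#' are sigmoid-calibrated into a probability-like confidence `c_svm` in
#' `[0, 1]`, and a Gaussian process regression trained on a boxcar intention
#' target (0 on rest windows, 1 on intention windows) whose posterior mean is
#' the confidence `c_gpr`. Both operate on single 500-ms SMFs, as the
#' real-time path sees them. Retraining with identical inputs reproduces
#' identical confidences.
#'
#' @param x Numeric matrix of SMF windows (examples x 84).
#' @param y Labels: `"rest"` / `"intention"` (or 0/1).
#' @param gamma,cost SVM hyperparameters.
#' @param gpr_sigma RBF bandwidth of the GPR kernel; `NULL` (default) uses
#'   the deterministic median-heuristic `1 / (2 * median squared distance)`.
#' @param gpr_noise GPR observation-noise variance.
#' @param seed Seed of the internal fold split used for the sigmoid
#'   calibration.
#' @return Object of class `confidence_models`.
#' @export
train_confidence_models <- function(x, y, gamma = 0.01, cost = 1,
                                    gpr_sigma = NULL, gpr_noise = 0.1,
                                    seed = 1) {
  y <- as.character(y)
  y[y %in% c("0", "FALSE")] <- "rest"
  y[y %in% c("1", "TRUE")] <- "intention"
  if (length(unique(y)) < 2) {
    stop_smf("stratification_error", "need both rest and intention examples")
  }
  yf <- factor(y, levels = c("rest", "intention"))
  svm_fit <- e1071::svm(x, yf, kernel = "radial", gamma = gamma, cost = cost,
                        scale = apply(x, 2, sd) > 0)
  flip <- svm_flip(svm_fit, x)

  # Platt scaling on cross-validated decision values: in-sample margins of a
  # separating SVM would drive the sigmoid to saturation and make the
  # confidence stream uninformative on new data
  cvf <- stratified_folds(y, 3, seed)
  dv_cv <- numeric(length(y))
  for (f in 1:3) {
    tr <- cvf != f
    if (length(unique(y[tr])) < 2) next
    m <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                    gamma = gamma, cost = cost,
                    scale = apply(x[tr, , drop = FALSE], 2, sd) > 0)
    dv_cv[!tr] <- svm_flip(m, x[tr, , drop = FALSE][1:2, , drop = FALSE]) *
      as.numeric(attr(predict(m, x[!tr, , drop = FALSE],
                              decision.values = TRUE), "decision.values"))
  }
  dv <- dv_cv
  platt <- suppressWarnings(
    glm((yf == "intention") ~ dv, family = binomial())
  )
  target <- as.numeric(yf == "intention")
  if (is.null(gpr_sigma)) {
    idx <- seq_len(min(nrow(x), 200L))
    d2 <- as.numeric(stats::dist(x[idx, , drop = FALSE]))^2
    gpr_sigma <- 1 / (2 * stats::median(d2[d2 > 0]))
  }
  gpr <- kernlab::gausspr(x, target, type = "regression",
                          kernel = "rbfdot", kpar = list(sigma = gpr_sigma),
                          var = gpr_noise, scaled = FALSE)
  structure(
    list(svm = svm_fit, platt_coef = coef(platt), flip = flip, gpr = gpr,
         gpr_sigma = gpr_sigma),
    class = "confidence_models"
  )
}

#' Confidence streams from trained models
#'
#' @param models A [train_confidence_models()] result.
#' @param x SMF matrix (windows x 84).
#' @param time_ms Optional time stamps (ms) for the rows.
#' @return Data frame of class `confidence_stream` with `time_ms`, `c_svm`
#'   (in `[0, 1]`) and `c_gpr`.
#' @export
predict_confidences <- function(models, x, time_ms = NULL) {
  dv <- models$flip * as.numeric(attr(
    predict(models$svm, x, decision.values = TRUE), "decision.values"))
  c_svm <- plogis(models$platt_coef[1] + models$platt_coef[2] * dv)
  c_gpr <- as.numeric(kernlab::predict(models$gpr, x))
  out <- data.frame(
    time_ms = time_ms %||% seq_len(nrow(x)),
    c_svm = unname(c_svm), c_gpr = c_gpr
  )
  class(out) <- c("confidence_stream", "data.frame")
  out
}

#' Onset detector definition
#'
#' @param threshold_svm,threshold_gpr Detection thresholds on the two
#'   confidence streams; both must be strictly exceeded.
#' @param refractory_ms Lock-out after a detection (fixed default 1500 ms:
#'   onsets within 1.5 s of a detection are ignored).
#' @return List of class `onset_detector`.
#' @export
onset_detector <- function(threshold_svm, threshold_gpr, refractory_ms = 1500) {
  structure(
    list(threshold_svm = threshold_svm, threshold_gpr = threshold_gpr,
         refractory_ms = refractory_ms),
    class = "onset_detector"
  )
}

#' Detect movement-intention onsets in a confidence stream
#'
#' Scans the stream in time order; a time `t` is an onset iff both
#' confidences strictly exceed their thresholds and no onset occurred in the
#' half-open interval `(t - refractory, t)` — an onset exactly one refractory
#' period after the previous one is allowed, and threshold ties do not
#' trigger.
#'
#' @param stream A `confidence_stream` (columns `time_ms`, `c_svm`, `c_gpr`).
#' @param det An [onset_detector()].
#' @return Numeric vector of onset times (ms); possibly empty.
#' @export
detect_onsets <- function(stream, det) {
  o <- order(stream$time_ms)
  t_ms <- stream$time_ms[o]
  hit <- stream$c_svm[o] > det$threshold_svm &
    stream$c_gpr[o] > det$threshold_gpr
  onsets <- numeric(0)
  last <- -Inf
  for (i in which(hit)) {
    if (t_ms[i] - last >= det$refractory_ms) {
      onsets <- c(onsets, t_ms[i])
      last <- t_ms[i]
    }
  }
  onsets
}

#' Calibrate detector thresholds to a rest false-detection target
#'
#' Joint quantile sweep: both thresholds are set to the same quantile level
#' of their respective rest-segment confidence distributions, and the
#' smallest level whose rest false-detection rate is at most
#' `target_fp_per_min` is chosen (deterministic). At level 1 the thresholds
#' are nudged just above the rest maxima so a noise-only stream yields no
#' detections.
#'
#' @param streams A `confidence_stream` or list of them, covering rest data
#'   only (or carrying a logical `rest` column marking rest samples).
#' @param target_fp_per_min Tolerated false detections per minute of rest.
#' @param levels Quantile grid searched (default `seq(0.5, 1, 0.005)`).
#' @param refractory_ms Passed to the detector.
#' @return An [onset_detector()]; errors with class `calibration_error` if
#'   even the top of the grid exceeds the target, reporting the best
#'   achievable rate.
#' @export
calibrate_thresholds <- function(streams, target_fp_per_min = 1,
                                 levels = seq(0.5, 1, by = 0.005),
                                 refractory_ms = 1500) {
  if (inherits(streams, "data.frame")) streams <- list(streams)
  streams <- lapply(streams, function(s) {
    if (!is.null(s$rest)) s[s$rest, , drop = FALSE] else s
  })
  all_svm <- unlist(lapply(streams, `[[`, "c_svm"))
  all_gpr <- unlist(lapply(streams, `[[`, "c_gpr"))
  total_min <- sum(vapply(streams, function(s) {
    diff(range(s$time_ms)) + stats::median(diff(sort(s$time_ms)))
  }, 0)) / 60000
  eps <- 1e-12
  # a zero target cannot be certified from observed rest data; only
  # thresholds strictly above the rest maxima guarantee it
  if (target_fp_per_min <= 0) levels <- 1
  best <- NULL
  for (lv in levels) {
    th_s <- quantile(all_svm, lv, names = FALSE)
    th_g <- quantile(all_gpr, lv, names = FALSE)
    if (lv >= 1) {
      th_s <- th_s + eps + abs(th_s) * eps
      th_g <- th_g + eps + abs(th_g) * eps
    }
    det <- onset_detector(th_s, th_g, refractory_ms)
    fp <- sum(vapply(streams, function(s) length(detect_onsets(s, det)), 0L))
    rate <- fp / total_min
    if (is.null(best) || rate < best$rate) best <- list(det = det, rate = rate)
    if (rate <= target_fp_per_min) {
      det$calibrated_fp_per_min <- rate
      det$level <- lv
      return(det)
    }
  }
  stop_smf("calibration_error",
           "target %.3g FP/min unattainable; best achievable %.3g FP/min",
           target_fp_per_min, best$rate)
}

first_onset_bins <- function(search_ms = c(-2000, 1000), step_ms = 200) {
  edges <- seq(search_ms[1], search_ms[2], by = step_ms)
  data.frame(bin_start_ms = edges[-length(edges)], bin_end_ms = edges[-1])
}

#' Offline first-onset timing evaluation
#'
#' Ten-fold cross-validated reconstruction of the onset-timing histogram.
#' Per fold: the dual confidence models are trained on SMF windows of the
#' training trials (rest epoch windows as class rest, intention epoch
#' windows as class intention); the reference time `t*` is the window at
#' which movement-type classification accuracy peaks within the training
#' trials; thresholds are calibrated on training rest streams. Each test
#' trial is then scanned from `t* - 2000` to `t* + 1000` ms in 200-ms steps
#' and the first detected onset (relative to `t*`) is histogrammed; trials
#' with no detection are counted as N.D.
#'
#' @param session An open-loop `meg_session`.
#' @param stats Its [compute_baseline_stats()] (band baselines not needed).
#' @param folds Number of CV folds (default 10).
#' @param target_fp_per_min Calibration target for the thresholds.
#' @param rest_ends,intent_ends Window ends (ms, cue-relative) defining the
#'   rest and intention training epochs.
#' @param type_windows Candidate window ends for the peak-accuracy reference
#'   time.
#' @param gamma,cost SVM hyperparameters for the confidence classifier and
#'   the peak-time scorer.
#' @param seed Fold-assignment seed.
#' @param shuffle_labels If `TRUE`, permute both the movement-type labels
#'   (reference-time search) and the rest/intention epoch labels
#'   (confidence-model training) — the negative control under which the
#'   histogram should be consistent with uniform placement.
#' @return Object of class `onset_timing_histogram`: `bins` (data frame with
#'   `bin_start_ms`, `bin_end_ms`, `rate_percent`), `nd_percent`,
#'   `first_onsets_ms` (per detected trial), `n_trials`, plus the per-fold
#'   reference times. Bin rates and N.D. sum to 100.
#' @export
evaluate_first_onset <- function(session, stats, folds = 10,
                                 target_fp_per_min = 1,
                                 rest_ends = seq(-2000, -1000, by = 200),
                                 intent_ends = seq(0, 1000, by = 200),
                                 type_windows = seq(0, 1000, by = 100),
                                 gamma = 0.01, cost = 1, seed = 1,
                                 shuffle_labels = FALSE) {
  cues <- cue_events(session)
  n_tr <- nrow(cues)
  fold <- stratified_folds(cues$label, folds, seed)
  check_stratification(cues$label, fold)

  # per-trial SMF windows for training epochs and the type-window candidates
  all_ends <- sort(unique(c(rest_ends, intent_ends, type_windows)))
  feats <- extract_features(session, stats, all_ends, kinds = "smf")
  X <- feats$features$smf
  ridx <- match(rest_ends, all_ends)
  iidx <- match(intent_ends, all_ends)
  tidx <- match(type_windows, all_ends)

  labels_for_training <- if (shuffle_labels) {
    with_seed(seed + 77L, sample(cues$label))
  } else cues$label

  bins <- first_onset_bins()
  first_onsets <- rep(NA_real_, n_tr)
  ref_times <- numeric(folds)

  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)

    # training examples: one row per (trial, window)
    xr <- do.call(rbind, lapply(ridx, function(j) X[tr, j, , drop = TRUE]))
    xi <- do.call(rbind, lapply(iidx, function(j) X[tr, j, , drop = TRUE]))
    epoch_labels <- rep(c("rest", "intention"), c(nrow(xr), nrow(xi)))
    if (shuffle_labels) {
      epoch_labels <- with_seed(seed + 88L + f, sample(epoch_labels))
    }
    models <- train_confidence_models(
      rbind(xr, xi), epoch_labels,
      gamma = gamma, cost = cost
    )

    # reference time: peak type-classification accuracy within training
    # trials (small internal CV at fixed hyperparameters)
    t_star <- peak_type_window(X[tr, tidx, , drop = FALSE],
                               labels_for_training[tr], type_windows,
                               gamma, cost, seed + 10L * f)
    ref_times[f] <- t_star

    # thresholds from cross-validated training rest streams
    rest_stream <- cv_rest_confidences(X[tr, , , drop = FALSE], ridx, iidx,
                                       labels_for_training[tr],
                                       gamma, cost, seed + 300L + f)
    det <- tryCatch(
      calibrate_thresholds(rest_stream, target_fp_per_min),
      smfdecode_error = function(e) onset_detector(
        max(rest_stream$c_svm), max(rest_stream$c_gpr))
    )

    scan <- seq(t_star - 2000, t_star + 1000, by = 200)
    for (i in te) {
      cue_ms <- cues$time_s[i] * 1000
      xs <- t(vapply(scan, function(w)
        compute_smf(session, stats, cue_ms + w)$values,
        numeric(length(stats$parietal))))
      stream <- predict_confidences(models, xs, time_ms = scan)
      on <- detect_onsets(stream, det)
      if (length(on)) first_onsets[i] <- on[1] - t_star
    }
  }

  detected <- !is.na(first_onsets)
  counts <- vapply(seq_len(nrow(bins)), function(b) {
    hi_ok <- if (b == nrow(bins)) first_onsets <= bins$bin_end_ms[b] else
      first_onsets < bins$bin_end_ms[b]
    sum(detected & first_onsets >= bins$bin_start_ms[b] & hi_ok)
  }, 0L)
  # half-open bins; the final scanned point (+1000 ms) closes the last bin
  bins$rate_percent <- 100 * counts / n_tr
  structure(
    list(bins = bins, nd_percent = 100 * sum(!detected) / n_tr,
         first_onsets_ms = first_onsets, n_trials = n_tr,
         ref_times_ms = ref_times),
    class = "onset_timing_histogram"
  )
}

# Out-of-sample rest confidence stream for threshold calibration: k-fold CV
# over training trials; each fold's rest windows are scored by confidence
# models trained on the remaining trials. In-sample rest confidences are
# overfit low and would yield thresholds that fire constantly on held-out
# data.
cv_rest_confidences <- function(X, ridx, iidx, labels, gamma, cost,
                                seed, k = 3) {
  fold <- stratified_folds(labels, k, seed)
  out <- NULL
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    ho <- which(fold == f)
    xr <- do.call(rbind, lapply(ridx, function(j) X[tr, j, , drop = TRUE]))
    xi <- do.call(rbind, lapply(iidx, function(j) X[tr, j, , drop = TRUE]))
    m <- train_confidence_models(
      rbind(xr, xi), rep(c("rest", "intention"), c(nrow(xr), nrow(xi))),
      gamma = gamma, cost = cost
    )
    xho <- do.call(rbind, lapply(ridx, function(j) X[ho, j, , drop = TRUE]))
    out <- rbind(out, predict_confidences(m, xho))
  }
  out$time_ms <- 200 * seq_len(nrow(out))
  out
}

# Peak-accuracy window within a training set: k-fold CV accuracy per window
# at fixed hyperparameters; earliest window wins ties.
peak_type_window <- function(X, labels, windows, gamma, cost, seed, k = 5) {
  fold <- stratified_folds(labels, k, seed)
  acc <- numeric(length(windows))
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (!any(te) || length(unique(labels[tr])) < 2) next
    for (w in seq_along(windows)) {
      x_te <- X[te, w, , drop = FALSE]
      dim(x_te) <- dim(x_te)[c(1, 3)]
      pred <- svm_fit_predict(X[tr, w, , drop = TRUE], labels[tr], x_te,
                              gamma, cost)
      acc[w] <- acc[w] + sum(pred == labels[te])
    }
  }
  windows[which.max(acc)]
}

#' @export
print.onset_timing_histogram <- function(x, ...) {
  md <- x$bins$bin_start_ms[which.max(x$bins$rate_percent)]
  cat(sprintf(
    "<onset_timing_histogram> %d trials, modal bin [%g, %g) ms, N.D. %.1f%%\n",
    x$n_trials, md, md + diff(x$bins$bin_start_ms[1:2]), x$nd_percent
  ))
  invisible(x)
}
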