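#' Inverse-solution configuration
#'
#' Settings of the regularized linear (Tikhonov minimum-norm) inverse used
#' for cortical current estimation. The hierarchical-Bayes hyperparameters
#' `m0` and `gamma0` of the full variational source-imaging method this
#' stage simplifies are carried for provenance only; the simplified filter
#' does not use them.
#'
#' @param lambda Regularization weight (>= 0). Scales the noise covariance
#'   in `W = L' (L L' + lambda * Cn)^{-1}`.
#' @param baseline_window_ms Cue-relative window for noise / baseline current
#'   statistics (default -1500..-500 ms).
#' @param escp_window_ms Cue-relative averaging window of the estimated slow
#'   cortical potential (fixed default 0..500 ms).
#' @param filter_window_ms Cue-relative window whose signals inform the
#'   filter estimate (default 0..1000 ms).
#' @param sensors `"all"` or `"parietal"`.
#' @param depth_weight Normalize lead-field columns before inversion
#'   (default `TRUE`). This is the usual depth weighting of distributed
#'   minimum-norm imaging: without it, superficial strong-column sources
#'   capture the estimate and deep dipoles mislocalize. Estimated currents
#'   are then in per-vertex arbitrary units, which is immaterial here
#'   because eSCPs are z-scored per vertex and F-maps are invariant to
#'   per-vertex scale.
#' @param m0,gamma0 Provenance fields (defaults 100 and 10), unused.
#' @return List of class `inverse_config`.
#' @export
inverse_config <- function(lambda = 0.01,
                           baseline_window_ms = c(-1500, -500),
                           escp_window_ms = c(0, 500),
                           filter_window_ms = c(0, 1000),
                           sensors = c("all", "parietal"),
                           depth_weight = TRUE,
                           m0 = 100, gamma0 = 10) {
  if (lambda < 0) stop_smf("invalid_config", "lambda must be >= 0")
  sensors <- match.arg(sensors)
  structure(as.list(environment()), class = "inverse_config")
}

#' Tikhonov minimum-norm inverse filter
#'
#' `W = L' (L L' + lambda * Cn)^{-1}` with `Cn` a sensor noise covariance
#' (identity scaled to the mean noise power if not supplied). With
#' `lambda = 0` an ill-conditioned gram matrix raises a conditioning error
#' advising `lambda > 0`.
#'
#' @param lf A [compute_lead_field()] result.
#' @param cfg An [inverse_config()].
#' @param noise_cov Optional sensor covariance matrix (defaults to identity).
#' @param sensor_idx Optional integer subset of sensors.
#' @return Matrix `W` (n_vertices x n_sensors_used) with attribute
#'   `sensor_idx`.
#' @export
compute_inverse_filter <- function(lf, cfg = inverse_config(),
                                   noise_cov = NULL, sensor_idx = NULL) {
  L <- lf$L
  if (is.null(sensor_idx)) {
    sensor_idx <- if (cfg$sensors == "parietal") {
      which(lf$array$parietal_mask)
    } else seq_len(nrow(L))
  }
  L <- L[sensor_idx, , drop = FALSE]
  if (isTRUE(cfg$depth_weight)) {
    cn <- sqrt(colSums(L^2))
    cn[cn < .Machine$double.eps] <- 1
    L <- sweep(L, 2, cn, "/")
  }
  G <- L %*% t(L)
  Cn <- noise_cov %||% (diag(nrow(G)) * mean(diag(G)) / nrow(G))
  A <- G + cfg$lambda * Cn
  if (cfg$lambda == 0 && rcond(A) < 1e-12) {
    stop_smf("conditioning_error",
             "gram matrix is ill-conditioned with lambda = 0; use lambda > 0")
  }
  W <- t(L) %*% solve(A)
  attr(W, "sensor_idx") <- sensor_idx
  W
}

#' Apply an inverse filter to sensor data
#'
#' @param W Filter from [compute_inverse_filter()].
#' @param data Sensor matrix (all sensors x samples); the filter's stored
#'   sensor subset is applied.
#' @return Vertex x samples current matrix.
#' @export
apply_inverse <- function(W, data) {
  idx <- attr(W, "sensor_idx")
  W %*% data[idx, , drop = FALSE]
}

#' Estimate cue-locked cortical currents and eSCPs
#'
#' Computes one inverse filter per session — Tikhonov minimum-norm with the
#' sensor noise covariance estimated from the cue-relative baseline window
#' (-1500..-500 ms) pooled over trials — and applies it to each trial. The
#' estimated slow cortical potential (eSCP) of a trial is the per-vertex
#' mean current over 0..500 ms after the cue; the normalized eSCP z-scores
#' each vertex against its own baseline-window current distribution.
#'
#' @param session A `meg_session` with cue events.
#' @param lf A [compute_lead_field()] matched to the session's array.
#' @param cfg An [inverse_config()].
#' @return Object of class `current_estimate`: `escp` (trials x vertices,
#'   raw), `escp_z` (normalized), `labels`, `W`, `cfg`.
#' @export
estimate_currents <- function(session, lf, cfg = inverse_config()) {
  stopifnot(inherits(session, "meg_session"))
  if (nrow(lf$L) != nrow(session$data)) {
    stop_smf("geometry_error", "lead field does not match the session's array")
  }
  cues <- cue_events(session)
  rate <- session$rate
  base_idx <- function(cue_ms) {
    (round((cue_ms + cfg$baseline_window_ms[1]) * rate / 1000) + 1L):
      round((cue_ms + cfg$baseline_window_ms[2]) * rate / 1000)
  }
  escp_idx <- function(cue_ms) {
    (round((cue_ms + cfg$escp_window_ms[1]) * rate / 1000) + 1L):
      round((cue_ms + cfg$escp_window_ms[2]) * rate / 1000)
  }

  sensor_idx <- if (cfg$sensors == "parietal") {
    which(session$array$parietal_mask)
  } else seq_len(nrow(session$data))

  # noise covariance from baseline windows, pooled over trials
  bs <- lapply(cues$time_s * 1000, function(cm) {
    idx <- base_idx(cm)
    idx <- idx[idx >= 1 & idx <= ncol(session$data)]
    session$data[sensor_idx, idx, drop = FALSE]
  })
  B <- do.call(cbind, bs)
  B <- B - rowMeans(B)
  Cn <- tcrossprod(B) / (ncol(B) - 1)

  W <- compute_inverse_filter(lf, cfg, noise_cov = Cn, sensor_idx = sensor_idx)

  n_tr <- nrow(cues)
  n_v <- ncol(lf$L)
  escp <- matrix(NA_real_, n_tr, n_v)
  bmean <- matrix(NA_real_, n_tr, n_v)
  bsq <- matrix(NA_real_, n_tr, n_v)
  n_bs <- 0L
  for (i in seq_len(n_tr)) {
    cm <- cues$time_s[i] * 1000
    J_escp <- apply_inverse(W, session$data[, escp_idx(cm), drop = FALSE])
    escp[i, ] <- rowMeans(J_escp)
    J_base <- apply_inverse(W, session$data[, base_idx(cm), drop = FALSE])
    bmean[i, ] <- rowMeans(J_base)
    bsq[i, ] <- rowMeans(J_base^2)
    n_bs <- ncol(J_base)
  }
  mu <- colMeans(bmean)
  sigma <- sqrt(pmax(colMeans(bsq) - mu^2, .Machine$double.eps))
  escp_z <- sweep(sweep(escp, 2, mu), 2, sigma, "/")

  structure(
    list(escp = escp, escp_z = escp_z, labels = cues$label,
         W = W, cfg = cfg, mesh = lf$mesh),
    class = "current_estimate"
  )
}

#' Per-vertex one-way ANOVA map of eSCPs
#'
#' Tests, vertex by vertex, whether the eSCP differs between movement-type
#' trial groups (classical one-way ANOVA, equal-variance F). The display
#' mask keeps vertices with `p < 0.05`, unadjusted by default as in
#' conventional F-maps; `fdr = TRUE` switches the mask to
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param est A `current_estimate`, or a trials x vertices matrix.
#' @param labels Trial group labels (taken from `est` if absent).
#' @param alpha Mask level (default 0.05).
#' @param fdr Mask on BH-adjusted p-values instead (default `FALSE`).
#' @param normalized Use the normalized eSCP (`TRUE`, default) or the raw
#'   one; the F-statistics are identical because the normalization is a
#'   per-vertex affine map applied to all trials.
#' @return Data frame: `vertex`, `F`, `p`, `masked`.
#' @export
escp_anova_map <- function(est, labels = NULL, alpha = 0.05, fdr = FALSE,
                           normalized = TRUE) {
  if (inherits(est, "current_estimate")) {
    labels <- labels %||% est$labels
    m <- if (normalized) est$escp_z else est$escp
  } else {
    m <- as.matrix(est)
  }
  if (is.null(labels)) stop_smf("invalid_config", "labels required")
  g <- factor(labels)
  if (any(table(g) < 2)) {
    stop_smf("dof_error", "every group needs >= 2 trials")
  }
  n_v <- ncol(m)
  Fv <- numeric(n_v)
  pv <- numeric(n_v)
  for (j in seq_len(n_v)) {
    if (var(m[, j]) < .Machine$double.eps) {
      Fv[j] <- 0
      pv[j] <- 1
    } else {
      ow <- oneway.test(m[, j] ~ g, var.equal = TRUE)
      Fv[j] <- unname(ow$statistic)
      pv[j] <- ow$p.value
      if (is.na(Fv[j])) { Fv[j] <- 0; pv[j] <- 1 }
    }
  }
  p_mask <- if (fdr) stats::p.adjust(pv, "BH") else pv
  data.frame(vertex = seq_len(n_v), F = Fv, p = pv, masked = p_mask < alpha)
}
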