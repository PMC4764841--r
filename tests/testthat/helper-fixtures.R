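# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_array <- function() {
  cached("tiny_array", function() make_sensor_array(84, seed = 7))
}

# A compact open-loop session at default SNR: 8 trials per type.
small_session <- function(seed = 3) {
  cached(paste0("session_", seed), function() {
    simulate_open_loop(sim_config(n_trials_per_type = 8, seed = seed),
                       tiny_array())
  })
}

small_stats <- function(seed = 3, bands = character(0)) {
  key <- paste0("stats_", seed, "_", paste(bands, collapse = "+"))
  cached(key, function() {
    compute_baseline_stats(small_session(seed), bands = bands)
  })
}

small_features <- function(seed = 3) {
  cached(paste0("features_", seed), function() {
    extract_features(small_session(seed), small_stats(seed),
                     window_grid(-2000, 1000, 100), kinds = "smf")
  })
}

# Reduced decoder spec for test-scale nested CV.
test_spec <- function(seed = 1) {
  decoder_spec(gamma = 2^c(-13, -9, -5), cost = 2^c(-1, 3, 7),
               outer_folds = 4, inner_folds = 3,
               windows = seq(0, 1000, by = 200), seed = seed)
}

# Hand-built session around a raw data matrix (for arithmetic oracles).
fake_session <- function(data, rate = 1000, schedule = NULL) {
  arr <- tiny_array()
  stopifnot(nrow(data) == arr$n_sensors)
  structure(
    list(data = data, rate = rate, lowpass = 200,
         schedule = schedule %||% data.frame(time_s = numeric(0),
                                             event = character(0),
                                             label = character(0)),
         array = arr, config = NULL, truth = NULL, kind = "synthetic",
         seed = NA),
    class = "meg_session"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Labelled feature set with controllable class separation, for decoder tests.
fake_feature_set <- function(n_per_class = 8, n_windows = 6, n_ch = 84,
                             sep = 0, seed = 1,
                             window_end_ms = seq(0, 1000, by = 200)) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- array(rnorm(n * n_windows * n_ch), c(n, n_windows, n_ch))
  labels <- rep(c("grasp", "open"), each = n_per_class)
  X[labels == "grasp", , ] <- X[labels == "grasp", , ] + sep
  structure(
    list(features = list(smf = X), labels = labels,
         trial_id = seq_len(n), cue_time_s = seq_len(n),
         window_end_ms = window_end_ms, kinds = "smf"),
    class = "labeled_feature_set"
  )
}
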