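test_that("baseline statistics cover exactly the first 50 s", {
  set.seed(1)
  n <- 52000
  data <- matrix(rnorm(84 * n), 84)
  ses <- fake_session(data)
  st <- compute_baseline_stats(ses, bands = character(0))
  # standard-normal channels: mean near 0, SD near 1 at 50,000 samples
  expect_true(all(abs(st$mean) < 0.02))
  expect_true(all(abs(st$sd - 1) < 0.02))
  expect_equal(st$mean[5], mean(data[5, 1:50000]))
  expect_equal(st$sd[5], sd(data[5, 1:50000]))

  # a constant parietal channel is degenerate, not silently infinite
  data2 <- data
  data2[which(ses$array$parietal_mask)[1], ] <- 3
  expect_error(compute_baseline_stats(fake_session(data2),
                                      bands = character(0)),
               class = "degenerate_channel")

  # 49-s session: not enough baseline
  expect_error(compute_baseline_stats(fake_session(data[, 1:49000]),
                                      bands = character(0)),
               class = "insufficient_baseline")
})

test_that("SMF is the baseline-z-scored 500-ms window mean", {
  set.seed(2)
  n <- 52000
  data <- matrix(rnorm(84 * n, mean = 100, sd = 50), 84)
  ses <- fake_session(data)
  st <- compute_baseline_stats(ses, bands = character(0))
  par <- st$parietal
  ch_row <- par[3]

  # ramp 0..499 against baseline mean 100, SD 50: (249.5 - 100)/50 = 2.99
  data[ch_row, 50501:51000] <- 0:499
  ses <- fake_session(data)
  expected <- (249.5 - st$mean[ch_row]) / st$sd[ch_row]
  fw <- compute_smf(ses, st, 51000)
  expect_equal(fw$values[3], expected, tolerance = 1e-12)
  expect_equal(fw$values[3], 2.99, tolerance = 0.05)

  # window equal to the baseline mean gives exactly zero
  data[ch_row, 50501:51000] <- st$mean[ch_row]
  expect_equal(compute_smf(fake_session(data), st, 51000)$values[3], 0)

  # out-of-range windows error
  expect_error(compute_smf(ses, st, 200), class = "window_bounds")
  expect_error(compute_smf(ses, st, n + 600), class = "window_bounds")
})

test_that("band powers have the right spectral support", {
  set.seed(3)
  n <- 52000
  data <- matrix(rnorm(84 * n, sd = 0.1), 84)
  t_s <- (0:(n - 1)) / 1000
  par1 <- 5 # parietal index into the 84-vector
  ses0 <- fake_session(data)
  st <- compute_baseline_stats(ses0, bands = c("alpha", "high_gamma"))
  ch_row <- st$parietal[par1]

  # pure 10 Hz in the analysis window
  d10 <- data
  d10[ch_row, 50501:51000] <- 5 * sin(2 * pi * 10 * t_s[50501:51000])
  a <- compute_band_power(fake_session(d10), st, 51000, "alpha", raw = TRUE)
  g <- compute_band_power(fake_session(d10), st, 51000, "high_gamma",
                          raw = TRUE)
  expect_gt(a$values[par1], 0)
  expect_lt(g$values[par1], 1e-10 * a$values[par1])

  # pure 100 Hz: the reverse
  d100 <- data
  d100[ch_row, 50501:51000] <- 5 * sin(2 * pi * 100 * t_s[50501:51000])
  a2 <- compute_band_power(fake_session(d100), st, 51000, "alpha", raw = TRUE)
  g2 <- compute_band_power(fake_session(d100), st, 51000, "high_gamma",
                           raw = TRUE)
  expect_gt(g2$values[par1], 0)
  expect_lt(a2$values[par1], 1e-6 * g2$values[par1])
})

test_that("window power agrees with a direct DFT oracle", {
  set.seed(4)
  data <- matrix(rnorm(84 * 52000), 84)
  ses <- fake_session(data)
  st <- compute_baseline_stats(ses, bands = "beta")
  par1 <- 7
  ch_row <- st$parietal[par1]
  x <- data[ch_row, 50501:51000] - st$mean[ch_row]
  nw <- length(x)
  freqs <- (0:(nw - 1)) * 1000 / nw
  bins <- which(freqs >= 13 & freqs < 30)
  # explicit trigonometric DFT, no fft()
  oracle <- sum(vapply(bins, function(k) {
    w <- 2 * pi * (k - 1) * (0:(nw - 1)) / nw
    sum(x * cos(w))^2 + sum(x * sin(w))^2
  }, 0))
  got <- compute_band_power(ses, st, 51000, "beta", raw = TRUE)$values[par1]
  expect_equal(got, oracle, tolerance = 1e-9)
  # Parseval: total power over all bins equals n * sum(x^2)
  expect_equal(sum(Mod(fft(x))^2), nw * sum(x^2), tolerance = 1e-9)
})

test_that("SMF is invariant to per-channel affine rescaling of raw data", {
  ses <- small_session()
  st <- small_stats()
  set.seed(5)
  gains <- runif(84, 0.5, 3)
  offsets <- rnorm(84, sd = 10)
  data2 <- ses$data * gains + offsets
  ses2 <- fake_session(data2, schedule = ses$schedule)
  st2 <- compute_baseline_stats(ses2, bands = character(0))
  for (w in c(55000, 60300, 81000)) {
    expect_equal(compute_smf(ses2, st2, w)$values,
                 compute_smf(ses, st, w)$values, tolerance = 1e-9)
  }
})

test_that("features are equivariant under time translation", {
  ses <- small_session()
  st <- small_stats()
  shift <- 700 # ms
  ses_sh <- fake_session(cbind(matrix(0, 84, shift),
                               ses$data[, 1:(ncol(ses$data) - shift)]),
                         schedule = ses$schedule)
  # same baseline stats supplied to both: shifting data and window together
  # must reproduce the identical feature
  for (w in c(56000, 60100)) {
    expect_identical(compute_smf(ses, st, w)$values,
                     compute_smf(ses_sh, st, w + shift)$values)
  }
})

test_that("window grids validate their parameters", {
  expect_error(window_grid(0, 1000, 0), class = "invalid_config")
  expect_error(window_grid(1000, 0, 100), class = "invalid_config")
  g <- window_grid(-2000, 1000, 100)
  expect_length(g, 31)
})
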