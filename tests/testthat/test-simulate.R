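test_that("power-law noise has the requested spectral exponent", {
  fs <- 200
  n <- 200 * fs   # 200 s realizations
  white <- gen_powerlaw_noise(n, fs, exponent = 0, seed = 1)
  expect_lt(abs(periodogram_slope(white, fs, 2, 40)), 0.1)
  pink2 <- gen_powerlaw_noise(n, fs, exponent = 2, seed = 2)
  expect_lt(abs(periodogram_slope(pink2, fs, 2, 40) - (-2)), 0.1)
})

test_that("power-law noise is normalized to unit sample variance", {
  for (chi in c(0, 1, 2.5)) {
    x <- gen_powerlaw_noise(500, 200, chi, seed = chi * 10 + 1)
    expect_equal(var(x), 1, tolerance = 1e-6)
  }
  expect_error(gen_powerlaw_noise(1, 200, 1), "n_samples")
  expect_error(gen_powerlaw_noise(100, -1, 1), "fs")
  expect_error(gen_powerlaw_noise(100, 200, -0.5), "exponent")
})

test_that("oscillations sit at their centre frequency and cancel across phases", {
  fs <- 200
  n <- 2 * fs
  expect_identical(gen_oscillation(10, 0, n, fs, seed = 1), rep(0, n))
  x <- gen_oscillation(10, 1, n, fs, seed = 2)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], 10, tolerance = 0.51)
  expect_error(gen_oscillation(120, 1, n, fs), "fs/2")
  # Monte-Carlo phase cancellation: the average of many random-phase
  # epochs is nearly flat
  set.seed(3)
  avg <- rowMeans(vapply(1:500, function(i) gen_oscillation(10, 1, n, fs),
                         numeric(n)))
  expect_lt(diff(range(avg)), 0.1 * diff(range(x)))
})

test_that("generated epoch sets have the contracted shape and are deterministic", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 8,
                    n_channels = 6, epoch_span = c(-1, 2), seed = 7)
  g1 <- gen_epoch_set(cfg)
  expect_identical(dim(g1$epochs$data), c(12L * 8L, 6L, 600L))
  expect_identical(nrow(g1$epochs$labels), 96L)
  expect_setequal(unique(g1$epochs$labels$task), c("WM", "SWIT", "MSIT"))
  g2 <- gen_epoch_set(cfg)
  expect_identical(g1$epochs$data, g2$epochs$data)
  expect_identical(g1$truth$exponents, g2$truth$exponents)
  # reduced designs shrink the cell count accordingly
  small <- gen_epoch_set(sim_config(n_trials_per_condition = 8,
                                    n_channels = 4, tasks = "WM",
                                    contents = "colour",
                                    epoch_span = c(0, 1), seed = 1))
  expect_identical(dim(small$epochs$data), c(16L, 4L, 200L))
})

test_that("a demand amplitude factor squares into hard/easy band power", {
  f <- 0.8
  cfg <- sim_config(
    n_subjects = 1, n_trials_per_condition = 60, n_channels = 4,
    channel_kinds = "eeg", epoch_span = c(0, 1.2),
    aperiodic_exponent = c(mean = 1.5, sd = 0),
    demand_effect = list(broadband_amplitude_factor = f, slope_delta = 0,
                         channel_map = c(1, 1, 0, 0)),
    content_effect = list(broadband_amplitude_factor = 1, slope_delta = 0,
                          channel_map = rep(0, 4)),
    oscillations = list(), evoked = NULL, noise_floor = 0,
    tasks = "WM", contents = "alphanumeric", seed = 21)
  g <- gen_epoch_set(cfg)
  lab <- g$epochs$labels
  ratio_for <- function(ch) {
    hard <- t(g$epochs$data[lab$demand == "hard", ch, ])
    easy <- t(g$epochs$data[lab$demand == "easy", ch, ])
    welch_band_power(hard, 200, 3, 30) / welch_band_power(easy, 200, 3, 30)
  }
  expect_equal(mean(c(ratio_for(1), ratio_for(2))), f^2, tolerance = 0.05)
  # ground truth records the exact multiplicative factors
  expect_equal(unname(g$truth$amp_factors["WM.alphanumeric.hard", ]),
               c(f, f, 1, 1))
  expect_equal(unname(g$truth$amp_factors["WM.alphanumeric.easy", ]),
               rep(1, 4))
  # unmapped channels show no systematic demand difference
  expect_equal(ratio_for(3), 1, tolerance = 0.1)
})

test_that("unmapped channels carry no condition effect across seeds", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(
      n_subjects = 1, n_trials_per_condition = 30, n_channels = 2,
      channel_kinds = "eeg", epoch_span = c(0, 1.2),
      aperiodic_exponent = c(mean = 1.5, sd = 0),
      demand_effect = list(broadband_amplitude_factor = 0.7, slope_delta = 0,
                           channel_map = c(1, 0)),
      content_effect = list(broadband_amplitude_factor = 1, slope_delta = 0,
                            channel_map = c(0, 0)),
      oscillations = list(), evoked = NULL, noise_floor = 0,
      tasks = "WM", contents = "alphanumeric", seed = 100 + s)
    g <- gen_epoch_set(cfg)
    lab <- g$epochs$labels
    pw <- apply(g$epochs$data[, 2, ], 1, function(v) {
      sp <- stats::spec.pgram(stats::ts(v, frequency = 200), taper = 0,
                              detrend = FALSE, plot = FALSE)
      mean(sp$spec[sp$freq >= 3 & sp$freq <= 30])
    })
    p <- t.test(pw[lab$demand == "hard"], pw[lab$demand == "easy"])$p.value
    if (p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("degenerate all-zero effect maps raise a warning", {
  cfg <- sim_config(n_trials_per_condition = 8, n_channels = 2,
                    demand_effect = list(broadband_amplitude_factor = 0.8,
                                         slope_delta = 0,
                                         channel_map = c(0, 0)),
                    tasks = "WM", contents = "alphanumeric",
                    epoch_span = c(0, 0.5), seed = 1)
  expect_warning(gen_epoch_set(cfg), "all zero")
})

test_that("epoch sets round-trip through the array + JSON container", {
  g <- gen_epoch_set(sim_config(n_trials_per_condition = 8, n_channels = 3,
                                tasks = "WM", contents = "alphanumeric",
                                epoch_span = c(0, 0.5), seed = 9))
  prefix <- file.path(tempdir(), "es_roundtrip")
  write_epoch_set(g$epochs, prefix)
  back <- read_epoch_set(prefix)
  expect_identical(back$data, g$epochs$data)
  expect_equal(back$fs, g$epochs$fs)
  expect_identical(back$labels$demand, g$epochs$labels$demand)
})
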