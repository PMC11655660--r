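# Independent straight-line IRASA oracle used for cross-checking: a
# per-series loop built on stats::spec.pgram periodograms and linear
# (approx) resampling — deliberately a different code path from the
# package's batched FFT implementation.
irasa_oracle <- function(x, fs, h_set, grid) {
  n <- length(x)
  per <- function(v) {
    m <- length(v)
    w <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))
    X <- stats::fft(v * w)
    K <- floor(m / 2)
    list(f = (1:K) * fs / m,
         p = (Mod(X[2:(K + 1)])^2) * 2 / (fs * sum(w^2)))
  }
  geo <- sapply(h_set, function(h) {
    up <- stats::approx(seq_len(n), x,
                        xout = seq(1, n, length.out = round(n * h)))$y
    dn <- stats::approx(seq_len(n), x,
                        xout = seq(1, n, length.out = round(n / h)))$y
    pu <- per(up)
    pd <- per(dn)
    sqrt(stats::approx(pu$f, pu$p, xout = grid)$y *
         stats::approx(pd$f, pd$p, xout = grid, rule = 2)$y)
  })
  apply(geo, 1, stats::median)
}

test_that("the resampling-adjusted Nyquist bound is fs/(2*h_max)", {
  expect_equal(frequency_bound(200, 1.9), 200 / 3.8)  # 52.63 Hz
  expect_equal(frequency_bound(1000, 1), 500)
  expect_equal(frequency_bound(200, 2), 50)
  expect_error(frequency_bound(200, 0.9), "h_max")
  # grids above the bound are rejected at validation
  cfg_bad <- irasa_config(freq_grid = 1:60)
  expect_error(irasadecode:::validate_irasa_config(cfg_bad, fs = 200),
               "estimable")
  expect_true(irasadecode:::validate_irasa_config(irasa_config(), fs = 200))
})

test_that("PSD estimation is calibrated and localizes sinusoids", {
  fs <- 200
  expect_identical(compute_psd(rep(0, 400), fs, 1:30), rep(0, 30))
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  p <- compute_psd(sin(2 * pi * 10 * t), fs, 1:30)
  expect_identical(which.max(p), 10L)
  # Parseval: integrated density over a bin-aligned grid matches the
  # series variance
  x <- gen_powerlaw_noise(20 * fs, fs, 0, seed = 6)
  grid <- seq(0.05, 99.95, by = 0.05)
  expect_equal(sum(compute_psd(x, fs, grid)) * 0.05, var(x),
               tolerance = 0.05)
})

test_that("spectral separation obeys its algebraic contracts", {
  cfg <- irasa_config()
  x <- gen_powerlaw_noise(240, 200, 1.2, seed = 3)
  fr <- separate(x, 200, cfg)
  expect_true(all(fr$aperiodic >= 0))
  expect_true(all(fr$mixed >= 0))
  expect_lt(max(abs(fr$oscillatory - (fr$mixed - fr$aperiodic))), 1e-10)
  # scale equivariance: input * k -> spectra * k^2, slope unchanged,
  # intercept shifted by 2*log10(k)
  k <- 3
  fr2 <- separate(k * x, 200, cfg)
  expect_equal(fr2$mixed, k^2 * fr$mixed, tolerance = 1e-8)
  expect_equal(fr2$aperiodic, k^2 * fr$aperiodic, tolerance = 1e-8)
  f1 <- fit_aperiodic(drop(fr$aperiodic), fr$freq)
  f2 <- fit_aperiodic(drop(fr2$aperiodic), fr$freq)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-8)
  expect_equal(f2$intercept, f1$intercept + 2 * log10(k), tolerance = 1e-8)
})

test_that("aperiodic slopes are recovered across the exponent range", {
  cfg <- irasa_config()
  for (chi in c(0.5, 1, 1.5, 2)) {
    set.seed(round(10 * chi))
    m <- vapply(1:200, function(i) gen_powerlaw_noise(240, 200, chi),
                numeric(240))
    r <- irasadecode:::irasa_batch(m, 200, cfg)
    slopes <- irasadecode:::fit_aperiodic_mat(r$aperiodic, r$freq,
                                              cfg$fit_range)$slope
    expect_lt(abs(mean(slopes) - (-chi)), 0.2)
  }
})

test_that("white noise yields a near-zero oscillatory component", {
  # the signed median over epochs estimates the separator's systematic
  # offset; 2000 epochs suppress the median's own sampling noise
  cfg <- irasa_config()
  set.seed(4)
  m <- irasadecode:::powerlaw_noise_mat(240, 200, 0, 2000)
  r <- irasadecode:::irasa_batch(m, 200, cfg)
  ratio <- abs(apply(r$oscillatory, 1, median)) /
    apply(r$aperiodic, 1, median)
  expect_lt(max(ratio), 0.15)
  # and the fitted aperiodic slope is flat
  slopes <- irasadecode:::fit_aperiodic_mat(r$aperiodic, r$freq,
                                            cfg$fit_range)$slope
  expect_lt(abs(mean(slopes)), 0.1)
})

test_that("an added oscillation appears in the oscillatory component", {
  cfg <- irasa_config()
  set.seed(7)
  base <- irasadecode:::powerlaw_noise_mat(240, 200, 2, 100)
  t <- seq(0, 239) / 200
  osc <- vapply(1:100,
                function(i) sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)),
                numeric(240))
  r <- irasadecode:::irasa_batch(base + osc, 200, cfg)
  expect_identical(which.max(rowMeans(r$oscillatory)), 10L)
  # matched control: mean aperiodic strictly decreasing over 3-30 Hz
  r0 <- irasadecode:::irasa_batch(base, 200, cfg)
  ap0 <- rowMeans(r0$aperiodic)[cfg$freq_grid >= 3]
  expect_true(all(diff(ap0) < 0))
  # with the oscillation the aperiodic spectrum still falls coarsely
  # (residual peak leakage can produce small local bumps)
  ap <- rowMeans(r$aperiodic)
  expect_gt(ap[3], ap[10])
  expect_gt(ap[10], ap[30])
  expect_lt(fit_aperiodic(ap, r$freq)$slope, -1)
})

test_that("separation agrees with an independently coded IRASA oracle", {
  cfg <- irasa_config()
  for (s in 1:10) {
    x <- gen_powerlaw_noise(240, 200, 1.5, seed = s)
    a_pkg <- drop(separate(x, 200, cfg)$aperiodic)
    a_or <- irasa_oracle(x, 200, cfg$h_set, cfg$freq_grid)
    expect_gt(cor(log10(a_pkg), log10(a_or)), 0.99)
  }
})

test_that("log-log aperiodic fits are exact on analytic spectra", {
  f <- 1:30
  fit <- fit_aperiodic(1000 * f^-2, f, fit_range = c(3, 30))
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-10)
  fitc <- fit_aperiodic(rep(7, 30), f, fit_range = c(3, 30))
  expect_equal(fitc$slope, 0, tolerance = 1e-10)
  expect_equal(fitc$intercept, log10(7), tolerance = 1e-10)
  bad <- 1000 * f^-2
  bad[10] <- 0
  expect_error(fit_aperiodic(bad, f, fit_range = c(3, 30)), "10")
  expect_error(fit_aperiodic(bad, f, fit_range = c(29, 30)), ">= 3")
})

test_that("band features average the configured ranges", {
  cfg <- irasa_config()
  f <- 1:30
  # oscillatory all zero -> all band powers zero; constant aperiodic ->
  # broadband power equals the constant
  frame <- spectral_frame(f, matrix(5, 1, 30), matrix(5, 1, 30))
  fit <- fit_aperiodic(rep(5, 30), f)
  bf <- band_features(frame, fit, cfg)
  expect_equal(bf$theta, 0)
  expect_equal(bf$alpha, 0)
  expect_equal(bf$beta, 0)
  expect_equal(bf$bb_power, 5)
  expect_equal(bf$slope, 0, tolerance = 1e-10)
  # a single oscillatory bin at 10 Hz spreads over the 5-point alpha band
  A <- 2.5
  mixed <- rep(1, 30)
  mixed[10] <- mixed[10] + A
  frame2 <- spectral_frame(f, matrix(mixed, 1), matrix(1, 1, 30))
  bf2 <- band_features(frame2, fit_aperiodic(rep(1, 30), f), cfg)
  expect_equal(bf2$alpha, A / 5)
  expect_equal(bf2$theta, 0)
})

test_that("negative oscillatory values are retained in band means", {
  cfg <- irasa_config()
  f <- 1:30
  mixed <- rep(1, 30)
  ap <- rep(1.5, 30)   # aperiodic above mixed -> negative oscillatory
  frame <- spectral_frame(f, matrix(mixed, 1), matrix(ap, 1))
  bf <- band_features(frame, fit_aperiodic(ap, f), cfg)
  expect_equal(bf$alpha, -0.5)
})

test_that("spectral_features yields six labelled channel-feature matrices", {
  g <- gen_epoch_set(sim_config(n_trials_per_condition = 10, n_channels = 3,
                                tasks = "WM", contents = "alphanumeric",
                                epoch_span = c(0.3, 1.5), seed = 13))
  feats <- spectral_features(g$epochs)
  expect_identical(names(feats), signal_names())
  for (sf in feats) {
    expect_identical(dim(sf$x), c(20L, 3L))
    expect_identical(sf$feature_ids, g$epochs$channels$name)
    expect_identical(sf$labels$demand, g$epochs$labels$demand)
  }
  # slope features should track the subject exponent
  expect_lt(abs(mean(feats$slope$x) + unname(g$truth$exponents[1])), 0.3)
})
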