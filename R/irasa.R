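#' IRASA configuration
#'
#' Settings for irregular-resampling auto-spectral analysis: the
#' resampling-factor set, the output frequency grid, the log-log fit
#' range for the aperiodic line, and the band definitions used for the
#' six per-trial signal features.
#'
#' Defaults follow common practice for cognitive M/EEG: resampling
#' factors h from 1.10 to 1.90 in steps of 0.05, a 1-30 Hz grid in 1 Hz
#' steps, band ranges theta 3-7 Hz, alpha 8-12 Hz, beta 15-30 Hz (the
#' 13-14 Hz gap between alpha and beta is intentional and preserved),
#' and aperiodic broadband power averaged over 3-30 Hz. The slope and
#' intercept are fitted over `fit_range` (default 3-30 Hz, matching the
#' broadband definition) with the intercept defined as the fitted line's
#' value at 1 Hz (log-frequency zero), in `log_base` units.
#'
#' @param h_set resampling factors, all > 1.
#' @param freq_grid strictly increasing output frequencies in Hz. Must
#'   stay below [frequency_bound()] for the sampling rate in use.
#' @param fit_range `c(lo, hi)` Hz interval for the aperiodic line fit.
#' @param bands named list of `c(lo, hi)` Hz intervals.
#' @param broadband_range `c(lo, hi)` Hz interval for aperiodic
#'   broadband power.
#' @param h_agg how branch spectra are combined across resampling
#'   factors: `"median"` (default, robust to residual oscillatory peaks)
#'   or `"mean"`.
#' @param log_base base of the log-log fit (default 10).
#' @return an object of class `irasa_config`.
#' @export
irasa_config <- function(h_set = seq(1.1, 1.9, by = 0.05),
                         freq_grid = 1:30,
                         fit_range = c(3, 30),
                         bands = list(theta = c(3, 7),
                                      alpha = c(8, 12),
                                      beta = c(15, 30)),
                         broadband_range = c(3, 30),
                         h_agg = c("median", "mean"),
                         log_base = 10) {
  h_agg <- match.arg(h_agg)
  if (is.null(h_set) || length(h_set) < 1) stop_invalid("h_set is required")
  if (any(h_set <= 1)) stop_invalid("all resampling factors h must be > 1")
  if (any(diff(freq_grid) <= 0)) {
    stop_invalid("freq_grid must be strictly increasing")
  }
  if (min(freq_grid) <= 0) stop_invalid("freq_grid must be positive")
  span <- range(freq_grid)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (b[1] < span[1] || b[2] > span[2]) {
      stop_invalid("band '%s' (%g-%g Hz) lies outside the frequency grid",
                   nm, b[1], b[2])
    }
  }
  if (broadband_range[1] < span[1] || broadband_range[2] > span[2]) {
    stop_invalid("broadband_range lies outside the frequency grid")
  }
  structure(list(h_set = sort(h_set), freq_grid = as.numeric(freq_grid),
                 fit_range = fit_range, bands = bands,
                 broadband_range = broadband_range, h_agg = h_agg,
                 log_base = log_base),
            class = "irasa_config")
}

#' Highest estimable frequency under resampling
#'
#' The downsampled branch of IRASA (factor `1/h`) has an effective
#' Nyquist frequency of `fs / (2 h)`; for the largest resampling factor
#' this bounds the frequencies at which the aperiodic spectrum remains
#' estimable. Configuration validation rejects frequency grids above it.
#'
#' @param fs sampling rate, Hz.
#' @param h_max largest resampling factor (>= 1).
#' @return the bound `fs / (2 * h_max)` in Hz.
#' @export
frequency_bound <- function(fs, h_max) {
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  if (!is.numeric(h_max) || h_max < 1) stop_invalid("h_max must be >= 1")
  fs / (2 * h_max)
}

validate_irasa_config <- function(config, fs, n_samples = NULL) {
  if (!inherits(config, "irasa_config")) {
    stop_invalid("config must be an irasa_config")
  }
  bound <- frequency_bound(fs, max(config$h_set))
  if (max(config$freq_grid) > bound) {
    stop_invalid(paste0(
      "freq_grid extends to %g Hz but only frequencies up to %.4g Hz are ",
      "estimable at fs = %g Hz with h_max = %g"),
      max(config$freq_grid), bound, fs, max(config$h_set))
  }
  if (!is.null(n_samples)) {
    # need at least one native spectral bin at or below the lowest grid
    # frequency for interpolation
    if (fs / n_samples > min(config$freq_grid)) {
      stop_invalid(paste0(
        "segment of %d samples at %g Hz has spectral resolution %.3g Hz, ",
        "coarser than the lowest grid frequency %g Hz"),
        n_samples, fs, fs / n_samples, min(config$freq_grid))
    }
  }
  invisible(TRUE)
}

# Fourier-method resampling of the columns of `x` to length `m`
# (amplitude-preserving; equivalent to ideal band-limited interpolation
# of the periodic extension). Used for the h and 1/h branches.
resample_fourier <- function(x, m) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- as.integer(m)
  if (m == n) return(x)
  X <- stats::mvfft(x)
  hm <- m %/% 2L
  K <- min(n %/% 2L, hm)
  H <- matrix(0 + 0i, hm + 1L, ncol(x))
  H[1L, ] <- X[1L, ]
  if (K >= 1L) H[1L + seq_len(K), ] <- X[1L + seq_len(K), , drop = FALSE]
  # shared Nyquist bin is split when upsampling from an even length
  if (m > n && n %% 2L == 0L) H[1L + K, ] <- H[1L + K, ] * 0.5
  if (m %% 2L == 0L) H[hm + 1L, ] <- Re(H[hm + 1L, ])
  Y <- matrix(0 + 0i, m, ncol(x))
  Y[seq_len(hm + 1L), ] <- H
  if (hm >= 1L) {
    kk <- seq_len(m - hm - 1L)
    Y[m + 1L - kk, ] <- Conj(H[1L + kk, , drop = FALSE])
  }
  Re(stats::mvfft(Y, inverse = TRUE)) / n
}

# One-sided Hann-tapered periodogram density of each column.
# Returns a matrix with rows at frequencies (1:K) * fs / n, K = floor(n/2).
psd_hann <- function(x, fs) {
  x <- as.matrix(x)
  n <- nrow(x)
  w <- hann_window(n)
  U <- sum(w^2)
  X <- stats::mvfft(x * w)
  K <- n %/% 2L
  (Mod(X[1L + seq_len(K), , drop = FALSE])^2) * (2 / (fs * U))
}

# Linear-interpolation design from a native frequency axis onto a target
# grid; errors if the target leaves the native range. With
# `left_clamp = TRUE`, targets below the first native bin take that
# bin's value (used only for coarse down-branch spectra whose first bin
# can sit above the lowest grid frequency).
interp_design <- function(f_native, f_target, left_clamp = FALSE) {
  low_ok <- left_clamp || min(f_target) >= f_native[1]
  if (!low_ok || max(f_target) > f_native[length(f_native)]) {
    stop_invalid(paste0(
      "target frequencies %.4g-%.4g Hz exceed the resolvable native range ",
      "%.4g-%.4g Hz"),
      min(f_target), max(f_target), f_native[1], f_native[length(f_native)])
  }
  i1 <- findInterval(f_target, f_native, all.inside = TRUE)
  w2 <- (f_target - f_native[i1]) / (f_native[i1 + 1L] - f_native[i1])
  w2 <- pmin(pmax(w2, 0), 1)
  list(i1 = i1, i2 = i1 + 1L, w2 = w2)
}

apply_interp <- function(P, d) {
  P[d$i1, , drop = FALSE] * (1 - d$w2) + P[d$i2, , drop = FALSE] * d$w2
}

#' Power spectral density on a fixed frequency grid
#'
#' Single Hann-tapered modified periodogram, linearly interpolated onto
#' the requested grid from the native `fs / n` resolution.
#'
#' @param x numeric time series.
#' @param fs sampling rate, Hz.
#' @param freq_grid output frequencies, Hz.
#' @return nonnegative power density values, one per grid frequency.
#' @export
compute_psd <- function(x, fs, freq_grid) {
  if (length(x) < 2) stop_invalid("time series must have >= 2 samples")
  if (fs <= 0) stop_invalid("fs must be positive")
  P <- psd_hann(matrix(x, ncol = 1), fs)
  f_native <- seq_len(nrow(P)) * fs / length(x)
  drop(apply_interp(P, interp_design(f_native, freq_grid)))
}

# Row-wise median/mean of a matrix, vectorized (no per-row R calls).
row_agg <- function(M, how) {
  if (how == "mean") return(rowMeans(M))
  nc <- ncol(M)
  Ms <- matrix(M[order(row(M), M)], nrow(M), nc, byrow = TRUE)
  if (nc %% 2L == 1L) Ms[, (nc + 1L) %/% 2L]
  else (Ms[, nc %/% 2L] + Ms[, nc %/% 2L + 1L]) / 2
}

# Batched IRASA over the columns of `mat` (samples x series). This is
# the computational core: for each resampling factor h the series are
# Fourier-resampled by h and 1/h but their spectra are computed at the
# *nominal* (unchanged) sampling rate, so resampling acts as a time
# stretch/compression. A narrow-band oscillation at f0 then appears at
# f0/h in the stretched branch and f0*h in the compressed branch, while
# the self-similar 1/f^chi component keeps its shape (the branch scale
# factors h^(1-chi) and h^(chi-1) cancel in the geometric mean). Each
# branch spectrum is interpolated onto the native axis k/T, the two
# branches are combined by geometric mean, and the aperiodic spectrum
# is the median (or mean) across the h set. The oscillatory spectrum is
# the mixed spectrum minus the aperiodic one.
irasa_batch <- function(mat, fs, config) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  validate_irasa_config(config, fs, n_samples = n)
  grid <- config$freq_grid
  T_dur <- n / fs
  K <- ceiling(max(grid) * T_dur) + 1L
  f_native <- seq_len(K) / T_dur
  d <- interp_design(f_native, grid)

  mixed_native <- psd_hann(mat, fs)[seq_len(K), , drop = FALSE]
  H <- length(config$h_set)
  S <- ncol(mat)
  branches <- array(0, dim = c(K, S, H))
  for (i in seq_len(H)) {
    h <- config$h_set[i]
    m_up <- round(n * h)
    m_dn <- round(n / h)
    p_up <- psd_hann(resample_fourier(mat, m_up), fs)
    p_dn <- psd_hann(resample_fourier(mat, m_dn), fs)
    f_up <- seq_len(nrow(p_up)) * fs / m_up
    f_dn <- seq_len(nrow(p_dn)) * fs / m_dn
    p_up_i <- apply_interp(p_up, interp_design(f_up, f_native))
    p_dn_i <- apply_interp(p_dn, interp_design(f_dn, f_native,
                                               left_clamp = TRUE))
    branches[, , i] <- sqrt(p_up_i * p_dn_i)
  }
  ap_native <- matrix(row_agg(matrix(branches, K * S, H), config$h_agg), K, S)
  mixed <- apply_interp(mixed_native, d)
  aperiodic <- apply_interp(ap_native, d)
  list(freq = grid, mixed = mixed, aperiodic = aperiodic,
       oscillatory = mixed - aperiodic)
}

#' Separate a time series into aperiodic and oscillatory spectra
#'
#' Runs IRASA on one epoch-channel series: the mixed Hann-periodogram
#' spectrum is decomposed into an aperiodic component (geometric mean of
#' the h- and 1/h-resampled branch spectra, aggregated across the h set)
#' and an oscillatory residual (`mixed - aperiodic`, signed), all
#' evaluated on the configured frequency grid.
#'
#' @param x numeric time series (one epoch, one channel).
#' @param fs sampling rate, Hz.
#' @param config an [irasa_config].
#' @return a `spectral_frame` with one row: list with `freq`, and
#'   1 x length(freq) matrices `mixed`, `aperiodic`, `oscillatory`.
#' @export
separate <- function(x, fs, config) {
  if (length(x) < 2) stop_invalid("time series must have >= 2 samples")
  r <- irasa_batch(matrix(as.numeric(x), ncol = 1), fs, config)
  spectral_frame(r$freq, t(r$mixed), t(r$aperiodic))
}

#' Spectral frame container
#'
#' Holds mixed, aperiodic and oscillatory power spectra on a shared
#' frequency grid for a batch of epoch-channel series (one row each).
#' The oscillatory component is defined as `mixed - aperiodic`
#' elementwise and may be negative.
#'
#' @param freq frequency grid, Hz.
#' @param mixed,aperiodic rows x frequencies matrices of nonnegative
#'   power density.
#' @param index optional data frame (epoch, channel) identifying rows.
#' @return an object of class `spectral_frame`.
#' @export
spectral_frame <- function(freq, mixed, aperiodic, index = NULL) {
  mixed <- as.matrix(mixed)
  aperiodic <- as.matrix(aperiodic)
  stopifnot(ncol(mixed) == length(freq), ncol(aperiodic) == length(freq),
            nrow(mixed) == nrow(aperiodic))
  if (any(mixed < 0) || any(aperiodic < 0)) {
    stop_invalid("mixed and aperiodic spectra must be nonnegative")
  }
  structure(list(freq = as.numeric(freq), mixed = mixed,
                 aperiodic = aperiodic, oscillatory = mixed - aperiodic,
                 index = index),
            class = "spectral_frame")
}

#' Fit the aperiodic line in log-log coordinates
#'
#' Ordinary least squares of log(power) on log(frequency) over
#' `fit_range`, the standard parameterization of 1/f-like activity. The
#' slope is the (negated) spectral exponent; the intercept is the fitted
#' line's value at 1 Hz (log-frequency zero).
#'
#' @param aperiodic aperiodic power values on `freq`.
#' @param freq frequency grid, Hz.
#' @param fit_range `c(lo, hi)` Hz.
#' @param log_base logarithm base (default 10).
#' @return an `aperiodic_fit` list with `slope`, `intercept` and `rss`.
#' @export
fit_aperiodic <- function(aperiodic, freq, fit_range = c(3, 30),
                          log_base = 10) {
  sel <- freq >= fit_range[1] & freq <= fit_range[2]
  if (sum(sel) < 3) stop_invalid("need >= 3 grid points inside fit_range")
  p <- aperiodic[sel]
  if (any(p <= 0)) {
    stop_invalid("non-positive aperiodic power at %s Hz; cannot take logs",
                 paste(freq[sel][p <= 0], collapse = ", "))
  }
  lf <- log(freq[sel], base = log_base)
  lp <- log(p, base = log_base)
  fit <- stats::lm.fit(cbind(1, lf), lp)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 rss = sum(fit$residuals^2)),
            class = "aperiodic_fit")
}

# Batched log-log fit: P is frequencies x series.
fit_aperiodic_mat <- function(P, freq, fit_range, log_base = 10) {
  sel <- freq >= fit_range[1] & freq <= fit_range[2]
  if (sum(sel) < 3) stop_invalid("need >= 3 grid points inside fit_range")
  Ps <- P[sel, , drop = FALSE]
  if (any(Ps <= 0)) {
    bad <- unique(freq[sel][rowSums(Ps <= 0) > 0])
    stop_invalid("non-positive aperiodic power at %s Hz; cannot take logs",
                 paste(bad, collapse = ", "))
  }
  lf <- log(freq[sel], base = log_base)
  L <- log(Ps, base = log_base)
  X <- cbind(1, lf)
  coef <- solve(crossprod(X), crossprod(X, L))
  res <- L - X %*% coef
  data.frame(slope = coef[2, ], intercept = coef[1, ],
             rss = colSums(res^2))
}

band_mean <- function(P, freq, range) {
  sel <- freq >= range[1] & freq <= range[2]
  if (!any(sel)) stop_invalid("band %g-%g Hz contains no grid point",
                              range[1], range[2])
  colMeans(P[sel, , drop = FALSE])
}

#' Extract the six per-trial signal features from a spectral frame
#'
#' For each row of the frame: aperiodic broadband power (mean aperiodic
#' power over `broadband_range`), the log-log slope and intercept of the
#' supplied fit, and mean oscillatory power in the theta, alpha and beta
#' bands. Band means keep negative oscillatory values; truncating them
#' would bias downstream decoding.
#'
#' @param frame a [spectral_frame].
#' @param fit an `aperiodic_fit` (one row) or data frame of `slope` /
#'   `intercept` values aligned with the frame rows.
#' @param config an [irasa_config] supplying band definitions.
#' @return data frame with columns `bb_power`, `slope`, `intercept`,
#'   `theta`, `alpha`, `beta`, one row per frame row.
#' @export
band_features <- function(frame, fit, config) {
  stopifnot(inherits(frame, "spectral_frame"))
  freq <- frame$freq
  ap <- t(frame$aperiodic)   # frequencies x rows
  os <- t(frame$oscillatory)
  if (inherits(fit, "aperiodic_fit")) {
    fit <- data.frame(slope = fit$slope, intercept = fit$intercept)
  }
  out <- data.frame(
    bb_power = band_mean(ap, freq, config$broadband_range),
    slope = fit$slope,
    intercept = fit$intercept
  )
  for (nm in names(config$bands)) {
    out[[nm]] <- band_mean(os, freq, config$bands[[nm]])
  }
  out
}

#' Names of the six per-trial spectral signals
#'
#' Three aperiodic quantities (broadband power, slope, intercept) and
#' three oscillatory band powers (theta, alpha, beta).
#'
#' @return character vector of signal names.
#' @export
signal_names <- function() {
  c("bb_power", "slope", "intercept", "theta", "alpha", "beta")
}
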