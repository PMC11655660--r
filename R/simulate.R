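#' Simulation configuration
#'
#' Describes a synthetic M/EEG study: its factorial design (task x
#' content x demand), recording geometry, aperiodic (1/f-like) background
#' activity, non-phase-locked oscillations, an optional phase-locked
#' evoked transient, and the condition effects applied through
#' channel-space maps. The generator applies all effects multiplicatively
#' and records every applied factor in a ground-truth object, so each
#' downstream stage can be validated against known structure.
#'
#' Effect conventions: a `broadband_amplitude_factor` of `g` with channel
#' map weight `m` multiplies the aperiodic signal amplitude on that
#' channel by `g^m` in the hard (for `demand_effect`) or colour (for
#' `content_effect`) condition; power therefore scales by `g^(2m)`.
#' `slope_delta` is added to the aperiodic exponent, again weighted by the
#' map. The default demand effect is a broadband amplitude *decrease* in
#' the hard condition (factor 0.8, i.e. a 36% power reduction on fully
#' mapped channels), matching the expectation that rising cognitive
#' demand lowers aperiodic broadband power; the sign is configurable.
#'
#' @param n_subjects number of simulated participants.
#' @param n_trials_per_condition trials per condition cell (>= 8 so that
#'   pseudo-trials of 4 exist in every cross-validation fold).
#' @param n_channels number of channels. Defaults to 64 rather than a
#'   full 370-sensor array; decoding behaviour is dimension-generic and
#'   the count is configurable.
#' @param channel_kinds character vector recycled over channels; subset
#'   of `"eeg"`, `"magnetometer"`, `"gradiometer"`. Each kind gets a
#'   distinct nominal signal scale (V vs T vs T/m) so that downstream
#'   standardization matters.
#' @param fs sampling rate, Hz.
#' @param epoch_span numeric `c(start, end)` in seconds relative to
#'   stimulus onset.
#' @param aperiodic_exponent `c(mean, sd)` of the per-subject 1/f
#'   exponent chi (power ~ 1/f^chi).
#' @param demand_effect list with `broadband_amplitude_factor`,
#'   `slope_delta` and `channel_map` (length-`n_channels` weights in
#'   `[0, 1]`, or a named list of such vectors keyed by task for
#'   task-specific maps; `NULL` = first half of channels at weight 1).
#' @param content_effect same structure, applied to the colour condition;
#'   `NULL` map = second half of channels at weight 1.
#' @param oscillations list of oscillation specs, each a list with
#'   `center_freq` (Hz), `amplitude` (relative to the unit-variance
#'   aperiodic background), `bandwidth` (Hz; per-trial centre frequency
#'   jitter range), `demand_amplitude_factor`, `channel_map` (`NULL` =
#'   all channels at weight 1). Oscillations get a fresh uniform random
#'   phase per trial, so they are induced (non-phase-locked) activity.
#' @param evoked `NULL`, or a list with `latency` (s), `duration` (s) and
#'   `amplitude`: a raised-cosine transient added identically to every
#'   trial (phase-locked).
#' @param noise_floor standard deviation of additive white sensor noise,
#'   in the same relative units as the unit-variance background.
#' @param tasks,contents subsets of the full design, for smaller runs.
#' @param seed master seed; every random draw descends from it via
#'   [derive_seed()] (one stream per subject).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1,
                       n_trials_per_condition = 40,
                       n_channels = 64,
                       channel_kinds = c("eeg", "magnetometer", "gradiometer"),
                       fs = 200,
                       epoch_span = c(-1, 2),
                       aperiodic_exponent = c(mean = 1.5, sd = 0.2),
                       demand_effect = list(broadband_amplitude_factor = 0.8,
                                            slope_delta = 0.1,
                                            channel_map = NULL),
                       content_effect = list(broadband_amplitude_factor = 0.9,
                                             slope_delta = 0,
                                             channel_map = NULL),
                       oscillations = list(list(center_freq = 10,
                                                amplitude = 1,
                                                bandwidth = 2,
                                                demand_amplitude_factor = 0.8,
                                                channel_map = NULL)),
                       evoked = list(latency = 0.1, duration = 0.3,
                                     amplitude = 2),
                       noise_floor = 0.3,
                       tasks = task_levels(),
                       contents = content_levels(),
                       seed = 1) {
  cfg <- list(
    n_subjects = n_subjects,
    n_trials_per_condition = n_trials_per_condition,
    n_channels = n_channels,
    channel_kinds = channel_kinds,
    fs = fs,
    epoch_span = epoch_span,
    aperiodic_exponent = aperiodic_exponent,
    demand_effect = demand_effect,
    content_effect = content_effect,
    oscillations = oscillations,
    evoked = evoked,
    noise_floor = noise_floor,
    tasks = tasks,
    contents = contents,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$fs <= 0) stop_invalid("fs must be positive")
  if (length(cfg$epoch_span) != 2L || cfg$epoch_span[1] >= cfg$epoch_span[2]) {
    stop_invalid("epoch_span must be c(start, end) with start < end")
  }
  if (cfg$n_trials_per_condition < 8) {
    stop_invalid("n_trials_per_condition must be >= 8")
  }
  if (cfg$n_channels < 1 || cfg$n_subjects < 1) {
    stop_invalid("n_channels and n_subjects must be >= 1")
  }
  if (!all(cfg$channel_kinds %in% names(channel_kind_units()))) {
    stop_invalid("channel_kinds must be drawn from: %s",
                 paste(names(channel_kind_units()), collapse = ", "))
  }
  if (!all(cfg$tasks %in% task_levels()) || length(cfg$tasks) < 1) {
    stop_invalid("tasks must be a non-empty subset of WM, SWIT, MSIT")
  }
  if (!all(cfg$contents %in% content_levels()) || length(cfg$contents) < 1) {
    stop_invalid("contents must be a non-empty subset of alphanumeric, colour")
  }
  for (eff in list(cfg$demand_effect, cfg$content_effect)) {
    if (eff$broadband_amplitude_factor <= 0) {
      stop_invalid("broadband_amplitude_factor must be > 0")
    }
  }
  for (osc in cfg$oscillations) {
    if (osc$center_freq <= 0 || osc$center_freq >= cfg$fs / 2) {
      stop_invalid("oscillation center_freq must lie in (0, fs/2)")
    }
    if (osc$demand_amplitude_factor <= 0) {
      stop_invalid("oscillation demand_amplitude_factor must be > 0")
    }
  }
  check_map <- function(m) {
    if (!is.null(m) && (any(m < 0) || any(m > 1))) {
      stop_invalid("channel_map weights must lie in [0, 1]")
    }
    if (!is.null(m) && length(m) != cfg$n_channels && !is.list(m)) {
      stop_invalid("channel_map length (%d) must equal n_channels (%d)",
                   length(m), cfg$n_channels)
    }
  }
  dm <- cfg$demand_effect$channel_map
  if (is.list(dm)) lapply(dm, check_map) else check_map(dm)
  check_map(cfg$content_effect$channel_map)
  for (osc in cfg$oscillations) check_map(osc$channel_map)
  invisible(cfg)
}

# Resolve a channel map specification to a numeric weight vector for one
# task. `map` may be NULL (use `default`), a vector, or a named list
# keyed by task.
resolve_map <- function(map, task, n_channels, default) {
  if (is.null(map)) return(default)
  if (is.list(map)) {
    if (is.null(map[[task]])) {
      stop_invalid("channel_map list has no entry for task '%s'", task)
    }
    return(as.numeric(map[[task]]))
  }
  as.numeric(map)
}

#' Power-law (1/f^chi) noise
#'
#' Synthesizes noise whose expected power spectrum is proportional to
#' `1/f^exponent`, by spectral shaping: the FFT of white Gaussian noise
#' is scaled by `f^(-exponent/2)` (DC removed) and inverted. The result
#' is normalized to unit sample variance.
#'
#' @param n_samples series length (>= 2).
#' @param fs sampling rate, Hz.
#' @param exponent spectral exponent chi >= 0 (0 = white noise).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of length `n_samples` with sample variance 1.
#' @export
gen_powerlaw_noise <- function(n_samples, fs, exponent, seed = NULL) {
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  if (n_samples < 2) stop_invalid("n_samples must be >= 2")
  if (exponent < 0) stop_invalid("exponent must be >= 0")
  draw <- function() powerlaw_noise_mat(n_samples, fs, exponent)[, 1]
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Matrix version: one column per channel, exponents recycled over
# columns. Uses the current RNG stream. Each column is normalized to
# unit sample variance.
powerlaw_noise_mat <- function(n, fs, exponents, n_series = length(exponents)) {
  exponents <- rep_len(exponents, n_series)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n   # two-sided frequency magnitude per bin
  lf <- log(ifelse(f > 0, f, 1))
  # n x C amplitude shaping, exact 1/f^chi target spectrum in expectation
  amp <- exp(outer(lf, -exponents / 2))
  amp[1, ] <- 0                   # remove DC
  x <- matrix(stats::rnorm(n * n_series), n, n_series)
  y <- Re(stats::mvfft(stats::mvfft(x) * amp, inverse = TRUE)) / n
  sdv <- sqrt(colMeans(y^2) - colMeans(y)^2) * sqrt(n / (n - 1))
  sweep(y, 2, sdv, "/")
}

#' Narrow-band oscillation with random phase
#'
#' A sinusoid at `center_freq` whose phase is drawn uniformly on
#' `[0, 2*pi)` per call, so that averaging across epochs cancels it
#' (induced, non-phase-locked activity).
#'
#' @param center_freq oscillation frequency in Hz, must be below `fs/2`.
#' @param amplitude peak amplitude.
#' @param n_samples series length.
#' @param fs sampling rate, Hz.
#' @param phase fixed phase in radians, or `NULL` to draw one.
#' @param seed integer seed for the phase draw; `NULL` uses the current
#'   RNG stream.
#' @return numeric vector of length `n_samples`.
#' @export
gen_oscillation <- function(center_freq, amplitude, n_samples, fs,
                            phase = NULL, seed = NULL) {
  if (center_freq <= 0 || center_freq >= fs / 2) {
    stop_invalid("center_freq must lie in (0, fs/2)")
  }
  draw <- function() {
    ph <- if (is.null(phase)) stats::runif(1, 0, 2 * pi) else phase
    t <- seq(0, n_samples - 1) / fs
    amplitude * sin(2 * pi * center_freq * t + ph)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Raised-cosine transient, zero outside [latency, latency + duration].
evoked_waveform <- function(evoked, n, fs, t0) {
  t <- t0 + seq(0, n - 1) / fs
  w <- numeric(n)
  inside <- t >= evoked$latency & t < evoked$latency + evoked$duration
  u <- (t[inside] - evoked$latency) / evoked$duration
  w[inside] <- evoked$amplitude * 0.5 * (1 - cos(2 * pi * u))
  w
}

nominal_channel_scale <- function(kind) {
  c(eeg = 2e-5, magnetometer = 2e-13, gradiometer = 2e-11)[kind]
}

#' Generate a synthetic epoched data set with known ground truth
#'
#' Builds a full factorial design (tasks x contents x demands from the
#' configuration, `n_trials_per_condition` trials each, per subject).
#' Every trial is composed, per channel, of (i) unit-variance 1/f^chi
#' background noise with the subject's exponent plus any map-weighted
#' `slope_delta`, scaled by the map-weighted condition amplitude factors;
#' (ii) the configured random-phase oscillations; (iii) the optional
#' phase-locked evoked transient; and (iv) white sensor noise — all
#' multiplied by the channel's nominal kind scale.
#'
#' @param config a [sim_config].
#' @return a list with elements `epochs` (an [epoch_set]) and `truth`
#'   (a `ground_truth` list recording per-subject exponents, the resolved
#'   demand/content maps, the oscillation specs, and the exact
#'   multiplicative amplitude factor applied to each condition x channel).
#' @export
gen_epoch_set <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- round(cfg$fs * (cfg$epoch_span[2] - cfg$epoch_span[1]))
  C <- cfg$n_channels
  kinds <- rep_len(cfg$channel_kinds, C)
  scales <- nominal_channel_scale(kinds)
  channels <- data.frame(
    name = sprintf("%s%03d", toupper(substr(kinds, 1, 3)), seq_len(C)),
    kind = kinds,
    unit = channel_kind_units()[kinds],
    scale = scales,
    stringsAsFactors = FALSE
  )
  half <- seq_len(ceiling(C / 2))
  default_demand_map <- as.numeric(seq_len(C) %in% half)
  default_content_map <- as.numeric(!(seq_len(C) %in% half))

  cells <- expand.grid(demand = demand_levels(),
                       content = cfg$contents,
                       task = cfg$tasks,
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, 3:1]
  n_cells <- nrow(cells)
  nt <- cfg$n_trials_per_condition
  n_ep_subj <- n_cells * nt
  total <- cfg$n_subjects * n_ep_subj

  data <- array(0, dim = c(total, C, n))
  labels <- data.frame(subject = character(total), task = character(total),
                       content = character(total), demand = character(total),
                       stringsAsFactors = FALSE)

  check_degenerate <- function(map, factor, what) {
    if (all(map == 0) && factor != 1) {
      warning(sprintf("%s channel_map is all zero but its factor is %g: %s",
                      what, factor, "effect cannot manifest"), call. = FALSE)
    }
  }

  evoked_sig <- if (!is.null(cfg$evoked)) {
    evoked_waveform(cfg$evoked, n, cfg$fs, cfg$epoch_span[1])
  } else NULL

  exponents <- numeric(cfg$n_subjects)
  # exact per-channel amplitude factor for each condition cell
  amp_factors <- matrix(1, n_cells, C)
  rownames(amp_factors) <- paste(cells$task, cells$content, cells$demand,
                                 sep = ".")
  demand_maps <- list()

  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    subj_id <- sprintf("S%02d", s)
    with_seed(derive_seed(cfg$seed, s), {
      chi_s <- stats::rnorm(1, cfg$aperiodic_exponent[["mean"]],
                            cfg$aperiodic_exponent[["sd"]])
      exponents[s] <- chi_s
      for (ci in seq_len(n_cells)) {
        task <- cells$task[ci]
        content <- cells$content[ci]
        demand <- cells$demand[ci]
        dmap <- resolve_map(cfg$demand_effect$channel_map, task, C,
                            default_demand_map)
        cmap <- resolve_map(cfg$content_effect$channel_map, task, C,
                            default_content_map)
        demand_maps[[task]] <- dmap
        if (s == 1L && ci == 1L) {
          check_degenerate(dmap, cfg$demand_effect$broadband_amplitude_factor,
                           "demand_effect")
          check_degenerate(cmap, cfg$content_effect$broadband_amplitude_factor,
                           "content_effect")
        }
        hard <- demand == "hard"
        colour <- content == "colour"
        af <- rep(1, C)
        chi_c <- rep(chi_s, C)
        if (hard) {
          af <- af * cfg$demand_effect$broadband_amplitude_factor^dmap
          chi_c <- chi_c + cfg$demand_effect$slope_delta * dmap
        }
        if (colour) {
          af <- af * cfg$content_effect$broadband_amplitude_factor^cmap
          chi_c <- chi_c + cfg$content_effect$slope_delta * cmap
        }
        if (s == 1L) amp_factors[ci, ] <- af
        chi_c <- pmax(chi_c, 0)
        for (tr in seq_len(nt)) {
          x <- powerlaw_noise_mat(n, cfg$fs, chi_c)
          x <- sweep(x, 2, af, "*")
          for (osc in cfg$oscillations) {
            omap <- if (is.null(osc$channel_map)) rep(1, C) else
              resolve_map(osc$channel_map, task, C, rep(1, C))
            f_tr <- stats::runif(1, osc$center_freq - osc$bandwidth / 2,
                                 osc$center_freq + osc$bandwidth / 2)
            o <- gen_oscillation(f_tr, osc$amplitude, n, cfg$fs)
            oamp <- omap * if (hard) osc$demand_amplitude_factor^omap else 1
            x <- x + outer(o, oamp)
          }
          if (!is.null(evoked_sig)) x <- x + evoked_sig
          if (cfg$noise_floor > 0) {
            x <- x + matrix(stats::rnorm(n * C, sd = cfg$noise_floor), n, C)
          }
          x <- sweep(x, 2, scales, "*")
          idx <- idx + 1L
          data[idx, , ] <- t(x)
          labels$subject[idx] <- subj_id
          labels$task[idx] <- task
          labels$content[idx] <- content
          labels$demand[idx] <- demand
        }
      }
    })
  }

  epochs <- epoch_set(data, fs = cfg$fs, t0 = cfg$epoch_span[1],
                      channels = channels, labels = labels)
  truth <- structure(list(
    exponents = stats::setNames(exponents,
                                sprintf("S%02d", seq_len(cfg$n_subjects))),
    demand_maps = demand_maps,
    content_map = resolve_map(cfg$content_effect$channel_map, cfg$tasks[1],
                              C, default_content_map),
    amp_factors = amp_factors,
    oscillations = cfg$oscillations,
    config = cfg
  ), class = "ground_truth")
  list(epochs = epochs, truth = truth)
}

#' Serialize a ground-truth record to JSON
#'
#' @param truth a `ground_truth` object from [gen_epoch_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$config <- unclass(out$config)
  out$amp_factors <- as.data.frame(out$amp_factors)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
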