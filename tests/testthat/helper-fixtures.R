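# Shared fixtures, all generated in code at test time.

# Log-log periodogram regression oracle, independent of the package's
# spectral code path (stats::spec.pgram + lm).
periodogram_slope <- function(x, fs, flo, fhi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  sel <- sp$freq >= flo & sp$freq <= fhi
  unname(stats::coef(stats::lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel])))[2])
}

# Mean band power oracle via Welch-style averaged periodograms
# (stats::spec.pgram per epoch), independent of the package PSD code.
welch_band_power <- function(epoch_mat, fs, flo, fhi) {
  ps <- apply(epoch_mat, 2, function(v) {
    sp <- stats::spec.pgram(stats::ts(v, frequency = fs), taper = 0,
                            detrend = FALSE, plot = FALSE)
    mean(sp$spec[sp$freq >= flo & sp$freq <= fhi])
  })
  mean(ps)
}

# Build a minimal epoch_set by hand.
toy_epochs <- function(data, fs = 200, t0 = -1,
                       kinds = rep("eeg", dim(data)[2]),
                       labels = NULL) {
  nc <- dim(data)[2]
  channels <- data.frame(
    name = sprintf("CH%02d", seq_len(nc)),
    kind = kinds,
    unit = c(eeg = "V", magnetometer = "T", gradiometer = "T/m")[kinds],
    stringsAsFactors = FALSE)
  if (is.null(labels)) {
    labels <- data.frame(subject = "S01", task = "WM",
                         content = "alphanumeric",
                         demand = rep(c("easy", "hard"),
                                      length.out = dim(data)[1]),
                         stringsAsFactors = FALSE)
  }
  epoch_set(data, fs = fs, t0 = t0, channels = channels, labels = labels)
}

demand_levels_acc <- c("easy", "hard")

# Seeded draws that leave the ambient RNG state alone.
with_seed_freq <- function(seed, lo = 9, hi = 11) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  runif(1, lo, hi)
}

with_seed_matrix <- function(seed, nr, nc) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

with_seed_vec <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n)
}

# Two-class Gaussian feature set with a mean shift `d` (in pooled-sd
# units) applied to the named columns.
gaussian_classes <- function(n_per_class, n_feat, d = 0, shifted = 1,
                             seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * n_feat), 2 * n_per_class, n_feat)
  y <- factor(rep(c("easy", "hard"), each = n_per_class),
              levels = c("easy", "hard"))
  x[y == "hard", shifted] <- x[y == "hard", shifted] + d
  colnames(x) <- sprintf("F%02d", seq_len(n_feat))
  list(x = x, y = y)
}
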