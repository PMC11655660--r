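#' Per-trial feature matrix for one signal type
#'
#' Observations x features matrix for one of the six spectral signals
#' (`bb_power`, `slope`, `intercept`, `theta`, `alpha`, `beta`), with
#' per-observation condition labels. Features are channels in sensor
#' space or ROI names in source space; the decoding stages are agnostic
#' to which.
#'
#' @param signal signal name, one of [signal_names()].
#' @param x numeric matrix, observations x features, all finite.
#' @param feature_ids character vector of channel or ROI names.
#' @param labels data frame, one row per observation, with at least
#'   `subject`, `task`, `content`, `demand`.
#' @return an object of class `signal_features`.
#' @export
signal_features <- function(signal, x, feature_ids, labels) {
  if (!signal %in% signal_names()) {
    stop_invalid("unknown signal '%s'; expected one of: %s", signal,
                 paste(signal_names(), collapse = ", "))
  }
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_invalid("feature matrix contains non-finite values")
  if (ncol(x) != length(feature_ids)) {
    stop_invalid("feature_ids length (%d) must match matrix columns (%d)",
                 length(feature_ids), ncol(x))
  }
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (nrow(labels) != nrow(x)) {
    stop_invalid("labels rows (%d) must match matrix rows (%d)",
                 nrow(labels), nrow(x))
  }
  colnames(x) <- feature_ids
  structure(list(signal = signal, x = x,
                 feature_ids = as.character(feature_ids), labels = labels),
            class = "signal_features")
}

#' @export
print.signal_features <- function(x, ...) {
  cat(sprintf("<signal_features> %s: %d observations x %d features\n",
              x$signal, nrow(x$x), ncol(x$x)))
  invisible(x)
}

# Subset observations of a signal_features object.
sf_subset <- function(sf, rows) {
  signal_features(sf$signal, sf$x[rows, , drop = FALSE], sf$feature_ids,
                  sf$labels[rows, , drop = FALSE])
}

#' Extract all six per-trial signals from an epoch set
#'
#' Runs IRASA on every epoch x channel series of the (already windowed)
#' epoch set, fits the aperiodic line per series, and assembles one
#' [signal_features] object per signal type: trials as observations,
#' channels as features.
#'
#' @param epochs an [epoch_set], typically after evoked subtraction and
#'   cropping to the analysis window.
#' @param config an [irasa_config].
#' @return named list of six [signal_features] objects.
#' @export
spectral_features <- function(epochs, config = irasa_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  ne <- n_epochs(epochs)
  nc <- n_channels(epochs)
  ns <- n_samples(epochs)
  # samples x (epoch * channel) with epoch index varying fastest
  mat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = ns)
  r <- irasa_batch(mat, epochs$fs, config)
  fits <- fit_aperiodic_mat(r$aperiodic, r$freq, config$fit_range,
                            config$log_base)
  frame <- spectral_frame(r$freq, t(r$mixed), t(r$aperiodic))
  feats <- band_features(frame, fits, config)
  out <- list()
  for (sig in signal_names()) {
    out[[sig]] <- signal_features(
      sig, matrix(feats[[sig]], ne, nc), epochs$channels$name, epochs$labels)
  }
  out
}

#' Write per-trial features as a tidy TSV table
#'
#' One row per (trial, channel, signal) with the condition labels.
#'
#' @param features named list from [spectral_features()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  rows <- lapply(features, function(sf) {
    nfeat <- length(sf$feature_ids)
    nobs <- nrow(sf$x)
    data.frame(
      sf$labels[rep(seq_len(nobs), nfeat), , drop = FALSE],
      trial = rep(seq_len(nobs), nfeat),
      channel = rep(sf$feature_ids, each = nobs),
      signal = sf$signal,
      value = as.vector(sf$x),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
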