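#' Peak-to-peak rejection thresholds by channel kind
#'
#' Defaults are the conventional M/EEG artifact limits: 350 microvolts
#' for EEG, 5000 fT for magnetometers and 4000 fT/cm for gradiometers,
#' expressed in SI base units (V, T, T/m).
#'
#' @param eeg volts peak-to-peak.
#' @param magnetometer tesla peak-to-peak.
#' @param gradiometer tesla/metre peak-to-peak (4000 fT/cm = 4e-10 T/m).
#' @return named list of thresholds.
#' @export
rejection_thresholds <- function(eeg = 350e-6,
                                 magnetometer = 5000e-15,
                                 gradiometer = 4e-10) {
  th <- list(eeg = eeg, magnetometer = magnetometer,
             gradiometer = gradiometer)
  if (any(unlist(th) <= 0)) stop_invalid("all thresholds must be positive")
  th
}

#' Reject epochs exceeding peak-to-peak amplitude thresholds
#'
#' An epoch is dropped iff any of its channels has a peak-to-peak
#' amplitude (max minus min over samples) above the threshold for that
#' channel's kind. The rejection report lists every offending
#' (epoch, channel) pair with its measured amplitude, which can be
#' written as TSV for audit.
#'
#' @param epochs an [epoch_set].
#' @param thresholds list from [rejection_thresholds()].
#' @return list with `epochs` (the retained subset) and `report` (data
#'   frame: `epoch`, `channel`, `kind`, `ptp`, `threshold`).
#' @export
reject_epochs <- function(epochs, thresholds = rejection_thresholds()) {
  stopifnot(inherits(epochs, "epoch_set"))
  kinds <- epochs$channels$kind
  missing_kind <- setdiff(unique(kinds), names(thresholds))
  if (length(missing_kind)) {
    stop_invalid("no rejection threshold configured for channel kind(s): %s",
                 paste(missing_kind, collapse = ", "))
  }
  th <- unlist(thresholds[kinds])
  # peak-to-peak per epoch x channel
  ptp <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  over <- sweep(ptp, 2, th, ">")
  bad <- which(over, arr.ind = TRUE)
  report <- data.frame(
    epoch = bad[, 1],
    channel = epochs$channels$name[bad[, 2]],
    kind = kinds[bad[, 2]],
    ptp = ptp[bad],
    threshold = th[bad[, 2]],
    row.names = NULL, stringsAsFactors = FALSE
  )
  report <- report[order(report$epoch, report$channel), , drop = FALSE]
  keep <- !(seq_len(n_epochs(epochs)) %in% report$epoch)
  out <- epoch_set(epochs$data[keep, , , drop = FALSE], epochs$fs, epochs$t0,
                   epochs$channels, epochs$labels[keep, , drop = FALSE])
  list(epochs = out, report = report)
}

#' Write a rejection report as TSV
#'
#' @param report data frame from [reject_epochs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove evoked (phase-locked) activity
#'
#' Within each finest labelled condition cell (subject x task x content
#' x demand), subtracts the cell-mean time series from every trial of
#' that cell, channel by channel. Phase-locked transients (which survive
#' trial averaging) are removed; non-phase-locked oscillations (which
#' cancel in the average) are preserved, which is the point: downstream
#' spectral features then reflect induced activity only.
#'
#' @param epochs an [epoch_set]; every condition cell must hold at least
#'   two epochs (subtracting a singleton's mean would zero the trial).
#' @return an [epoch_set] of residuals; each cell's residual mean is the
#'   zero series.
#' @export
subtract_evoked <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  cells <- condition_cells(epochs$labels)
  counts <- table(cells)
  if (any(counts < 2)) {
    stop_invalid("condition cell(s) with a single epoch: %s",
                 paste(names(counts)[counts < 2], collapse = ", "))
  }
  data <- epochs$data
  for (cell in levels(cells)) {
    rows <- which(cells == cell)
    block <- data[rows, , , drop = FALSE]
    m <- colMeans(block)  # channels x samples
    data[rows, , ] <- sweep(block, c(2, 3), m, "-")
  }
  epoch_set(data, epochs$fs, epochs$t0, epochs$channels, epochs$labels)
}

#' Crop epochs to an analysis window
#'
#' Restricts every epoch to the half-open interval `[start, end)` on the
#' sample grid (sample `i` lives at time `t0 + i/fs`), the convention
#' that gives unambiguous sample counts: a 0.3-1.5 s window at 200 Hz
#' yields exactly 240 samples.
#'
#' @param epochs an [epoch_set].
#' @param start,end window bounds in seconds relative to stimulus onset.
#' @return an [epoch_set] with updated `t0`.
#' @export
crop_window <- function(epochs, start, end) {
  stopifnot(inherits(epochs, "epoch_set"))
  ns <- n_samples(epochs)
  t_end <- epochs$t0 + ns / epochs$fs
  if (start < epochs$t0 - 1e-9 || end > t_end + 1e-9 || start >= end) {
    stop_invalid("window [%g, %g) falls outside the epoch span [%g, %g)",
                 start, end, epochs$t0, t_end)
  }
  i0 <- round((start - epochs$t0) * epochs$fs) + 1L
  i1 <- round((end - epochs$t0) * epochs$fs)
  epoch_set(epochs$data[, , i0:i1, drop = FALSE], epochs$fs,
            t0 = epochs$t0 + (i0 - 1L) / epochs$fs,
            epochs$channels, epochs$labels)
}
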