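#' Epoched multichannel electrophysiological data
#'
#' The universal input container of the package: a labelled
#' epochs x channels x samples tensor with its sampling rate, epoch
#' timing and channel metadata. All preprocessing and spectral stages
#' consume and return objects of this class.
#'
#' @param data numeric array of dimension `c(n_epochs, n_channels,
#'   n_samples)`. Units are per-channel (volts for EEG, tesla for
#'   magnetometers, tesla/metre for gradiometers).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds relative to stimulus
#'   onset (e.g. -1 for epochs spanning -1 to 2 s).
#' @param channels data frame with columns `name`, `kind` (one of
#'   `"eeg"`, `"magnetometer"`, `"gradiometer"`) and `unit`.
#' @param labels data frame with one row per epoch and columns
#'   `subject`, `task` (`"WM"`, `"SWIT"`, `"MSIT"`), `content`
#'   (`"alphanumeric"`, `"colour"`) and `demand` (`"easy"`, `"hard"`).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0, channels, labels) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_invalid("`data` must be a 3-d array (epochs x channels x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_invalid("`fs` must be a single positive number")
  }
  d <- dim(data)
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (nrow(channels) != d[2]) {
    stop_invalid("channel table has %d rows but data has %d channels",
                 nrow(channels), d[2])
  }
  if (nrow(labels) != d[1]) {
    stop_invalid("label table has %d rows but data has %d epochs",
                 nrow(labels), d[1])
  }
  req <- c("name", "kind", "unit")
  if (!all(req %in% names(channels))) {
    stop_invalid("channel table must have columns: %s",
                 paste(req, collapse = ", "))
  }
  bad_kind <- setdiff(unique(channels$kind), names(channel_kind_units()))
  if (length(bad_kind)) {
    stop_invalid("unknown channel kind(s): %s", paste(bad_kind, collapse = ", "))
  }
  reql <- c("subject", "task", "content", "demand")
  if (!all(reql %in% names(labels))) {
    stop_invalid("label table must have columns: %s",
                 paste(reql, collapse = ", "))
  }
  check_vocab <- function(x, vocab, what) {
    bad <- setdiff(unique(as.character(x)), vocab)
    if (length(bad)) {
      stop_invalid("invalid %s value(s): %s", what, paste(bad, collapse = ", "))
    }
  }
  check_vocab(labels$task, task_levels(), "task")
  check_vocab(labels$content, content_levels(), "content")
  check_vocab(labels$demand, demand_levels(), "demand")
  structure(
    list(data = data, fs = fs, t0 = t0, channels = channels, labels = labels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples @ %g Hz, t0 = %g s\n",
    d[1], d[2], d[3], x$fs, x$t0))
  cat(sprintf("  subjects: %s\n",
              paste(unique(x$labels$subject), collapse = ", ")))
  cat(sprintf("  channel kinds: %s\n",
              paste(names(table(x$channels$kind)), collapse = ", ")))
  invisible(x)
}

task_levels <- function() c("WM", "SWIT", "MSIT")
content_levels <- function() c("alphanumeric", "colour")
demand_levels <- function() c("easy", "hard")

channel_kind_units <- function() {
  c(eeg = "V", magnetometer = "T", gradiometer = "T/m")
}

n_epochs <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

# Interaction factor identifying the finest labelled condition cell.
condition_cells <- function(labels) {
  interaction(labels$subject, labels$task, labels$content, labels$demand,
              drop = TRUE, lex.order = TRUE)
}

#' Write an epoch set to disk
#'
#' Stores the data tensor as a flat little-endian double array
#' (`<prefix>.dat`, epoch-major, i.e. `aperm(data, c(3, 2, 1))` order)
#' with a JSON sidecar (`<prefix>.json`) holding the sampling rate,
#' epoch timing, channel table and label table.
#'
#' @param x an [epoch_set].
#' @param prefix path prefix; `.dat` and `.json` are appended.
#' @return `prefix`, invisibly.
#' @export
write_epoch_set <- function(x, prefix) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(x$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  sidecar <- list(
    dims = d, dim_order = c("epoch", "channel", "sample"),
    fs = x$fs, t0 = x$t0,
    channels = x$channels, labels = x$labels
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param prefix path prefix used when writing.
#' @return an [epoch_set].
#' @export
read_epoch_set <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  d <- as.integer(sidecar$dims)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "double", n = prod(d), size = 8,
                 endian = "little")
  data <- aperm(array(raw, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  epoch_set(data, fs = sidecar$fs, t0 = sidecar$t0,
            channels = sidecar$channels, labels = sidecar$labels)
}
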