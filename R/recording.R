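#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG signal with montage labels, sampling rate
#' and chronological block annotations. The data matrix is channel x sample
#' (microvolts); annotations mark contiguous task blocks carrying a workload
#' label (\code{"low"}/\code{"high"}), an experimental condition
#' (\code{"nback"}/\code{"maneuver"}) and a phase index.
#'
#' @param data numeric matrix, channels x samples (one row per channel).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of 10/10 electrode names, one per row.
#' @param reference reference scheme label; default \code{"linked-mastoid"}.
#' @param annotations data.frame of blocks as returned by
#'   \code{\link{block_annotations}} (may have zero rows).
#' @param band band tag of the data (\code{"broadband"} until band-pass
#'   filtered).
#' @return An object of class \code{"eeg_recording"}.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          reference = "linked-mastoid",
                          annotations = block_annotations(),
                          band = "broadband") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (nrow(data) != length(channel_labels))
    stop("data must have exactly one row per channel label")
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  annotations <- validate_blocks(annotations)
  if (nrow(annotations) > 0 &&
      max(annotations$end_s) > ncol(data) / fs + 1e-9)
    stop("annotations extend beyond the recording")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 reference = reference, annotations = annotations,
                 band = band),
            class = "eeg_recording")
}

#' Block annotations
#'
#' Build (and validate) the chronological block table of a recording.
#'
#' @param start_s,end_s block boundaries in seconds.
#' @param label workload class per block, \code{"low"} or \code{"high"}.
#' @param condition \code{"nback"} or \code{"maneuver"}.
#' @param phase integer phase (repetition) index.
#' @return data.frame with one row per block.
#' @export
block_annotations <- function(start_s = numeric(0), end_s = numeric(0),
                              label = character(0), condition = character(0),
                              phase = integer(0)) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label),
                   condition = as.character(condition),
                   phase = as.integer(phase), stringsAsFactors = FALSE)
  validate_blocks(df)
}

validate_blocks <- function(df) {
  if (!is.data.frame(df)) stop("annotations must be a data.frame")
  need <- c("start_s", "end_s", "label", "condition", "phase")
  if (!all(need %in% names(df))) stop("annotations need columns: ",
                                      paste(need, collapse = ", "))
  if (nrow(df) == 0) return(df)
  if (any(df$end_s <= df$start_s)) stop("block end_s must exceed start_s")
  if (!all(df$label %in% c("low", "high"))) stop("labels must be low/high")
  if (!all(df$condition %in% c("nback", "maneuver")))
    stop("condition must be nback/maneuver")
  if (is.unsorted(df$start_s, strictly = FALSE))
    stop("blocks must be chronological")
  if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9))
    stop("blocks must not overlap")
  df
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz (%s, %s ref)\n",
              nrow(x$data), ncol(x$data) / x$fs, x$fs, x$band, x$reference))
  if (nrow(x$annotations) > 0) {
    tab <- table(x$annotations$label)
    cat(sprintf("  %d blocks [%s], condition(s): %s\n", nrow(x$annotations),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
                paste(unique(x$annotations$condition), collapse = ", ")))
  } else cat("  no annotations\n")
  invisible(x)
}

#' Set of fixed-length epochs
#'
#' Epoch x channel x sample tensor with per-epoch class labels and block ids.
#' Usually produced by \code{\link{epoch_recording}} from an annotated
#' recording; the constructor checks shape consistency.
#'
#' @param epochs 3-d array: epoch x channel x sample.
#' @param labels class label per epoch (\code{"low"}/\code{"high"}).
#' @param block_ids integer block index per epoch.
#' @param band band tag (\code{"alpha"}, \code{"theta"} or
#'   \code{"broadband"}).
#' @param fs sampling rate (Hz).
#' @param epoch_length_s epoch duration in seconds (default 60).
#' @param channel_labels optional channel (or component) names.
#' @param phases optional integer phase per epoch.
#' @param condition optional condition tag.
#' @return Object of class \code{"epoch_set"}.
#' @export
epoch_set <- function(epochs, labels, block_ids, band = "broadband", fs,
                      epoch_length_s = ncol_samples(epochs) / fs,
                      channel_labels = NULL, phases = NULL, condition = NA) {
  if (length(dim(epochs)) != 3L) stop("epochs must be a 3-d array")
  n <- dim(epochs)[1L]
  if (length(labels) != n || length(block_ids) != n)
    stop("labels/block_ids must have one entry per epoch")
  if (abs(epoch_length_s * fs - dim(epochs)[3L]) > 1e-6)
    stop("epoch_length_s * fs must equal the sample count")
  structure(list(epochs = epochs, labels = as.character(labels),
                 block_ids = as.integer(block_ids), band = band, fs = fs,
                 epoch_length_s = epoch_length_s,
                 channel_labels = channel_labels,
                 phases = if (is.null(phases)) rep(1L, n) else as.integer(phases),
                 condition = condition),
            class = "epoch_set")
}

ncol_samples <- function(epochs) dim(epochs)[3L]

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%s band)\n",
              d[1], d[2], d[3], x$band))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x an \code{\link{epoch_set}}.
#' @return integer epoch count.
#' @export
n_epochs <- function(x) dim(x$epochs)[1L]

#' Extract one epoch as a single-epoch set
#' @param x an \code{epoch_set}.
#' @param i epoch index.
#' @return single-epoch \code{epoch_set}.
#' @export
epoch_subset <- function(x, i) {
  epoch_set(x$epochs[i, , , drop = FALSE], x$labels[i], x$block_ids[i],
            x$band, x$fs, x$epoch_length_s, x$channel_labels, x$phases[i],
            x$condition)
}
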