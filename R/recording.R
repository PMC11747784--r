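#' Construct an EEG recording
#'
#' An `eeg_recording` bundles a multichannel EEG signal (microvolts) with its
#' digital trigger line and acquisition metadata. The trigger encodes the
#' paradigm state sample-by-sample: 0 during visual stimulation, 1 during
#' rest, which is what [epochs_from_trigger()] decodes into epochs.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_names Character vector naming the rows of `data`. Defaults
#'   to the montage used throughout the package: O1, O2, Pz, Cz.
#' @param fs Sampling rate in Hz (default 250).
#' @param trigger Integer vector with one value per sample, alphabet {0, 1}
#'   (0 = stimulation, 1 = rest). Defaults to all-zero.
#' @param meta Named list of free-form metadata (subject id, condition,
#'   session notes, ...).
#'
#' @return An object of class `eeg_recording`.
#' @export
#'
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 500), nrow = 4))
#' rec
eeg_recording <- function(data,
                          channel_names = c("O1", "O2", "Pz", "Cz"),
                          fs = 250,
                          trigger = NULL,
                          meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  n <- ncol(data)
  if (is.null(trigger)) trigger <- integer(n)
  trigger <- as.integer(trigger)
  rec <- structure(
    list(
      data = data,
      channel_names = as.character(channel_names),
      fs = fs,
      trigger = trigger,
      meta = meta
    ),
    class = "eeg_recording"
  )
  validate_recording(rec)
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Validate an EEG recording
#'
#' Checks the structural invariants of an [eeg_recording()]: matching trigger
#' length, positive sampling rate, channel-name alignment, and the binary
#' trigger alphabet.
#'
#' @param rec An `eeg_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (length(rec$channel_names) != nrow(rec$data)) {
    stop("`channel_names` length must equal the number of data rows",
         call. = FALSE)
  }
  if (length(rec$trigger) != ncol(rec$data)) {
    stop("trigger length (", length(rec$trigger),
         ") must equal the number of samples (", ncol(rec$data), ")",
         call. = FALSE)
  }
  if (length(rec$trigger) && !all(rec$trigger %in% c(0L, 1L))) {
    stop("trigger values must be 0 (stimulation) or 1 (rest)", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat("<eeg_recording> ", nrow(x$data), " channel(s) x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", format(dur, digits = 4), " s)\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  if (length(x$meta)) {
    cat("  meta: ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                          sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples and duration of a recording
#' @param rec An `eeg_recording`.
#' @return `n_samples()`: integer sample count. `duration()`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

#' Decode the trigger line into stimulation/rest epochs
#'
#' Maximal runs of a constant trigger value become epochs; trigger value 0 is
#' labelled `"stimulation"` and 1 `"rest"`. Epochs are expressed as 0-based
#' half-open sample intervals `[start, end)` and tile the recording with no
#' gaps or overlaps.
#'
#' Isolated single-sample trigger glitches are deliberately not smoothed;
#' `min_epoch_samples` drops epochs shorter than the threshold instead, so
#' that any cleaning is an explicit, visible choice.
#'
#' @param rec An `eeg_recording`.
#' @param min_epoch_samples Drop epochs with fewer samples than this
#'   (default 0: keep everything).
#'
#' @return A tibble with columns `start`, `end` (0-based, half-open) and
#'   `label` (`"stimulation"` or `"rest"`), ordered by `start`. Empty
#'   recordings yield an empty tibble.
#' @export
#'
#' @examples
#' rec <- eeg_recording(matrix(0, 1, 20), channel_names = "O1",
#'                      trigger = rep(c(0L, 1L), each = 10))
#' epochs_from_trigger(rec)
epochs_from_trigger <- function(rec, min_epoch_samples = 0L) {
  validate_recording(rec)
  trig <- rec$trigger
  if (length(trig) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          label = character()))
  }
  r <- rle(trig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- tibble::tibble(
    start = as.integer(starts),
    end = as.integer(ends),
    label = ifelse(r$values == 0L, "stimulation", "rest")
  )
  if (min_epoch_samples > 0L) {
    out <- dplyr::filter(out, .data$end - .data$start >= min_epoch_samples)
  }
  out
}
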