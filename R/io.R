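#' Read an OpenBCI-GUI style text recording
#'
#' Parses the plain-text dialect used by OpenBCI GUI exports: header lines
#' prefixed with `%`, then comma-separated data rows of the form
#' `sample_index, <EEG channel 1..N>, trigger`. EEG values are microvolts and
#' are preserved to full printed precision; `key = value` header lines are
#' captured into `meta` (with `Sample Rate` and `Channels` recognised as the
#' sampling rate and channel names).
#'
#' @param path Path to the `.txt` file.
#' @param channel_names Optional channel names, overriding the header (and
#'   the O1/O2/Pz/Cz default) if given.
#' @param fs Optional sampling rate in Hz, overriding the header.
#'
#' @return An [eeg_recording()].
#' @export
read_openbci_txt <- function(path, channel_names = NULL, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- grepl("^%", lines)
  n_header <- if (any(!is_header)) which(!is_header)[1] - 1L else length(lines)
  header <- lines[seq_len(n_header)]

  meta <- list()
  hdr_fs <- NULL
  hdr_channels <- NULL
  for (h in header) {
    h <- sub("^%+\\s*", "", h)
    if (!grepl("=", h, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", h))
    value <- trimws(sub("^[^=]*=", "", h))
    if (tolower(key) %in% c("sample rate", "fs")) {
      hdr_fs <- as.numeric(sub("\\s*Hz\\s*$", "", value, ignore.case = TRUE))
    } else if (tolower(key) == "channels") {
      hdr_channels <- trimws(strsplit(value, ",", fixed = TRUE)[[1]])
    } else {
      meta[[key]] <- value
    }
  }

  body <- lines[seq_len(length(lines)) > n_header]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop("format error at data line ", bad + n_header,
         ": expected ", ncols[1], " columns, found ", ncols[bad],
         call. = FALSE)
  }
  if (ncols[1] < 3L) {
    stop("format error: need at least sample index, one EEG column and a ",
         "trigger column (found ", ncols[1], " columns)", call. = FALSE)
  }
  mat <- matrix(as.numeric(trimws(unlist(fields))),
                nrow = length(body), byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    stop("format error: non-numeric value at data line ", bad + n_header,
         call. = FALSE)
  }
  idx <- mat[, 1]
  if (is.unsorted(idx, strictly = TRUE)) {
    bad <- which(diff(idx) <= 0)[1] + 1L
    stop("format error: non-monotone sample index at data line ",
         bad + n_header, call. = FALSE)
  }
  trig <- mat[, ncol(mat)]
  if (!all(trig %in% c(0, 1))) {
    bad <- which(!(trig %in% c(0, 1)))[1]
    stop("format error: trigger value ", trig[bad], " at data line ",
         bad + n_header, " (expected 0 or 1)", call. = FALSE)
  }
  eeg <- t(mat[, -c(1, ncol(mat)), drop = FALSE])

  n_ch <- nrow(eeg)
  ch <- channel_names %||% hdr_channels %||%
    (if (n_ch == 4L) c("O1", "O2", "Pz", "Cz") else paste0("ch", seq_len(n_ch)))
  eeg_recording(eeg,
                channel_names = ch,
                fs = fs %||% hdr_fs %||% 250,
                trigger = as.integer(trig),
                meta = meta)
}

#' Write a recording to disk
#'
#' `write_recording()` writes the OpenBCI-GUI style text dialect read by
#' [read_openbci_txt()] (header lines prefixed `%` carrying the sampling
#' rate, channel names and metadata; comma-separated rows of sample index,
#' EEG channels, trigger). `write_recording_native()` /
#' `read_recording_native()` use the package's native pair: a headerless CSV
#' with the same columns plus a `<name>.meta.json` sidecar holding `fs`,
#' `channel_names` and `meta`.
#'
#' Values are written with 10 significant digits, so a round trip preserves
#' microvolt values to well within 1e-6 relative error and the trigger
#' exactly.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  header <- c(
    "%OpenBCI Raw EEG Data",
    sprintf("%%Sample Rate = %s Hz", format(rec$fs, digits = 10)),
    sprintf("%%Channels = %s", paste(rec$channel_names, collapse = ",")),
    vapply(names(rec$meta),
           function(k) sprintf("%%%s = %s", k, format(rec$meta[[k]])),
           character(1))
  )
  n <- ncol(rec$data)
  body <- if (n > 0) {
    cols <- c(list(format(seq_len(n) - 1L)),
              lapply(seq_len(nrow(rec$data)),
                     function(i) sprintf("%.10g", rec$data[i, ])),
              list(format(rec$trigger)))
    do.call(paste, c(cols, sep = ","))
  } else {
    character()
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
write_recording_native <- function(rec, path) {
  validate_recording(rec)
  df <- data.frame(sample = seq_len(ncol(rec$data)) - 1L,
                   t(rec$data),
                   trigger = rec$trigger,
                   check.names = FALSE)
  names(df) <- c("sample", rec$channel_names, "trigger")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- paste0(sub("\\.csv$", "", path), ".meta.json")
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names, meta = rec$meta),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording_native <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- paste0(sub("\\.csv$", "", path), ".meta.json")
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  ch <- setdiff(names(df), c("sample", "trigger"))
  eeg_recording(t(as.matrix(df[, ch, drop = FALSE])),
                channel_names = ch,
                fs = side$fs %||% 250,
                trigger = as.integer(df$trigger),
                meta = side$meta %||% list())
}
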