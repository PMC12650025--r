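#' Construct an EEG record
#'
#' The basic data container of the package: one subject's multichannel EEG as
#' a channels x samples numeric matrix plus its sampling rate and metadata.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs_hz sampling rate in Hz (> 0).
#' @param channel_names optional character vector, one name per channel.
#' @param subject_id subject identifier (any scalar, coerced to character).
#' @param group_label one of `"case"`, `"control"`, `"unknown"`.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs_hz, channel_names = NULL,
                       subject_id = "s1", group_label = "unknown") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (nrow(data) < 2L) stop("an EEG record needs at least 2 channels", call. = FALSE)
  if (ncol(data) < 1L) stop("an EEG record needs at least 1 sample", call. = FALSE)
  stopifnot_scalar(fs_hz, "fs_hz", positive = TRUE)
  group_label <- match.arg(group_label, c("case", "control", "unknown"))
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length must match the number of channels", call. = FALSE)
  }
  dimnames(data) <- NULL
  structure(
    list(
      data = data,
      fs_hz = fs_hz,
      channel_names = as.character(channel_names),
      subject_id = as.character(subject_id),
      group_label = group_label
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> subject %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group_label, nrow(x$data), ncol(x$data), x$fs_hz,
    ncol(x$data) / x$fs_hz
  ))
  invisible(x)
}

#' Read an EEG record from a CSV matrix
#'
#' Expects a plain numeric CSV with one row per channel and one column per
#' sample (no header), the on-disk format written by [write_eeg_csv()].
#'
#' @param path file path.
#' @inheritParams eeg_record
#' @return an `eeg_record`.
#' @export
read_eeg_csv <- function(path, fs_hz, channel_names = NULL,
                         subject_id = NULL, group_label = "unknown") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  eeg_record(m, fs_hz, channel_names,
             subject_id = subject_id %||% sub("\\.csv$", "", basename(path)),
             group_label = group_label)
}

#' Split a record into consecutive fixed-length windows
#'
#' Divides the record into `floor(n / (window_s * fs))` non-overlapping
#' windows of `window_s` seconds (a trailing remainder is discarded). Each
#' window keeps the parent's subject id and group label, so per-window
#' feature rows remain attributable to their subject.
#'
#' @param rec an `eeg_record`.
#' @param window_s window length in seconds.
#' @return list of `eeg_record` windows (possibly of length 1).
#' @export
split_record <- function(rec, window_s) {
  ws <- round(window_s * rec$fs_hz)
  nwin <- max(1L, ncol(rec$data) %/% ws)
  lapply(seq_len(nwin), function(w) {
    sl <- ((w - 1L) * ws + 1L):min(w * ws, ncol(rec$data))
    eeg_record(rec$data[, sl, drop = FALSE], rec$fs_hz, rec$channel_names,
               subject_id = rec$subject_id, group_label = rec$group_label)
  })
}

#' Write an EEG record as a CSV matrix
#'
#' @param rec an `eeg_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
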