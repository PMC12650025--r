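# Preprocessing: zero-phase band-pass, sliding-window robust amplitude
# correction, average re-referencing. The stages run in that order; an
# optional component-cleaning callback slot sits where ICA-based component
# rejection would run in a full lab pipeline (identity by default, since the
# trained component classifier is out of scope here).

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt]), so the filter is zero-phase. The default 0.5-45 Hz
#' band keeps delta through low-gamma rhythms and excludes DC drift and
#' 50/60 Hz line noise.
#'
#' @param rec an `eeg_record`.
#' @param low_hz,high_hz band edges; must satisfy 0 < low < high < Nyquist.
#' @param order filter order (per pass).
#' @return filtered `eeg_record` (same shape).
#' @export
band_pass <- function(rec, low_hz = 0.5, high_hz = 45, order = 4L) {
  nyq <- rec$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("need 0 < low_hz < high_hz < fs_hz/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  n <- ncol(rec$data)
  # odd-reflection padding suppresses filtfilt edge transients; the mean is
  # removed first (it lies outside the passband in any case)
  pad <- min(n - 1L, 3L * ceiling(rec$fs_hz / low_hz))
  out <- t(apply(rec$data, 1L, function(x) {
    x <- x - mean(x)
    left <- 2 * x[1L] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y[(pad + 1L):(pad + n)]
  }))
  if (any(!is.finite(out))) stop("band_pass produced non-finite values", call. = FALSE)
  rec$data <- out
  rec
}

# Sliding-window RMS per channel; returns window start indices and an
# n_channels x n_windows RMS matrix.
window_rms <- function(data, win, hop) {
  n <- ncol(data)
  starts <- seq(1L, max(n - win + 1L, 1L), by = hop)
  rms <- vapply(starts, function(s) {
    seg <- data[, s:min(s + win - 1L, n), drop = FALSE]
    sqrt(rowMeans(seg^2))
  }, numeric(nrow(data)))
  if (is.null(dim(rms))) rms <- matrix(rms, nrow = nrow(data))
  list(starts = starts, rms = rms)
}

#' Robust amplitude-artifact correction
#'
#' Sliding-window correction in the spirit of artifact subspace
#' reconstruction's calibration logic: per channel, window RMS values are
#' summarised by their median and the spread between the `q_low` and `q_high`
#' quantiles; windows whose RMS exceeds `median + k * IQR` are scaled down to
#' that robust envelope (tapered at window edges). Clean data passes through
#' essentially unchanged.
#'
#' @param rec an `eeg_record`.
#' @param q_low,q_high quantile pair defining the robust spread of window RMS
#'   (defaults 0.25 / 0.75).
#' @param k spread multiplier for the rejection threshold.
#' @param window_s window length in seconds (50% overlap).
#' @return corrected `eeg_record`; attribute `"windows_corrected"` counts the
#'   channel-windows that were attenuated.
#' @export
artifact_correct <- function(rec, q_low = 0.25, q_high = 0.75, k = 5,
                             window_s = 0.5) {
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1)) {
    stop("need 0 <= q_low < q_high <= 1", call. = FALSE)
  }
  if (ncol(rec$data) < 2L) stop("record is empty or too short", call. = FALSE)
  win <- max(2L, round(window_s * rec$fs_hz))
  hop <- max(1L, win %/% 2L)
  w <- window_rms(rec$data, win, hop)
  out <- rec$data
  n <- ncol(out)
  n_corrected <- 0L
  for (ch in seq_len(nrow(out))) {
    r <- w$rms[ch, ]
    med <- stats::median(r)
    qs <- stats::quantile(r, c(q_low, q_high), names = FALSE)
    thr <- med + k * max(qs[2L] - qs[1L], 1e-12)
    bad <- which(r > thr)
    for (b in bad) {
      s <- w$starts[b]
      e <- min(s + win - 1L, n)
      scale <- thr / r[b]
      # raised-cosine taper so corrected windows blend into neighbours
      len <- e - s + 1L
      taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
      gain <- 1 - (1 - scale) * taper
      out[ch, s:e] <- out[ch, s:e] * pmin(gain, 1)
      n_corrected <- n_corrected + 1L
    }
  }
  rec$data <- out
  attr(rec, "windows_corrected") <- n_corrected
  rec
}

#' Average re-reference
#'
#' Subtracts the across-channel mean at every sample, the reference
#' convention under which microstate templates are defined. Idempotent.
#'
#' @param rec an `eeg_record` (>= 2 channels).
#' @return re-referenced `eeg_record`.
#' @export
average_reference <- function(rec) {
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Full preprocessing pipeline
#'
#' Band-pass filter, then robust amplitude correction, then average
#' re-referencing, in that order. `component_hook` is an optional
#' function(eeg_record) -> eeg_record applied after artifact correction,
#' where ICA-based component cleaning would sit; the default is identity.
#'
#' @param rec an `eeg_record`.
#' @param low_hz,high_hz band-pass edges.
#' @param q_low,q_high,k artifact-correction parameters.
#' @param component_hook optional cleaning callback (default identity).
#' @return preprocessed `eeg_record`.
#' @export
preprocess <- function(rec, low_hz = 0.5, high_hz = 45,
                       q_low = 0.25, q_high = 0.75, k = 5,
                       component_hook = NULL) {
  rec <- band_pass(rec, low_hz, high_hz)
  rec <- artifact_correct(rec, q_low, q_high, k)
  if (!is.null(component_hook)) rec <- component_hook(rec)
  rec <- average_reference(rec)
  if (any(!is.finite(rec$data))) {
    stop("preprocessing produced non-finite values", call. = FALSE)
  }
  rec
}
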