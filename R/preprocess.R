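# Acquisition-chain preprocessing: band-limiting, downsampling, epoching.
# Filters are 4th-order Butterworth applied forward-backward (zero phase),
# matching the 0.5-100 Hz hardware chain the recordings emulate.

# forward-backward filtering with reflection padding so edge transients
# stay outside the returned samples; pad scales with the filter's
# slowest time constant (the lowest corner frequency). The mean is removed
# before filtering (and restored when the filter passes DC) so the
# zero-initial-condition transient is proportional to the fluctuation,
# not the offset.
filtfilt_pad <- function(bf, x, fs, lowest_corner_hz, dc_pass = FALSE) {
  n <- length(x)
  m <- mean(x)
  x <- x - m
  pad <- min(n - 1L, ceiling(6 * fs / lowest_corner_hz))
  ext <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  out <- signal::filtfilt(bf, ext)
  out[(pad + 1L):(pad + n)] + if (dc_pass) m else 0
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`) to every channel. Defaults reproduce the
#' acquisition filters (high-pass 0.5 Hz, low-pass 100 Hz).
#'
#' @param rec an `eeg_recording`.
#' @param hp high-pass corner in Hz.
#' @param lp low-pass corner in Hz.
#' @param order filter order (per pass).
#' @return A filtered `eeg_recording` with unchanged events.
#' @export
bandlimit <- function(rec, hp = 0.5, lp = 100, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(hp > 0 && hp < lp && lp < nyq))
    stop("need 0 < hp < lp < fs/2; got hp = ", hp, ", lp = ", lp,
         ", fs/2 = ", nyq)
  bf <- signal::butter(order, c(hp, lp) / nyq, type = "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- filtfilt_pad(bf, rec$data[ch, ], rec$fs, hp)
  out
}

#' Downsample a recording
#'
#' Anti-alias low-pass (zero-phase Butterworth, cutoff `0.4 * target_fs`)
#' followed by resampling of the filtered signal onto the new uniform time
#' grid by linear interpolation; event markers are remapped to the nearest
#' new sample. Output length is `round(n * target_fs / fs)`.
#'
#' @param rec an `eeg_recording`.
#' @param target_fs new sampling rate in Hz, below `rec$fs`.
#' @param order anti-alias filter order (per pass).
#' @return An `eeg_recording` at `target_fs`.
#' @export
downsample <- function(rec, target_fs, order = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs >= rec$fs)
    stop("target_fs = ", target_fs, " must be below the current rate ", rec$fs)
  n_in <- ncol(rec$data)
  n_out <- round(n_in * target_fs / rec$fs)
  bf <- signal::butter(order, (0.4 * target_fs) / (rec$fs / 2), type = "low")
  t_in <- (seq_len(n_in) - 1) / rec$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  newdata <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    filt <- filtfilt_pad(bf, rec$data[ch, ], rec$fs, 0.4 * target_fs,
                         dc_pass = TRUE)
    newdata[ch, ] <- stats::approx(t_in, filt, xout = t_out, rule = 2)$y
  }
  events <- rec$events
  if (nrow(events)) {
    events$sample <- pmin(n_out, pmax(1L, as.integer(
      round((events$sample - 1L) * target_fs / rec$fs) + 1L)))
  }
  eeg_recording(newdata, fs = target_fs, channel_names = rec$channel_names,
                events = events, meta = rec$meta)
}

#' Epoch a continuous recording on event markers
#'
#' Cuts one trial per event carrying `label`, aligned so that t = 0 is the
#' event sample, over the half-open window `[t_min, t_max)` ms. Events whose
#' window would run outside the recording are dropped; the number dropped is
#' reported via `message()` and attached to the result's `meta$n_dropped`.
#'
#' @param rec an `eeg_recording`.
#' @param label event label to epoch on.
#' @param window_ms length-2 numeric `(t_min, t_max)` in ms with
#'   `t_min < 0 < t_max`.
#' @return An `eeg_epochs` (trials x samples x channels).
#' @export
epoch <- function(rec, label, window_ms) {
  stopifnot(inherits(rec, "eeg_recording"), length(window_ms) == 2,
            window_ms[1] < 0, window_ms[2] > 0)
  onsets <- rec$events$sample[rec$events$label == label]
  if (!length(onsets))
    stop("no events with label '", label, "' in the recording")
  pre <- round(-window_ms[1] / 1000 * rec$fs)
  post <- round(window_ms[2] / 1000 * rec$fs)
  first <- onsets - pre
  last <- onsets + post - 1L
  keep <- first >= 1L & last <= ncol(rec$data)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " event(s) dropped: window outside recording bounds")
  onsets <- onsets[keep]
  if (!length(onsets))
    stop("all events dropped: window [", window_ms[1], ", ", window_ms[2],
         ") ms does not fit the recording")
  n_ch <- nrow(rec$data)
  n_samp <- pre + post
  arr <- array(0, c(length(onsets), n_samp, n_ch))
  for (i in seq_along(onsets)) {
    idx <- (onsets[i] - pre):(onsets[i] + post - 1L)
    arr[i, , ] <- t(rec$data[, idx, drop = FALSE])
  }
  eeg_epochs(arr, fs = rec$fs, window_ms = window_ms,
             channel_names = rec$channel_names,
             trial_meta = data.frame(onset_sample = onsets),
             meta = c(rec$meta, list(n_dropped = n_dropped, label = label)))
}
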