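# Core containers: continuous recordings and epoched trials, plus a
# plain-text on-disk container (CSV data + JSON header + TSV events).

#' Continuous EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param events data.frame with columns `sample` (1-based index) and
#'   `label`; may have zero rows.
#' @param meta named list of subject/paradigm metadata.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          events = NULL, meta = list()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (is.null(channel_names))
    channel_names <- if (!is.null(rownames(data))) rownames(data)
                     else paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  if (is.null(events))
    events <- data.frame(sample = integer(0), label = character(0))
  stopifnot(all(c("sample", "label") %in% names(events)))
  events$sample <- as.integer(events$sample)
  events$label <- as.character(events$label)
  if (nrow(events) && (min(events$sample) < 1 ||
                       max(events$sample) > ncol(data)))
    stop("event sample indices outside the recording")
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Number of samples and duration helpers
#' @param rec an `eeg_recording`.
#' @return `n_samples`: integer; `duration_s`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Epoched trials aligned to stimulus onset
#'
#' @param data numeric array trials x samples x channels (a matrix is taken
#'   as a single channel), in microvolts.
#' @param fs sampling rate in Hz.
#' @param window_ms length-2 numeric `(t_min, t_max)` in ms, `t_min < 0 <
#'   t_max`; the epoch covers the half-open interval `[t_min, t_max)` and
#'   t = 0 is the stimulus onset sample.
#' @param channel_names channel labels.
#' @param trial_meta data.frame with one row per trial, or NULL.
#' @param meta named list.
#' @return An object of class `eeg_epochs` with a `times_ms` axis.
#' @export
eeg_epochs <- function(data, fs, window_ms, channel_names = NULL,
                       trial_meta = NULL, meta = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3, fs > 0, length(window_ms) == 2,
            window_ms[1] < 0, window_ms[2] > 0)
  n_samp <- dim(data)[2]
  expected <- round((window_ms[2] - window_ms[1]) / 1000 * fs)
  if (abs(n_samp - expected) > 1)
    stop("data has ", n_samp, " samples but window ", window_ms[1], "..",
         window_ms[2], " ms at ", fs, " Hz implies ", expected)
  t0 <- round(-window_ms[1] / 1000 * fs)  # samples before onset
  times_ms <- (seq_len(n_samp) - 1 - t0) / fs * 1000
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[3]))
  structure(list(data = data, fs = fs, window_ms = window_ms,
                 times_ms = times_ms, channel_names = channel_names,
                 trial_meta = trial_meta, meta = meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d samples x %d channel(s) @ %g Hz, window [%g, %g) ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `eeg_epochs`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

# ---- plain-text container -------------------------------------------------

#' Write / read a recording as a plain-text container
#'
#' Stores a continuous recording as three sidecar files sharing a stem:
#' `<stem>.csv` (samples x channels, microvolts), `<stem>.json` (sampling
#' rate, channel names, metadata) and `<stem>.events.tsv` (columns `sample`,
#' `label`). Events round-trip exactly; sample values round-trip within
#' the precision of decimal text representation (~15 significant digits).
#'
#' @param rec an `eeg_recording`.
#' @param stem path stem without extension.
#' @return `write_recording()` returns `stem` invisibly; `read_recording()`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  header <- list(fs = rec$fs, channel_names = rec$channel_names,
                 units = "uV", meta = rec$meta)
  jsonlite::write_json(header, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(rec$events, paste0(stem, ".events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  ev_path <- paste0(stem, ".events.tsv")
  events <- if (file.exists(ev_path))
    utils::read.table(ev_path, header = TRUE, sep = "\t",
                      colClasses = c("integer", "character"))
  else NULL
  meta <- header$meta
  if (is.null(meta)) meta <- list()
  eeg_recording(t(as.matrix(df)), fs = header$fs,
                channel_names = header$channel_names,
                events = events, meta = as.list(meta))
}

#' Read a delimited event file
#'
#' Accepts either `onset_s` or `sample` as the time column and converts to
#' sample indices for a given sampling rate.
#'
#' @param path tab- or comma-separated file with a `label` column and one of
#'   `onset_s` / `sample`.
#' @param fs sampling rate used to convert `onset_s` to sample indices.
#' @return data.frame with columns `sample`, `label`.
#' @export
read_event_file <- function(path, fs) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if ("sample" %in% names(df)) {
    s <- as.integer(df$sample)
  } else if ("onset_s" %in% names(df)) {
    s <- as.integer(round(df$onset_s * fs)) + 1L
  } else stop("event file needs an 'onset_s' or 'sample' column")
  data.frame(sample = s, label = as.character(df$label))
}
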