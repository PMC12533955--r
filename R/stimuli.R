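# Auditory stimulus envelopes and event schedules for the three paradigms:
# broadband-noise burst trains (ERP/STP), 40 Hz click trains (ASSR), and the
# 1-100 Hz upsweep chirp. Only modulation envelopes and event times are
# modelled; the acoustic carrier is irrelevant for EEG simulation.

#' Stimulus specification
#'
#' Describes one of the three auditory paradigms used by the pipeline. The
#' defaults are the stimulus parameters of the mouse EEG protocol this
#' package implements: trains of ten 100 ms broadband-noise bursts at 1 or
#' 2 Hz with 8 s between trains, 1 s click trains at 40 Hz repeated 200
#' times, and a 2 s noise stimulus amplitude-modulated by a linear 1 to
#' 100 Hz upsweep repeated 300 times.
#'
#' @param kind one of `"bbn_train"`, `"assr"`, `"chirp"`.
#' @param ... kind-specific overrides, see Details.
#'
#' @details Kind-specific parameters (with defaults):
#' \describe{
#'   \item{bbn_train}{`burst_ms = 100`, `rise_fall_ms = 5`, `rate_hz = 1`
#'     (1 or 2), `bursts_per_train = 10`, `n_trains = 100`,
#'     `inter_train_s = 8` (anchored at last-burst offset).}
#'   \item{assr}{`click_rate_hz = 40`, `train_s = 1`, `n_trains = 200`.}
#'   \item{chirp}{`f_start_hz = 1`, `f_end_hz = 100`, `sweep_s = 2`,
#'     `n_reps = 300`.}
#' }
#'
#' @return An object of class `stimulus_spec`: a list with `kind` and the
#'   resolved parameters.
#' @export
#' @examples
#' stimulus_spec("assr")
#' stimulus_spec("chirp", f_end_hz = 80)
stimulus_spec <- function(kind = c("bbn_train", "assr", "chirp"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    bbn_train = list(burst_ms = 100, rise_fall_ms = 5, rate_hz = 1,
                     bursts_per_train = 10, n_trains = 100, inter_train_s = 8),
    assr = list(click_rate_hz = 40, train_s = 1, n_trains = 200),
    chirp = list(f_start_hz = 1, f_end_hz = 100, sweep_s = 2, n_reps = 300))
  params <- modifyList(defaults, list(...))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  if (kind == "chirp") {
    stopifnot(params$sweep_s > 0, params$f_start_hz > 0,
              params$n_reps >= 1)
    if (params$f_end_hz < params$f_start_hz)
      stop("f_end_hz must be >= f_start_hz")
  }
  if (kind == "assr")
    stopifnot(params$click_rate_hz > 0, params$train_s > 0,
              params$n_trains >= 1)
  if (kind == "bbn_train")
    stopifnot(params$burst_ms > 0, params$rate_hz > 0,
              params$bursts_per_train >= 1, params$n_trains >= 1,
              params$inter_train_s >= 0)
  structure(c(list(kind = kind), params), class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec>", x$kind, "\n")
  p <- x[setdiff(names(x), "kind")]
  cat(paste0("  ", names(p), " = ", unlist(p), collapse = "\n"), "\n")
  invisible(x)
}

#' Chirp amplitude-modulation envelope
#'
#' Raised-cosine envelope `e(t) = (1 - cos(phi(t))) / 2` whose instantaneous
#' modulation frequency sweeps linearly from `f_start_hz` to `f_end_hz` over
#' the sweep duration, i.e. `phi(t) = 2*pi*(f0*t + (f1 - f0)*t^2 / (2*T))`.
#' Modulation depth is 100% and the envelope starts at 0.
#'
#' @param spec a `stimulus_spec` of kind `"chirp"`.
#' @param fs sampling rate in Hz; must be at least twice `f_end_hz`.
#' @return Numeric vector of `round(sweep_s * fs)` samples in `[0, 1]`, with
#'   the modulation phase (radians) attached as attribute `"phase"` and the
#'   instantaneous modulation frequency (Hz) as `"inst_freq"`.
#' @export
#' @examples
#' env <- make_chirp_envelope(stimulus_spec("chirp"), fs = 1024)
#' range(env)
make_chirp_envelope <- function(spec, fs) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$kind != "chirp") stop("spec must have kind 'chirp'")
  f0 <- spec$f_start_hz; f1 <- spec$f_end_hz; T <- spec$sweep_s
  if (fs < 2 * f1)
    stop("fs = ", fs, " Hz is below the Nyquist rate for the ", f1,
         " Hz end of the modulation sweep; need fs >= ", 2 * f1)
  n <- round(T * fs)
  t <- (seq_len(n) - 1) / fs  # sample instants t = 0 .. T - 1/fs
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * T))
  env <- 0.5 * (1 - cos(phase))
  attr(env, "phase") <- phase
  attr(env, "inst_freq") <- f0 + (f1 - f0) * t / T
  attr(env, "fs") <- fs
  env
}

#' Click-train envelope for the auditory steady-state response
#'
#' Rectangular clicks of `click_ms` duration at exactly `click_rate_hz` for
#' `train_s` seconds.
#'
#' @param spec a `stimulus_spec` of kind `"assr"`.
#' @param fs sampling rate in Hz.
#' @param click_ms click width in ms; must leave a gap between clicks.
#' @return Numeric 0/1 vector of `round(train_s * fs)` samples; click onset
#'   sample indices (1-based) attached as attribute `"onsets"`.
#' @export
#' @examples
#' env <- make_click_train(stimulus_spec("assr"), fs = 1024)
#' length(attr(env, "onsets"))  # 40 clicks in 1 s at 40 Hz
make_click_train <- function(spec, fs, click_ms = 1) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$kind != "assr") stop("spec must have kind 'assr'")
  if (click_ms >= 1000 / spec$click_rate_hz)
    stop("click_ms = ", click_ms, " overlaps the next click at ",
         spec$click_rate_hz, " Hz (period ", 1000 / spec$click_rate_hz, " ms)")
  n <- round(spec$train_s * fs)
  env <- numeric(n)
  n_clicks <- round(spec$click_rate_hz * spec$train_s)
  onset_t <- (seq_len(n_clicks) - 1) / spec$click_rate_hz
  onsets <- round(onset_t * fs) + 1L
  width <- max(1L, round(click_ms / 1000 * fs))
  for (o in onsets) {
    idx <- o:min(n, o + width - 1L)
    env[idx] <- 1
  }
  attr(env, "onsets") <- onsets
  attr(env, "fs") <- fs
  env
}

#' Burst-onset schedule for broadband-noise trains
#'
#' Onset times for every noise burst, grouped by train. Within a train
#' onsets are spaced `1/rate_hz` apart; consecutive trains are separated by
#' `inter_train_s` measured from the offset of the last burst of one train
#' to the first onset of the next.
#'
#' @param spec a `stimulus_spec` of kind `"bbn_train"`.
#' @return A data.frame with columns `train` (1-based), `burst` (1-based
#'   within train) and `onset_s`.
#' @export
#' @examples
#' sched <- make_bbn_schedule(stimulus_spec("bbn_train", rate_hz = 2))
#' diff(sched$onset_s[1:3])  # 0.5 s spacing at 2 Hz
make_bbn_schedule <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$kind != "bbn_train") stop("spec must have kind 'bbn_train'")
  period <- 1 / spec$rate_hz
  within <- (seq_len(spec$bursts_per_train) - 1) * period
  # train length from first onset to last-burst offset
  train_len <- within[length(within)] + spec$burst_ms / 1000
  starts <- (seq_len(spec$n_trains) - 1) * (train_len + spec$inter_train_s)
  data.frame(
    train = rep(seq_len(spec$n_trains), each = spec$bursts_per_train),
    burst = rep(seq_len(spec$bursts_per_train), times = spec$n_trains),
    onset_s = rep(starts, each = spec$bursts_per_train) + rep(within, spec$n_trains))
}

#' Write an event schedule as a two-column delimited file
#'
#' @param onsets_s numeric vector of onset times in seconds.
#' @param labels character vector (recycled) of event labels.
#' @param path output path (tab-separated, columns `onset_s`, `label`).
#' @return `path`, invisibly.
#' @export
write_event_schedule <- function(onsets_s, labels, path) {
  df <- data.frame(onset_s = onsets_s,
                   label = rep_len(as.character(labels), length(onsets_s)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
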