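# Morlet-wavelet time-frequency decomposition, inter-trial phase coherence
# (ITPC) and baseline-corrected single-trial power (STP).
#
# The wavelet is the unit-energy complex Morlet
#   psi_f(t) = (sigma_t * sqrt(pi))^(-1/2) * exp(-t^2 / (2 sigma_t^2)) * exp(i 2 pi f t)
# with sigma_t = m / (2 pi f) for m cycles. m = 10 is the analysis default,
# trading temporal resolution for a narrow spectral response
# (sigma_f = f / m).

#' Morlet wavelet bank
#'
#' @param freqs center frequencies in Hz; default 100 layers linearly
#'   spaced from 1 to 100 Hz.
#' @param cycles Morlet parameter m (number of cycles); `sigma_t = m /
#'   (2 pi f)`.
#' @param fs sampling rate of the data the bank will be applied to.
#' @return An object of class `morlet_bank`.
#' @export
morlet_bank <- function(freqs = seq(1, 100, length.out = 100), cycles = 10,
                        fs = 1024) {
  stopifnot(cycles > 0, all(freqs > 0), all(diff(freqs) > 0), fs > 0)
  structure(list(freqs = freqs, cycles = cycles, fs = fs),
            class = "morlet_bank")
}

#' @export
print.morlet_bank <- function(x, ...) {
  cat(sprintf("<morlet_bank> %d layers %g-%g Hz, m = %g cycles, fs = %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$cycles, x$fs))
  invisible(x)
}

# sampled unit-energy Morlet wavelet, support +/- half_support_sigmas sigma_t
sample_morlet <- function(f, cycles, fs, half_support_sigmas = 6) {
  sigma_t <- cycles / (2 * pi * f)
  half_n <- ceiling(half_support_sigmas * sigma_t * fs)
  t <- (-half_n:half_n) / fs
  psi <- (sigma_t * sqrt(pi))^(-0.5) * exp(-t^2 / (2 * sigma_t^2)) *
    exp(1i * 2 * pi * f * t)
  # discrete unit-energy normalization (sum |psi|^2 / fs = 1)
  psi / sqrt(sum(Mod(psi)^2) / fs)
}

#' Morlet time-frequency decomposition of epoched data
#'
#' Convolves every trial with each wavelet of the bank (FFT convolution
#' with reflection padding) and returns per-trial complex coefficients.
#' Samples closer to an epoch edge than half the wavelet support
#' (3 sigma_t) are flagged unreliable in `edge_mask` and should be
#' excluded from statistics. Low-frequency layers whose edge zones cover
#' the whole epoch (for the 10-cycle 1 Hz wavelet that is any epoch under
#' ~9.5 s) are still computed but come back fully masked; a message
#' reports how many. The epoch is rejected only when even the
#' highest-frequency layer has no reliable sample.
#'
#' @param epochs an `eeg_epochs`.
#' @param bank a `morlet_bank` with `fs` matching the epochs.
#' @param channel channel index to decompose.
#' @return An object of class `tf_coeffs`: list with `values` (complex
#'   array trials x freqs x time), `freqs`, `times_ms`, `fs`, `edge_mask`
#'   (freqs x time logical, TRUE = unreliable), `trial_meta`, `meta`.
#' @export
morlet_tfr <- function(epochs, bank, channel = 1L) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(bank, "morlet_bank"))
  if (abs(bank$fs - epochs$fs) > 1e-9)
    stop("bank fs (", bank$fs, ") does not match epoch fs (", epochs$fs, ")")
  n_samp <- dim(epochs$data)[2]
  fs <- epochs$fs
  sigma_t <- bank$cycles / (2 * pi * bank$freqs)
  mask_w <- ceiling(3 * sigma_t * fs)  # unreliable zone at each edge
  if (n_samp <= 2 * min(mask_w))
    stop("epoch too short: even the ", max(bank$freqs), " Hz layer has no ",
         "reliable samples; need more than ", 2 * min(mask_w),
         " samples (", round(2 * min(mask_w) / fs, 3), " s), have ", n_samp)
  n_fully_masked <- sum(2 * mask_w >= n_samp)
  if (n_fully_masked > 0)
    message(n_fully_masked, " low-frequency layer(s) fully edge-masked ",
            "(epoch of ", n_samp, " samples; the ", min(bank$freqs),
            " Hz layer needs more than ", 2 * max(mask_w),
            " for reliable interior samples)")
  n_tr <- dim(epochs$data)[1]
  n_f <- length(bank$freqs)
  # reflection padding (capped at the epoch length) for the widest wavelet
  sigma_low <- max(sigma_t)
  pad <- min(n_samp - 1L, ceiling(6 * sigma_low * fs))
  n_ext <- n_samp + 2L * pad
  half_len <- ceiling(6 * sigma_t * fs)  # wavelets sampled on +/- 6 sigma_t
  n_fft <- stats::nextn(n_ext + 2L * max(half_len), c(2, 3, 5))
  # precompute wavelet spectra on the common FFT grid
  wav_fft <- matrix(0i, n_f, n_fft)
  for (k in seq_len(n_f)) {
    psi <- sample_morlet(bank$freqs[k], bank$cycles, fs)
    half_len[k] <- (length(psi) - 1L) / 2L
    buf <- complex(length.out = n_fft)
    buf[seq_along(psi)] <- psi
    wav_fft[k, ] <- fft(buf)
  }
  # batched FFT convolution: trials as columns of one matrix
  idx_ext <- c(rev(2:(pad + 1L)), seq_len(n_samp),
               rev((n_samp - pad):(n_samp - 1L)))
  ext_mat <- matrix(0, n_fft, n_tr)
  xm <- epochs$data[, idx_ext, channel]
  if (is.null(dim(xm))) xm <- matrix(xm, nrow = 1)
  ext_mat[seq_len(n_ext), ] <- t(xm)
  xf <- stats::mvfft(ext_mat)
  vals <- array(0i, c(n_tr, n_f, n_samp))
  for (k in seq_len(n_f)) {
    conv <- stats::mvfft(xf * wav_fft[k, ], inverse = TRUE) / n_fft
    # 'same' alignment: wavelet center at half_len offset, skip padding
    start <- pad + half_len[k] + 1L
    vals[, k, ] <- t(conv[start:(start + n_samp - 1L), , drop = FALSE]) / fs
  }
  edge_mask <- matrix(FALSE, n_f, n_samp)
  for (k in seq_len(n_f)) {
    w <- min(mask_w[k], n_samp)
    edge_mask[k, seq_len(w)] <- TRUE
    edge_mask[k, (n_samp - w + 1L):n_samp] <- TRUE
  }
  structure(list(values = vals, freqs = bank$freqs,
                 times_ms = epochs$times_ms, fs = fs,
                 edge_mask = edge_mask, trial_meta = epochs$trial_meta,
                 meta = epochs$meta),
            class = "tf_coeffs")
}

#' @export
print.tf_coeffs <- function(x, ...) {
  cat(sprintf("<tf_coeffs> %d trials x %d freqs x %d samples\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

# shared constructor for real-valued time-frequency grids
tf_grid <- function(values, freqs, times_ms, content, edge_mask = NULL,
                    meta = list()) {
  structure(list(values = values, freqs = freqs, times_ms = times_ms,
                 content = content, edge_mask = edge_mask, meta = meta),
            class = "tf_grid")
}

#' @export
print.tf_grid <- function(x, ...) {
  cat(sprintf("<tf_grid:%s> %d freqs x %d time points\n", x$content,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Inter-trial phase coherence
#'
#' `ITPC(f, t) = | mean_n W_n(f, t) / |W_n(f, t)| |`: the resultant length
#' of the per-trial unit phase vectors. 1 = identical phase across trials;
#' for N trials of uniform random phase the expected value is
#' `sqrt(pi) / (2 sqrt(N))`. Zero-magnitude coefficients are excluded from
#' the mean at that (f, t); the number excluded is reported in
#' `meta$n_zero_excluded`.
#'
#' @param coeffs a `tf_coeffs` from [morlet_tfr()] (needs >= 2 trials).
#' @return A `tf_grid` with `content = "itpc"`, values in [0, 1].
#' @export
compute_itpc <- function(coeffs) {
  stopifnot(inherits(coeffs, "tf_coeffs"))
  n_tr <- dim(coeffs$values)[1]
  if (n_tr < 2) stop("ITPC needs at least 2 trials")
  mag <- Mod(coeffs$values)
  zero <- mag == 0
  unit <- coeffs$values
  unit[!zero] <- unit[!zero] / mag[!zero]
  unit[zero] <- 0i
  n_eff <- n_tr - colSums(zero, dims = 1)  # freqs x time counts
  resultant <- colSums(unit, dims = 1)
  itpc <- matrix(0, dim(coeffs$values)[2], dim(coeffs$values)[3])
  ok <- n_eff > 0
  itpc[ok] <- Mod(resultant[ok]) / n_eff[ok]
  itpc <- pmin(itpc, 1)
  tf_grid(itpc, coeffs$freqs, coeffs$times_ms, "itpc",
          edge_mask = coeffs$edge_mask,
          meta = c(coeffs$meta, list(n_trials = n_tr,
                                     n_zero_excluded = sum(zero))))
}

#' Baseline-corrected single-trial power
#'
#' Per trial, power `P(f, t) = |W(f, t)|^2`; the mean power over the
#' baseline window (default [-250, -150) ms, half-open) is subtracted per
#' frequency layer from the whole trial, then the corrected trials are
#' averaged with equal weights. By construction the baseline-window mean of
#' the result is zero at every frequency.
#'
#' @param coeffs a `tf_coeffs` from [morlet_tfr()].
#' @param baseline_ms length-2 numeric, baseline window in ms (half-open).
#' @return A `tf_grid` with `content = "stp"` (uV^2).
#' @export
compute_stp <- function(coeffs, baseline_ms = c(-250, -150)) {
  stopifnot(inherits(coeffs, "tf_coeffs"), length(baseline_ms) == 2,
            baseline_ms[1] < baseline_ms[2])
  bl <- coeffs$times_ms >= baseline_ms[1] - 1e-9 &
    coeffs$times_ms < baseline_ms[2] - 1e-9
  if (!any(bl))
    stop("baseline window [", baseline_ms[1], ", ", baseline_ms[2],
         ") ms is outside the epoch (", min(coeffs$times_ms), " to ",
         max(coeffs$times_ms), " ms)")
  p <- Mod(coeffs$values)^2  # trials x freqs x time
  base <- rowMeans(p[, , bl, drop = FALSE], dims = 2)  # trials x freqs
  corrected <- sweep(p, c(1, 2), base, "-")
  stp <- colMeans(corrected, dims = 1)
  tf_grid(stp, coeffs$freqs, coeffs$times_ms, "stp",
          edge_mask = coeffs$edge_mask,
          meta = c(coeffs$meta, list(n_trials = dim(p)[1],
                                     baseline_ms = baseline_ms)))
}

#' Evoked ITPC and STP without materializing all trials
#'
#' Streams trials through [morlet_tfr()] in chunks and accumulates the
#' sufficient statistics for ITPC (sum of unit phasors) and STP (sum of
#' per-trial baseline-corrected power), so the full trials x freqs x time
#' complex array never needs to be held in memory. Results are identical
#' to [compute_itpc()] / [compute_stp()] on the full coefficient array.
#'
#' @param epochs an `eeg_epochs`.
#' @param bank a `morlet_bank`.
#' @param measures character subset of `c("itpc", "stp")`.
#' @param baseline_ms STP baseline window (half-open, ms).
#' @param channel channel index.
#' @param chunk_trials trials per chunk.
#' @return Named list of `tf_grid` objects (one per requested measure).
#' @export
evoked_measures <- function(epochs, bank, measures = c("itpc", "stp"),
                            baseline_ms = c(-250, -150), channel = 1L,
                            chunk_trials = 32L) {
  measures <- match.arg(measures, several.ok = TRUE)
  n_tr <- dim(epochs$data)[1]
  acc_phasor <- NULL; acc_power <- NULL; acc_base <- NULL
  n_zero <- 0L
  edge_mask <- NULL; freqs <- NULL; times_ms <- NULL
  bl <- NULL
  for (start in seq(1, n_tr, by = chunk_trials)) {
    idx <- start:min(n_tr, start + chunk_trials - 1L)
    sub <- epochs
    sub$data <- epochs$data[idx, , , drop = FALSE]
    sub$trial_meta <- NULL
    co <- suppressMessages(morlet_tfr(sub, bank, channel))
    if (is.null(edge_mask)) {
      edge_mask <- co$edge_mask; freqs <- co$freqs; times_ms <- co$times_ms
      bl <- times_ms >= baseline_ms[1] - 1e-9 & times_ms < baseline_ms[2] - 1e-9
      if ("stp" %in% measures && !any(bl))
        stop("baseline window outside the epoch")
      d <- dim(co$values)[2:3]
      acc_phasor <- matrix(0i, d[1], d[2])
      acc_power <- matrix(0, d[1], d[2])
      acc_base <- numeric(d[1])
    }
    if ("itpc" %in% measures) {
      mag <- Mod(co$values)
      zero <- mag == 0
      n_zero <- n_zero + sum(zero)
      unit <- co$values
      unit[!zero] <- unit[!zero] / mag[!zero]
      unit[zero] <- 0i
      acc_phasor <- acc_phasor + colSums(unit, dims = 1)
    }
    if ("stp" %in% measures) {
      p <- Mod(co$values)^2
      acc_power <- acc_power + colSums(p, dims = 1)
      acc_base <- acc_base + colSums(rowMeans(p[, , bl, drop = FALSE],
                                              dims = 2))
    }
  }
  out <- list()
  if ("itpc" %in% measures)
    out$itpc <- tf_grid(pmin(Mod(acc_phasor) / n_tr, 1), freqs, times_ms,
                        "itpc", edge_mask = edge_mask,
                        meta = c(epochs$meta,
                                 list(n_trials = n_tr,
                                      n_zero_excluded = n_zero)))
  if ("stp" %in% measures)
    out$stp <- tf_grid(acc_power / n_tr - acc_base / n_tr, freqs, times_ms,
                       "stp", edge_mask = edge_mask,
                       meta = c(epochs$meta,
                                list(n_trials = n_tr,
                                     baseline_ms = baseline_ms)))
  out
}
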