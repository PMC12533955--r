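# Resting-state power spectral density on a 0.5 Hz grid and canonical band
# binning. The estimator follows the acquisition-software convention:
# non-overlapping 2 s segments, each tapered by a Tukey window whose
# tapered (Hann-edged) portion totals 10% of the segment, one-sided
# periodograms in uV^2/Hz with window power correction, averaged.

#' Tukey (tapered-cosine) window
#'
#' `taper_fraction` is the total fraction of the window occupied by the two
#' cosine ramps together (half at each end); `taper_fraction = 1` gives a
#' full Hann window, `0` a rectangular window.
#'
#' @param n window length in samples.
#' @param taper_fraction total tapered fraction in [0, 1].
#' @return Numeric vector of length `n` in [0, 1].
#' @export
tukey_window <- function(n, taper_fraction = 0.1) {
  stopifnot(n >= 1, taper_fraction >= 0, taper_fraction <= 1)
  if (taper_fraction == 0) return(rep(1, n))
  w <- rep(1, n)
  x <- (seq_len(n) - 1) / (n - 1)
  a <- taper_fraction
  left <- x < a / 2
  right <- x > 1 - a / 2
  w[left] <- 0.5 * (1 + cos(pi * (2 * x[left] / a - 1)))
  w[right] <- 0.5 * (1 + cos(pi * (2 * (1 - x[right]) / a - 1)))
  w
}

#' Resting power spectral density
#'
#' Splits each channel into non-overlapping segments of `segment_s`
#' seconds, tapers each with a Tukey window (`taper_fraction` total taper),
#' computes one-sided periodograms scaled to uV^2/Hz with window power
#' correction (`sum(w^2)`), and averages across segments. With the default
#' 2 s segments the frequency grid has exactly 0.5 Hz resolution; the
#' density is returned on the 0.5-100 Hz grid.
#'
#' @param rec an `eeg_recording` (microvolts).
#' @param segment_s segment length in seconds.
#' @param taper_fraction total Tukey taper fraction (0.1 = "10% Hanning";
#'   1 = full Hann).
#' @param fmax highest frequency retained (Hz).
#' @return An object of class `eeg_psd`: list with `freqs` (Hz), `density`
#'   (freq x channel matrix, uV^2/Hz), `n_segments`, `df` (bin width),
#'   `channel_names`, `meta`.
#' @export
resting_psd <- function(rec, segment_s = 2, taper_fraction = 0.1,
                        fmax = 100) {
  stopifnot(inherits(rec, "eeg_recording"), segment_s > 0)
  nseg_len <- round(segment_s * rec$fs)
  n_seg <- floor(ncol(rec$data) / nseg_len)
  if (n_seg < 1)
    stop("recording (", ncol(rec$data), " samples) shorter than one ",
         segment_s, " s segment (", nseg_len, " samples)")
  w <- tukey_window(nseg_len, taper_fraction)
  u <- sum(w^2)  # window power correction
  df <- 1 / segment_s
  nf <- floor(nseg_len / 2)
  freqs_all <- (1:nf) * df
  keep <- freqs_all <= fmax + 1e-9
  freqs <- freqs_all[keep]
  dens <- matrix(0, length(freqs), nrow(rec$data))
  for (ch in seq_len(nrow(rec$data))) {
    acc <- numeric(length(freqs))
    for (s in seq_len(n_seg)) {
      seg <- rec$data[ch, ((s - 1) * nseg_len + 1):(s * nseg_len)]
      X <- fft(w * seg)
      # one-sided density: double all bins except DC and Nyquist
      p <- (Mod(X[2:(nf + 1)])^2) / (rec$fs * u)
      p <- p * 2
      if (nseg_len %% 2 == 0) p[nf] <- p[nf] / 2
      acc <- acc + p[keep]
    }
    dens[, ch] <- acc / n_seg
  }
  structure(list(freqs = freqs, density = dens, n_segments = n_seg,
                 df = df, channel_names = rec$channel_names,
                 meta = rec$meta),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d bins (%g-%g Hz, df = %g), %d channel(s), %d segments\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$df,
              ncol(x$density), x$n_segments))
  invisible(x)
}

#' Canonical EEG band definitions
#'
#' Theta 4-8, alpha 8-13, beta 13-30, low gamma 30-55 and high gamma
#' 65-100 Hz. Intervals are half-open `[lo, hi)` except high gamma, which
#' is closed at 100 Hz; the 55-65 Hz region (power-line vicinity) belongs
#' to no band.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
canonical_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
       low_gamma = c(30, 55), high_gamma = c(65, 100))
}

#' Bin a power spectral density into canonical bands
#'
#' Band power is the mean density (uV^2/Hz) over the bins with
#' `lo <= f < hi` (high gamma includes the 100 Hz bin).
#'
#' @param psd an `eeg_psd`.
#' @param bands named list of `c(lo, hi)` pairs.
#' @param subject,genotype,treatment,movement_fraction optional label
#'   columns copied into every row (taken from `psd$meta` when NULL).
#' @return data.frame with columns `subject`, `channel`, `band`, `power`,
#'   `genotype`, `treatment`, `movement_fraction` (one row per band x
#'   channel).
#' @export
bin_bands <- function(psd, bands = canonical_bands(), subject = NULL,
                      genotype = NULL, treatment = NULL,
                      movement_fraction = NULL) {
  stopifnot(inherits(psd, "eeg_psd"))
  if (max(psd$freqs) < 100 - 1e-9 || min(psd$freqs) > 4)
    stop("frequency grid must cover 4-100 Hz")
  grab <- function(x, key, default = NA) {
    if (!is.null(x)) x
    else if (!is.null(psd$meta[[key]])) psd$meta[[key]]
    else default
  }
  subject <- grab(subject, "subject", "s1")
  genotype <- grab(genotype, "group")
  treatment <- grab(treatment, "treatment")
  movement_fraction <- grab(movement_fraction, "movement_fraction")
  hi_band <- names(bands)[vapply(bands, function(b) b[2] >= 100, logical(1))]
  rows <- lapply(seq_along(psd$channel_names), function(ch) {
    pw <- vapply(names(bands), function(bn) {
      b <- bands[[bn]]
      sel <- psd$freqs >= b[1] - 1e-9 &
        (if (bn %in% hi_band) psd$freqs <= b[2] + 1e-9
         else psd$freqs < b[2] - 1e-9)
      mean(psd$density[sel, ch])
    }, numeric(1))
    data.frame(subject = subject, channel = psd$channel_names[ch],
               band = names(bands), power = unname(pw),
               genotype = genotype, treatment = treatment,
               movement_fraction = movement_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-band group power ratio
#'
#' Ratio of group mean band power (numerator / denominator) per band and
#' channel; 1 means equal power.
#'
#' @param table a band-power data.frame as returned by [bin_bands()]
#'   (rows from several subjects combined).
#' @param numerator_group,denominator_group values of `group_col` defining
#'   the two groups.
#' @param group_col column holding group labels (default `"genotype"`).
#' @return data.frame with columns `channel`, `band`, `ratio`.
#' @export
group_ratio <- function(table, numerator_group, denominator_group,
                        group_col = "genotype") {
  num <- table[table[[group_col]] == numerator_group, ]
  den <- table[table[[group_col]] == denominator_group, ]
  if (!nrow(num) || !nrow(den))
    stop("one of the groups has no rows")
  agg <- function(d) aggregate(power ~ channel + band, d, mean)
  a <- agg(num); b <- agg(den)
  m <- merge(a, b, by = c("channel", "band"), suffixes = c("_num", "_den"))
  if (any(m$power_den == 0))
    warning("zero denominator band power; ratio set to NA")
  m$ratio <- ifelse(m$power_den == 0, NA_real_, m$power_num / m$power_den)
  m[, c("channel", "band", "ratio")]
}

#' Write a PSD or band table to CSV
#'
#' @param x an `eeg_psd` or a band-power data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_psd_csv <- function(x, path) {
  if (inherits(x, "eeg_psd")) {
    df <- data.frame(freq = rep(x$freqs, ncol(x$density)),
                     channel = rep(x$channel_names, each = length(x$freqs)),
                     density = as.vector(x$density))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
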