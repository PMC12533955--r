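# Calibration utilities: estimate the realized family-wise error rate of
# the cluster permutation test on repeated null simulations, at a reduced
# problem scale so the estimate is affordable on one CPU.

#' Family-wise error rate of the cluster test under the null
#'
#' Repeatedly simulates two groups of subjects from the *same* generating
#' distribution (1/f background plus a stimulus-evoked response identical
#' in both groups), computes each subject's binned time-frequency summary
#' (baseline-corrected single-trial power by default), runs the cluster
#' permutation test, and records whether any cluster is flagged
#' significant in each direction. Under a correctly calibrated test the
#' per-direction rate is at most `alpha_per_tail`.
#'
#' The default scale (8 + 8 subjects, 12 trials each, 256 Hz sampling, 30
#' wavelet layers from 10 to 100 Hz, 30 x 64 binned grids, 500
#' permutations) is a reduced version of the canonical 100 x 256 / 2000
#' permutation analysis chosen so that several hundred repetitions run in
#' minutes; the statistic and its calibration are scale-free.
#'
#' @param n_reps number of independent null simulations.
#' @param seed master seed; per-repetition seeds are derived from it.
#' @param n_subjects subjects per group.
#' @param n_trials evoked trials per subject.
#' @param fs simulation sampling rate (Hz).
#' @param wavelet_freqs wavelet center frequencies (Hz).
#' @param n_time_bins time bins of the cluster-test matrix.
#' @param n_perm label permutations per test.
#' @param alpha_per_tail per-direction significance level.
#' @param measure `"stp"` or `"itpc"` subject summary.
#' @param noise_sd per-trial background SD (uV).
#' @param progress print a dot every 50 repetitions.
#' @return List with `rate_pos`, `rate_neg` (realized per-direction FWER),
#'   `flagged_pos`, `flagged_neg` (logical per repetition), and the
#'   settings used.
#' @export
cluster_test_fwer <- function(n_reps = 400, seed = 1, n_subjects = 8,
                              n_trials = 12, fs = 256,
                              wavelet_freqs = seq(10, 100, length.out = 30),
                              n_time_bins = 64, n_perm = 500,
                              alpha_per_tail = 0.025,
                              measure = c("stp", "itpc"), noise_sd = 8,
                              progress = FALSE) {
  measure <- match.arg(measure)
  spec <- stimulus_spec("bbn_train", n_trains = n_trials)
  window_ms <- c(-500, 1000)
  flagged_pos <- logical(n_reps)
  flagged_neg <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- (as.numeric(seed) * 1000 + r) %% 2147483647
    grids <- vector("list", 2L * n_subjects)
    emask <- NULL
    for (s in seq_len(2L * n_subjects)) {
      cfg <- sim_config(seed = rep_seed, fs = fs, broadband_sd = noise_sd)
      ep <- simulate_evoked(cfg, spec, subject = s, window_ms = window_ms,
                            noise_sd = noise_sd)
      bank <- morlet_bank(wavelet_freqs, cycles = 10, fs = fs)
      coeffs <- morlet_tfr(ep, bank)
      grid <- if (measure == "stp") compute_stp(coeffs)
              else compute_itpc(coeffs)
      b <- bin_tf(grid, n_time_bins)
      if (is.null(emask)) emask <- attr(b, "edge_mask")
      grids[[s]] <- unclass(b)
    }
    res <- cluster_permutation_test(
      grids[seq_len(n_subjects)], grids[n_subjects + seq_len(n_subjects)],
      n_perm = n_perm, alpha_per_tail = alpha_per_tail,
      seed = rep_seed + 7, mask = emask)
    cl <- res$clusters
    flagged_pos[r] <- any(cl$significant[cl$direction == "pos"])
    flagged_neg[r] <- any(cl$significant[cl$direction == "neg"])
    if (progress && r %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(rate_pos = mean(flagged_pos), rate_neg = mean(flagged_neg),
       flagged_pos = flagged_pos, flagged_neg = flagged_neg,
       n_reps = n_reps, n_perm = n_perm, alpha_per_tail = alpha_per_tail,
       n_subjects = n_subjects, n_trials = n_trials, fs = fs,
       measure = measure, seed = seed)
}
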