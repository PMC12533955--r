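# PSD estimator (Parseval and tone calibration), band binning, ratios.

test_that("a pure tone's power concentrates in its 0.5 Hz bin at A^2/2", {
  fs <- 1024
  t <- (0:(fs * 20 - 1)) / fs
  rec <- eeg_recording(matrix(2 * sin(2 * pi * 10 * t), 1), fs)
  psd <- resting_psd(rec)
  expect_equal(psd$df, 0.5)
  expect_equal(psd$n_segments, 10)
  peak <- which.max(psd$density[, 1])
  expect_equal(psd$freqs[peak], 10)
  # total tone power (A^2/2 = 2 uV^2) recovered by integrating the peak
  # neighborhood; the Tukey taper spreads a few percent into side bins
  near <- abs(psd$freqs - 10) <= 5
  expect_equal(sum(psd$density[near, 1]) * psd$df, 2, tolerance = 0.02)
  # bins away from the tone are tiny
  expect_lt(max(psd$density[!near, 1]), 0.01 * psd$density[peak, 1])
})

test_that("white-noise PSD integrates to the signal variance (Parseval)", {
  set.seed(31)
  fs <- 1024
  x <- rnorm(fs * 60, sd = 3)
  psd <- resting_psd(eeg_recording(matrix(x, 1), fs), fmax = fs / 2)
  expect_equal(sum(psd$density[, 1]) * psd$df, var(x), tolerance = 0.05)
  expect_true(all(psd$density >= 0))

  # zero signal -> zero density; too-short recording rejected
  z <- resting_psd(eeg_recording(matrix(0, 1, fs * 2), fs))
  expect_equal(max(z$density), 0)
  expect_error(resting_psd(eeg_recording(matrix(0, 1, 100), fs)), "shorter")
})

test_that("the PSD is invariant to segment order", {
  set.seed(5)
  fs <- 256
  segs <- lapply(1:6, function(i) rnorm(fs * 2))
  rec1 <- eeg_recording(matrix(unlist(segs), 1), fs)
  rec2 <- eeg_recording(matrix(unlist(segs[c(4, 1, 6, 2, 5, 3)]), 1), fs)
  expect_equal(resting_psd(rec1)$density, resting_psd(rec2)$density,
               tolerance = 1e-12)
})

test_that("band binning uses the printed edges with the 55-65 Hz gap", {
  freqs <- seq(0.5, 100, by = 0.5)
  flat <- structure(list(freqs = freqs,
                         density = matrix(1, length(freqs), 1),
                         n_segments = 1, df = 0.5, channel_names = "AC",
                         meta = list()), class = "eeg_psd")
  tab <- bin_bands(flat)
  expect_setequal(tab$band,
                  c("theta", "alpha", "beta", "low_gamma", "high_gamma"))
  expect_true(all(tab$power == 1))

  ramp <- flat
  ramp$density <- matrix(freqs, length(freqs), 1)
  tab2 <- bin_bands(ramp)
  # theta = mean of 4.0 .. 7.5 (8 Hz belongs to alpha)
  expect_equal(tab2$power[tab2$band == "theta"], 5.75)
  expect_equal(tab2$power[tab2$band == "alpha"], mean(seq(8, 12.5, 0.5)))
  expect_equal(tab2$power[tab2$band == "low_gamma"], mean(seq(30, 54.5, 0.5)))
  # high gamma is closed at 100
  expect_equal(tab2$power[tab2$band == "high_gamma"], mean(seq(65, 100, 0.5)))

  # a spike in the 55-65 Hz gap (power-line vicinity) touches no band
  gap <- flat
  gap$density[freqs >= 55 & freqs < 65, 1] <- 1000
  expect_equal(bin_bands(gap)$power, tab$power)

  # linear operator
  combo <- flat
  combo$density <- 2 * flat$density + 3 * ramp$density
  expect_equal(bin_bands(combo)$power,
               2 * tab$power + 3 * tab2$power)
})

test_that("group ratios isolate the band with the injected difference", {
  freqs <- seq(0.5, 100, by = 0.5)
  mk <- function(gamma_scale, subject, genotype) {
    d <- rep(1, length(freqs))
    d[freqs >= 30] <- gamma_scale
    psd <- structure(list(freqs = freqs, density = matrix(d, ncol = 1),
                          n_segments = 1, df = 0.5, channel_names = "AC",
                          meta = list()), class = "eeg_psd")
    bin_bands(psd, subject = subject, genotype = genotype)
  }
  tab <- rbind(mk(2, "k1", "KO"), mk(2, "k2", "KO"),
               mk(1, "w1", "WT"), mk(1, "w2", "WT"))
  gr <- group_ratio(tab, "KO", "WT")
  expect_equal(gr$ratio[gr$band == "low_gamma"], 2)
  expect_equal(gr$ratio[gr$band == "high_gamma"], 2)
  expect_equal(gr$ratio[gr$band == "theta"], 1)
  expect_equal(gr$ratio[gr$band == "beta"], 1)

  # identical groups -> all ratios 1
  same <- rbind(mk(1, "a", "KO"), mk(1, "b", "KO"),
                mk(1, "c", "WT"), mk(1, "d", "WT"))
  expect_true(all(group_ratio(same, "KO", "WT")$ratio == 1))
})
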