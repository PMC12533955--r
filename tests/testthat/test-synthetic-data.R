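# Generator contracts: determinism, null exchangeability, ground-truth
# structure of evoked responses, cohort design.

test_that("simulators are bit-reproducible from the seed", {
  cfg <- sim_config(seed = 42, resting_duration_s = 4, fs = 256)
  r1 <- simulate_resting(cfg, "KO-like", subject = 3)
  r2 <- simulate_resting(cfg, "KO-like", subject = 3)
  expect_identical(r1$data, r2$data)

  spec <- stimulus_spec("assr", n_trains = 5)
  e1 <- simulate_evoked(cfg, spec, subject = 2)
  e2 <- simulate_evoked(cfg, spec, subject = 2)
  expect_identical(e1$data, e2$data)
  # different subjects decorrelate
  e3 <- simulate_evoked(cfg, spec, subject = 3)
  expect_false(identical(e1$data, e3$data))
})

test_that("gamma_elevation = 1 leaves the groups exchangeable", {
  cfg <- sim_config(seed = 7, gamma_elevation = 1, resting_duration_s = 40,
                    fs = 512, channels = "AC")
  tab <- NULL
  for (g in c("WT-like", "KO-like")) for (s in 1:5) {
    rec <- simulate_resting(cfg, g, subject = s + ifelse(g == "KO-like", 50, 0))
    tab <- rbind(tab, bin_bands(resting_psd(rec), subject = paste0(g, s),
                                genotype = g))
  }
  gr <- group_ratio(tab, "KO-like", "WT-like")
  expect_true(all(gr$ratio > 0.75 & gr$ratio < 1.33))
})

test_that("fully locked noise-free ASSR trials give ITPC 1 at the drive frequency", {
  cfg <- sim_config(seed = 1, fs = 512)
  ep <- simulate_evoked(cfg, stimulus_spec("assr", n_trains = 8),
                        rho = 1, noise_sd = 0)
  expect_true(all(ep$trial_meta$locked))
  bank <- morlet_bank(40, cycles = 10, fs = 512)
  it <- compute_itpc(morlet_tfr(ep, bank))
  active <- it$times_ms > 200 & it$times_ms < 800
  expect_true(all(it$values[1, active] > 0.999))
})

test_that("the ERP paradigm injects a damped oscillation after the latency", {
  cfg <- sim_config(seed = 2, fs = 512, erp_amplitude_uV = 30,
                    erp_latency_ms = 30)
  ep <- simulate_evoked(cfg, stimulus_spec("bbn_train", n_trains = 40),
                        noise_sd = 5)
  erp <- colMeans(ep$data[, , 1])
  pre <- ep$times_ms < 0
  post <- ep$times_ms > 30 & ep$times_ms < 200
  expect_gt(max(abs(erp[post])), 5 * max(abs(erp[pre])))
  # nothing before the latency beyond residual noise
  expect_lt(max(abs(erp[ep$times_ms < 25])), 0.3 * max(abs(erp[post])))
})

test_that("cohorts mirror the arm sizes and movement structure", {
  cfg <- sim_config(seed = 9, n_subjects_per_group = c(9, 8, 8),
                    resting_duration_s = 2, fs = 256)
  cohort <- simulate_cohort(cfg, treatments = c("CTEP", "CTEP+minocycline",
                                                "vehicle"),
                            paradigms = character(0))
  trt <- vapply(cohort, function(s) s$treatment, character(1))
  geno <- vapply(cohort, function(s) s$genotype_like, character(1))
  expect_equal(sum(trt == "CTEP" & geno == "KO-like"), 9)
  expect_equal(sum(trt == "CTEP+minocycline" & geno == "KO-like"), 8)
  expect_equal(sum(trt == "vehicle" & geno == "KO-like"), 8)
  expect_equal(sum(geno == "WT-like"), 25)
  mv <- vapply(cohort, function(s) s$movement_fraction, numeric(1))
  expect_true(all(mv >= 0 & mv <= 1))

  # degenerate spread: all fractions collapse to the mean
  cfg0 <- sim_config(seed = 9, movement_sd = 0, resting_duration_s = 2,
                     fs = 256)
  c0 <- simulate_cohort(cfg0, paradigms = character(0))
  expect_true(all(vapply(c0, function(s) s$movement_fraction, numeric(1)) ==
                    cfg0$movement_mean))

  # group-correlated movement shows up with the injected sign
  cfg1 <- sim_config(seed = 11, n_subjects_per_group = 40,
                     resting_duration_s = 2, fs = 256)
  c1 <- simulate_cohort(cfg1, paradigms = character(0),
                        movement_offset = 0.15)
  ms <- movement_summary(c1)
  ko <- ms$summary$mean[ms$summary$group == "KO-like"]
  wt <- ms$summary$mean[ms$summary$group == "WT-like"]
  expect_gt(ko - wt, 0.05)
})
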