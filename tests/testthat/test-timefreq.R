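# Morlet decomposition against closed-form oracles; ITPC and STP
# statistics and their invariants.

test_that("wavelet layers match the analytic Gaussian frequency response", {
  fs <- 512
  ep <- make_epochs(function(i, t) sin(2 * pi * 40 * t), 1, fs,
                    c(-1000, 1000))
  f <- c(35, 40, 45)
  co <- morlet_tfr(ep, morlet_bank(f, cycles = 10, fs = fs))
  mid <- which.min(abs(co$times_ms))
  m <- Mod(co$values[1, , mid])
  expect_equal(which.max(m), 2)
  # unit-energy Morlet response to a tone at f0: proportional to
  # sqrt(sigma_t) * exp(-(f0 - f)^2 / (2 sigma_f^2)), sigma_f = f / m
  pred <- sqrt(1 / f) * exp(-(f - 40)^2 / (2 * (f / 10)^2))
  expect_equal(m / m[2], pred / pred[2], tolerance = 0.02)

  # zero input -> zero coefficients
  z <- morlet_tfr(make_epochs(function(i, t) 0 * t, 1, fs, c(-1000, 1000)),
                  morlet_bank(f, 10, fs))
  expect_equal(max(Mod(z$values)), 0)
})

test_that("the impulse response is a Gaussian of width sigma_t = m/(2 pi f)", {
  fs <- 512
  n <- fs * 2
  ep <- make_epochs(function(i, t) as.numeric(seq_along(t) == n / 2), 1, fs,
                    c(-1000, 1000))
  for (f in c(20, 40)) {
    co <- morlet_tfr(ep, morlet_bank(f, 10, fs))
    prof <- Mod(co$values[1, 1, ])
    t_s <- co$times_ms / 1000
    mu <- sum(t_s * prof) / sum(prof)
    sd_hat <- sqrt(sum((t_s - mu)^2 * prof) / sum(prof))
    expect_equal(sd_hat, 10 / (2 * pi * f), tolerance = 0.05)
    expect_equal(mu, t_s[n / 2], tolerance = 1e-3)
  }
})

test_that("epochs too short for any reliable sample are rejected, short \
epochs get fully masked low layers", {
  fs <- 256
  ep <- make_epochs(function(i, t) rnorm(length(t)), 2, fs, c(-100, 100))
  expect_error(morlet_tfr(ep, morlet_bank(c(1, 4), 10, fs)), "too short")
  ep2 <- make_epochs(function(i, t) rnorm(length(t)), 2, fs, c(-500, 1500))
  expect_message(co <- morlet_tfr(ep2, morlet_bank(c(1, 40), 10, fs)),
                 "fully edge-masked")
  expect_true(all(co$edge_mask[1, ]))
  expect_false(all(co$edge_mask[2, ]))
})

test_that("ITPC is 1 for identical trials, 0 for an antipodal pair, and \
invariant to positive trial rescaling", {
  fs <- 256
  base <- function(t) sin(2 * pi * 20 * t) + 0.3 * sin(2 * pi * 45 * t + 1)
  ep_same <- make_epochs(function(i, t) base(t), 5, fs, c(-500, 500))
  bank <- morlet_bank(c(20, 45), 10, fs)
  it1 <- compute_itpc(morlet_tfr(ep_same, bank))
  ok <- !it1$edge_mask
  expect_true(all(it1$values[ok] > 1 - 1e-9))
  expect_true(all(it1$values >= 0 & it1$values <= 1))

  ep_anti <- make_epochs(function(i, t) (-1)^i * base(t), 2, fs, c(-500, 500))
  it0 <- compute_itpc(morlet_tfr(ep_anti, bank))
  expect_lt(max(it0$values[ok]), 1e-9)

  # pure phase statistic: per-trial positive gains change nothing
  gains <- c(0.2, 1, 3, 10, 0.5)
  ep_scaled <- make_epochs(function(i, t) gains[i] * base(t), 5, fs,
                           c(-500, 500))
  it2 <- compute_itpc(morlet_tfr(ep_scaled, bank))
  expect_equal(it2$values, it1$values, tolerance = 1e-9)

  expect_error(compute_itpc(morlet_tfr(make_epochs(function(i, t) base(t),
                                                   1, fs, c(-500, 500)),
                                       bank)),
               "2 trials")
})

test_that("uniform random phases give the Rayleigh mean sqrt(pi)/(2 sqrt(N))", {
  fs <- 256
  bank <- morlet_bank(c(15, 30, 45, 60), 10, fs)
  set.seed(99)
  means <- replicate(12, {
    ep <- make_epochs(function(i, t) {
      phi <- runif(4, 0, 2 * pi)
      sin(2 * pi * 15 * t + phi[1]) + sin(2 * pi * 30 * t + phi[2]) +
        sin(2 * pi * 45 * t + phi[3]) + sin(2 * pi * 60 * t + phi[4])
    }, 100, fs, c(-500, 500))
    it <- compute_itpc(morlet_tfr(ep, bank))
    mean(it$values[!it$edge_mask])
  })
  expect_equal(mean(means), sqrt(pi) / (2 * sqrt(100)), tolerance = 0.05)
})

test_that("STP baseline correction zeroes the baseline and finds a planted burst", {
  fs <- 512
  burst <- function(i, t) {
    on <- t >= 0.1 & t < 0.4
    x <- rnorm(length(t), sd = 1)
    x[on] <- x[on] + 3 * sin(2 * pi * 40 * t[on] + runif(1, 0, 2 * pi))
    x
  }
  set.seed(17)
  ep <- make_epochs(burst, 30, fs, c(-500, 1000))
  bank <- morlet_bank(c(20, 40, 60), 10, fs)
  co <- morlet_tfr(ep, bank)
  stp <- compute_stp(co)
  # construction invariant: baseline-window mean is zero per frequency
  bl <- stp$times_ms >= -250 & stp$times_ms < -150
  expect_lt(max(abs(rowMeans(stp$values[, bl]))), 1e-10)
  # the 40 Hz layer lights up during the burst, clearly above the others
  during <- stp$times_ms > 150 & stp$times_ms < 350
  m <- rowMeans(stp$values[, during])
  expect_gt(m[2], 5 * max(abs(m[c(1, 3)])))

  expect_error(compute_stp(co, baseline_ms = c(-900, -800)), "outside")
})

test_that("STP is invariant to a constant power offset across trials", {
  fs <- 256
  set.seed(3)
  ep <- make_epochs(function(i, t) rnorm(length(t)), 6, fs, c(-500, 500))
  co <- morlet_tfr(ep, morlet_bank(c(20, 40), 10, fs))
  stp1 <- compute_stp(co)
  shifted <- co
  # add constant c to |W|^2 keeping phases
  cshift <- 4
  shifted$values <- sqrt(Mod(co$values)^2 + cshift) *
    exp(1i * Arg(co$values))
  stp2 <- compute_stp(shifted)
  expect_equal(stp2$values, stp1$values, tolerance = 1e-9)
})

test_that("stationary noise has no systematic post-stimulus STP deviation", {
  fs <- 256
  set.seed(41)
  ep <- make_epochs(function(i, t) rnorm(length(t), sd = 2), 60, fs,
                    c(-500, 1000))
  bank <- morlet_bank(c(25, 50), 10, fs)
  co <- morlet_tfr(ep, bank)
  stp <- compute_stp(co)
  post <- stp$times_ms > 0 & !apply(co$edge_mask, 2, any)
  # per-trial corrected means for an SE of the across-trial average
  p <- Mod(co$values)^2
  bl <- co$times_ms >= -250 & co$times_ms < -150
  per_trial <- apply(p[, , post, drop = FALSE], 1, mean) -
    apply(p[, , bl, drop = FALSE], 1, mean)
  se <- sd(per_trial) / sqrt(length(per_trial))
  expect_lt(abs(mean(stp$values[, post])), 2 * se)
})
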