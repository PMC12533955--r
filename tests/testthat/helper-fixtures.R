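# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no data files.

# single-channel epochs whose trial waveforms come from `wave_fun(trial)`
make_epochs <- function(wave_fun, n_trials, fs, window_ms) {
  n <- round((window_ms[2] - window_ms[1]) / 1000 * fs)
  pre <- round(-window_ms[1] / 1000 * fs)
  t_s <- (seq_len(n) - 1 - pre) / fs
  arr <- array(0, c(n_trials, n, 1))
  for (i in seq_len(n_trials)) arr[i, , 1] <- wave_fun(i, t_s)
  eeg_epochs(arr, fs, window_ms)
}

# independent 4-connectivity labeling oracle (pure R breadth-first search)
r_label_clusters <- function(supra) {
  nr <- nrow(supra); nc <- ncol(supra)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!supra[i, j] || labels[i, j] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); labels[i, j] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- cur[1] + d[1]; c2 <- cur[2] + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (supra[r2, c2] && labels[r2, c2] == 0L) {
          labels[r2, c2] <- nxt
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  labels
}

# brute-force enumeration oracle for the 3-vs-3 cluster test: per-pixel
# Welch t via stats::t.test, R labeling, max cluster size per direction
# over every label assignment; returns exact p per observed cluster size.
brute_force_cluster <- function(group_a, group_b, pixel_alpha = 0.05) {
  X <- c(group_a, group_b)
  n_a <- length(group_a); n_tot <- length(X)
  dims <- dim(X[[1]])
  supra_maps <- function(sel) {
    a <- X[sel]; b <- X[-sel]
    tmat <- matrix(0, dims[1], dims[2])
    pmat <- matrix(1, dims[1], dims[2])
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      va <- vapply(a, function(m) m[i, j], numeric(1))
      vb <- vapply(b, function(m) m[i, j], numeric(1))
      ht <- stats::t.test(va, vb)
      tmat[i, j] <- unname(ht$statistic)
      pmat[i, j] <- ht$p.value
    }
    list(t = tmat, p = pmat)
  }
  combs <- utils::combn(n_tot, n_a)
  max_pos <- numeric(ncol(combs)); max_neg <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    mp <- supra_maps(combs[, k])
    lab_p <- r_label_clusters(mp$p < pixel_alpha & mp$t > 0)
    lab_n <- r_label_clusters(mp$p < pixel_alpha & mp$t < 0)
    max_pos[k] <- if (max(lab_p) > 0) max(tabulate(lab_p[lab_p > 0])) else 0
    max_neg[k] <- if (max(lab_n) > 0) max(tabulate(lab_n[lab_n > 0])) else 0
  }
  obs <- supra_maps(seq_len(n_a))
  lab <- r_label_clusters(obs$p < pixel_alpha & obs$t > 0)
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  list(obs_pos_sizes = sizes,
       p_pos = vapply(sizes, function(s) mean(max_pos >= s), numeric(1)),
       null_pos = max_pos, null_neg = max_neg)
}

# brute-force Type II F for the group term in power ~ group + covariate:
# residual sums of squares of the nested least-squares fits.
ss_oracle_F <- function(power, group, covariate) {
  g <- as.factor(group)
  X_full <- model.matrix(~ g + covariate)
  X_red <- model.matrix(~ covariate)
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, power))
    sum((power - X %*% beta)^2)
  }
  df1 <- nlevels(g) - 1
  df2 <- length(power) - ncol(X_full)
  ((rss(X_red) - rss(X_full)) / df1) / (rss(X_full) / df2)
}

# synthetic band-power table: optional gamma-band group effect and a
# linear movement-covariate effect
make_band_table <- function(n_per, effect = 0, cov_effect = 0, seed = 1,
                            channels = "AC") {
  set.seed(seed)
  bands <- c("theta", "alpha", "beta", "low_gamma", "high_gamma")
  rows <- NULL
  for (ch in channels) {
    mv <- runif(2 * n_per, 0.2, 0.6)
    for (b in seq_along(bands)) {
      power <- rnorm(2 * n_per, mean = 10) +
        effect * rep(c(0, 1), each = n_per) * (b >= 4) +
        cov_effect * mv
      rows <- rbind(rows, data.frame(
        subject = paste0("s", seq_len(2 * n_per)), channel = ch,
        band = bands[b], power = power,
        genotype = rep(c("WT", "KO"), each = n_per),
        treatment = "vehicle", movement_fraction = mv))
    }
  }
  rows
}
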