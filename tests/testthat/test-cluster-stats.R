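# Time binning and the Monte Carlo cluster permutation test, including the
# exhaustive-enumeration oracle and symmetry/monotonicity invariants.

test_that("time binning averages near-equal contiguous bins", {
  g <- matrix(7, 10, 2048)
  b <- bin_tf(g, 256)
  expect_equal(dim(b), c(10, 256))
  expect_true(all(b == 7))

  # 2048 / 256: every bin is exactly 8 samples
  vals <- matrix(seq_len(2048), 10, 2048, byrow = TRUE)
  b2 <- bin_tf(vals, 256)
  brute <- sapply(split(seq_len(2048), rep(1:256, each = 8)),
                  function(ix) mean(vals[1, ix]))
  expect_equal(b2[1, ], unname(brute))

  # non-divisible: remainder spread over the leading bins, brute force check
  set.seed(8)
  g3 <- matrix(rnorm(3 * 37), 3, 37)
  b3 <- bin_tf(g3, 10)
  widths <- c(4, 4, 4, 4, 4, 4, 4, 3, 3, 3)
  idx <- rep(1:10, times = widths)
  for (r in 1:3)
    expect_equal(b3[r, ], as.numeric(tapply(g3[r, ], idx, mean)))

  expect_error(bin_tf(matrix(0, 5, 100), 256), "at least")
})

test_that("Monte Carlo p-values agree with exhaustive enumeration on a 3v3 toy", {
  set.seed(12)
  mk <- function(shift) {
    m <- matrix(rnorm(400), 20)
    m[5:10, 5:10] <- m[5:10, 5:10] + shift
    m
  }
  ga <- replicate(3, mk(2.5), simplify = FALSE)
  gb <- replicate(3, mk(0), simplify = FALSE)

  en <- cluster_permutation_test(ga, gb, enumerate = TRUE)
  expect_true(en$enumerated)
  expect_equal(en$n_perm, choose(6, 3))

  # independent oracle: t.test per pixel + R flood fill over all 20
  # assignments
  oracle <- brute_force_cluster(ga, gb)
  pkg_pos <- en$clusters[en$clusters$direction == "pos", ]
  expect_setequal(pkg_pos$size, oracle$obs_pos_sizes)
  for (i in seq_len(nrow(pkg_pos))) {
    j <- match(pkg_pos$size[i], oracle$obs_pos_sizes)
    expect_equal(pkg_pos$p_value[i], oracle$p_pos[j])
  }
  expect_equal(sort(en$null_max_pos), sort(oracle$null_pos))

  # Monte Carlo converges to the enumerated p within sampling error
  mc <- cluster_permutation_test(ga, gb, n_perm = 3000, seed = 4)
  big_en <- min(pkg_pos$p_value)
  big_mc <- min(mc$clusters$p_value[mc$clusters$direction == "pos"])
  expect_lt(abs(big_mc - big_en), 0.02)
})

test_that("identical groups yield no significant clusters", {
  set.seed(2)
  g <- replicate(4, matrix(rnorm(200), 10), simplify = FALSE)
  res <- cluster_permutation_test(g, g, n_perm = 200, seed = 1)
  expect_false(any(res$clusters$significant))
})

test_that("the test respects symmetry, ordering, and p-value bounds", {
  set.seed(21)
  mk <- function(shift) matrix(rnorm(150) + shift * (row(matrix(0, 10, 15)) < 4), 10)
  ga <- replicate(4, mk(1.5), simplify = FALSE)
  gb <- replicate(4, mk(0), simplify = FALSE)

  # enumeration mode makes the null (and hence p) order-invariant
  r1 <- cluster_permutation_test(ga, gb, enumerate = TRUE)
  # subject order within groups is irrelevant
  r2 <- cluster_permutation_test(ga[c(3, 1, 4, 2)], gb[c(2, 4, 1, 3)],
                                 enumerate = TRUE)
  expect_equal(r1$clusters, r2$clusters)
  expect_equal(r1$t_obs, r2$t_obs)

  # swapping groups maps positive clusters onto negative ones
  r3 <- cluster_permutation_test(gb, ga, enumerate = TRUE)
  cp <- r1$clusters[r1$clusters$direction == "pos", c("size", "mass")]
  cn <- r3$clusters[r3$clusters$direction == "neg", c("size", "mass")]
  expect_equal(cp[order(cp$size), ], cn[order(cn$size), ],
               ignore_attr = TRUE)
  expect_equal(r1$t_obs, -r3$t_obs)

  # Monte Carlo p-values bounded below by 1/(n_perm + 1)
  rmc <- cluster_permutation_test(ga, gb, n_perm = 400, seed = 7)
  expect_true(all(rmc$clusters$p_value >= 1 / 401))
  expect_true(all(rmc$clusters$p_value <= 1))

  # masks shrink as alpha decreases
  r_loose <- cluster_permutation_test(ga, gb, n_perm = 400, seed = 7,
                                      alpha_per_tail = 0.25)
  r_tight <- cluster_permutation_test(ga, gb, n_perm = 400, seed = 7,
                                      alpha_per_tail = 0.01)
  expect_true(all(r_tight$mask_pos <= r_loose$mask_pos))

  # seeded determinism
  r4 <- cluster_permutation_test(ga, gb, n_perm = 400, seed = 7)
  expect_identical(rmc$null_max_pos, r4$null_max_pos)
  expect_equal(rmc$clusters, r4$clusters)
})

test_that("masked pixels never enter clusters", {
  set.seed(33)
  mk <- function() {
    m <- matrix(rnorm(100), 10)
    m[1:3, ] <- m[1:3, ] + 10  # big difference confined to masked rows
    m
  }
  ga <- replicate(3, mk(), simplify = FALSE)
  gb <- replicate(3, matrix(rnorm(100), 10), simplify = FALSE)
  mask <- matrix(FALSE, 10, 10); mask[1:3, ] <- TRUE
  res <- cluster_permutation_test(ga, gb, n_perm = 100, seed = 2, mask = mask)
  if (nrow(res$clusters)) {
    sig_rows <- which(res$mask_pos | res$mask_neg, arr.ind = TRUE)
    expect_true(all(sig_rows[, 1] > 3))
  }
  expect_false(any(res$mask_pos[1:3, ]))
})

test_that("the C++ labeling agrees with the R flood-fill oracle", {
  set.seed(14)
  for (conn in c(4, 8)) {
    supra <- matrix(runif(600) < 0.35, 20, 30)
    cpp <- fxeeg:::label_clusters_cpp(supra, conn)
    if (conn == 4) {
      ref <- r_label_clusters(supra)
      # same partition: sizes and one-to-one label correspondence
      expect_equal(sort(tabulate(cpp[cpp > 0])), sort(tabulate(ref[ref > 0])))
      expect_equal(cpp > 0, supra)
      pairs <- unique(cbind(as.vector(cpp), as.vector(ref)))
      pairs <- pairs[pairs[, 1] > 0, , drop = FALSE]
      expect_equal(nrow(pairs), max(ref))
    } else {
      # 8-connectivity merges diagonal neighbours: never more clusters
      expect_lte(attr(cpp, "n_clusters"),
                 attr(fxeeg:::label_clusters_cpp(supra, 4), "n_clusters"))
    }
  }
})
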