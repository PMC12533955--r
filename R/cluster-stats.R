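# Monte Carlo cluster-based permutation test on binned time-frequency
# matrices (Maris-Oostenveld style): pixel-wise Welch t map, suprathreshold
# pixels grouped into contiguous clusters, cluster sizes compared against
# the distribution of the maximum cluster size under random subject-label
# reassignment. Controls the family-wise error rate per direction.

#' Bin a time-frequency grid for cluster statistics
#'
#' Partitions the time axis into `n_time_bins` near-equal contiguous bins
#' (when the sample count is not divisible, the remainder is spread over
#' the leading bins, one extra sample each) and averages within bins. The
#' frequency axis passes through unchanged, so a 100-layer wavelet grid
#' with >= 256 time samples becomes the canonical 100 x 256 matrix.
#'
#' @param grid a `tf_grid` (ITPC or STP), or a numeric freqs x time matrix.
#' @param n_time_bins number of time bins (default 256).
#' @param mask_threshold a time bin inherits the edge mask when more than
#'   this fraction of its samples is edge-masked.
#' @return A numeric freqs x n_time_bins matrix of class `binned_tf`, with
#'   attributes `freqs`, `bin_times_ms` (bin centers) and `edge_mask`
#'   (freqs x n_time_bins logical, if the input carried one).
#' @export
bin_tf <- function(grid, n_time_bins = 256, mask_threshold = 0.5) {
  if (inherits(grid, "tf_grid")) {
    values <- grid$values; freqs <- grid$freqs; times <- grid$times_ms
    emask <- grid$edge_mask
  } else {
    values <- grid; freqs <- seq_len(nrow(grid)); times <- seq_len(ncol(grid))
    emask <- NULL
  }
  n_t <- ncol(values)
  if (n_t < n_time_bins)
    stop("grid has ", n_t, " time samples; need at least ", n_time_bins)
  base_w <- n_t %/% n_time_bins
  rem <- n_t %% n_time_bins
  widths <- rep(base_w, n_time_bins)
  if (rem > 0) widths[seq_len(rem)] <- base_w + 1L
  idx <- rep(seq_len(n_time_bins), times = widths)
  # averaging operator as a sparse-free matrix product
  W <- matrix(0, n_t, n_time_bins)
  W[cbind(seq_len(n_t), idx)] <- 1 / widths[idx]
  binned <- values %*% W
  bin_times <- as.numeric(crossprod(times, W))
  out <- structure(binned, class = c("binned_tf", "matrix", "array"),
                   freqs = freqs, bin_times_ms = bin_times)
  if (!is.null(emask)) {
    mfrac <- (emask * 1) %*% W
    attr(out, "edge_mask") <- mfrac > mask_threshold
  }
  out
}

# Vectorized Welch t statistics for a block of label assignments.
# X: n_subjects x n_pixels; ind_a: n_assign x n_subjects 0/1 membership of
# group A. Returns list(t, df): n_assign x n_pixels matrices. Pixels with
# zero pooled standard error get t = 0 (df 1).
welch_t_block <- function(X, ind_a, n_a, n_b) {
  X2 <- X * X
  SA <- ind_a %*% X
  SA2 <- ind_a %*% X2
  tot <- matrix(colSums(X), nrow(ind_a), ncol(X), byrow = TRUE)
  tot2 <- matrix(colSums(X2), nrow(ind_a), ncol(X), byrow = TRUE)
  SB <- tot - SA
  SB2 <- tot2 - SA2
  mA <- SA / n_a; mB <- SB / n_b
  vA <- pmax((SA2 - SA^2 / n_a) / (n_a - 1), 0)
  vB <- pmax((SB2 - SB^2 / n_b) / (n_b - 1), 0)
  seA <- vA / n_a; seB <- vB / n_b
  se <- sqrt(seA + seB)
  tstat <- (mA - mB) / se
  degenerate <- !is.finite(tstat)
  tstat[degenerate] <- 0
  df <- (seA + seB)^2 / (seA^2 / (n_a - 1) + seB^2 / (n_b - 1))
  df[degenerate] <- 1
  list(t = tstat, df = df)
}

# Suprathreshold indicator at two-sided level alpha for Welch t values.
# |t| > qt(1 - alpha/2, n_tot - 2) is necessary (critical values shrink
# with df), so the exact Welch-df p is only evaluated on that subset.
welch_supra <- function(tvec, dfvec, alpha, crit_min) {
  cand <- abs(tvec) > crit_min
  out <- logical(length(tvec))
  if (any(cand))
    out[cand] <- 2 * pt(-abs(tvec[cand]), dfvec[cand]) < alpha
  out
}

#' Cluster-based Monte Carlo permutation test
#'
#' Compares two groups of binned time-frequency matrices. The pixel-wise
#' statistic is a Welch t (group A minus group B); pixels with two-sided
#' p below `pixel_alpha` form candidate clusters by contiguity, separately
#' for positive and negative t. The cluster statistic is its size (pixel
#' count; `"mass"` = sum of |t| optional). The null distribution is the
#' maximum cluster statistic per direction over random reassignments of the
#' subject labels preserving group sizes. An observed cluster is
#' significant when its Monte Carlo p-value
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)` is at most
#' `alpha_per_tail` — i.e. when it is larger than the 97.5th percentile of
#' the null at the default per-tail alpha of 0.025 (two-tailed 0.05).
#'
#' @param group_a,group_b lists of numeric matrices (e.g. [bin_tf()]
#'   output), one per subject, all the same dimension; >= 2 per group.
#' @param n_perm number of random label permutations (default 2000).
#' @param alpha_per_tail per-direction significance level (default 0.025).
#' @param pixel_alpha two-sided cluster-forming threshold on the pixel
#'   Welch t p-value (default 0.05).
#' @param connectivity 4 (edge-adjacent) or 8.
#' @param cluster_stat `"size"` (pixel count) or `"mass"` (sum of |t|).
#' @param seed integer; set for reproducible null samples.
#' @param enumerate if TRUE, replace Monte Carlo sampling by exhaustive
#'   enumeration of all `choose(nA + nB, nA)` label assignments (allowed
#'   when that count is <= 1e5); p-values are then exact:
#'   `#\{null >= observed\} / n_assignments`.
#' @param mask optional logical matrix (TRUE = exclude pixel from
#'   clustering), e.g. the binned wavelet edge mask.
#' @param block permutations are processed in blocks of this many
#'   assignments to bound memory.
#' @return An object of class `cluster_test_result`: list with `t_obs`,
#'   `df_obs`, `clusters` (data.frame: direction, id, size, mass,
#'   p_value, significant), `mask_pos`, `mask_neg` (logical significance
#'   masks), `null_max_pos`, `null_max_neg`, `n_perm`, `alpha_per_tail`,
#'   `enumerated`, `seed`, `config`.
#' @export
cluster_permutation_test <- function(group_a, group_b, n_perm = 2000,
                                     alpha_per_tail = 0.025,
                                     pixel_alpha = 0.05, connectivity = 4,
                                     cluster_stat = c("size", "mass"),
                                     seed = NULL, enumerate = FALSE,
                                     mask = NULL, block = 128L) {
  cluster_stat <- match.arg(cluster_stat)
  stopifnot(connectivity %in% c(4, 8))
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) stop("need at least 2 subjects per group")
  dims <- dim(group_a[[1]])
  all_m <- c(group_a, group_b)
  if (!all(vapply(all_m, function(m) identical(dim(m), dims), logical(1))))
    stop("all matrices must share the same dimensions")
  nr <- dims[1]; nc <- dims[2]
  if (!is.null(mask)) stopifnot(identical(dim(mask), dims))
  n_tot <- n_a + n_b
  X <- t(vapply(all_m, as.numeric, numeric(nr * nc)))  # subjects x pixels
  if (!all(is.finite(X))) stop("non-finite values in input matrices")
  if (!is.null(seed)) set.seed(seed)

  use_mass <- cluster_stat == "mass"
  excl <- if (is.null(mask)) rep(FALSE, nr * nc) else as.logical(mask)
  crit_min <- qt(1 - pixel_alpha / 2, n_tot - 2)

  max_stats <- function(tvec, dfvec, sign_pos) {
    supra <- welch_supra(tvec, dfvec, pixel_alpha, crit_min) &
      (if (sign_pos) tvec > 0 else tvec < 0) & !excl
    max_cluster_stat_cpp(supra, tvec, nr, nc, connectivity, use_mass)
  }

  # observed statistic map (true labels: first n_a subjects = group A)
  obs_ind <- matrix(0, 1, n_tot); obs_ind[1, seq_len(n_a)] <- 1
  obs <- welch_t_block(X, obs_ind, n_a, n_b)
  t_obs <- matrix(obs$t[1, ], nr, nc)
  p_obs <- matrix(2 * pt(-abs(obs$t[1, ]), obs$df[1, ]), nr, nc)

  # label assignments for the null
  if (enumerate) {
    n_assign <- choose(n_tot, n_a)
    if (n_assign > 1e5)
      stop("enumeration over ", n_assign, " assignments refused (> 1e5)")
    combs <- utils::combn(n_tot, n_a)
    ind <- matrix(0, ncol(combs), n_tot)
    for (j in seq_len(ncol(combs))) ind[j, combs[, j]] <- 1
  } else {
    ind <- matrix(0, n_perm, n_tot)
    for (j in seq_len(n_perm))
      ind[j, sample.int(n_tot, n_a)] <- 1
  }
  n_null <- nrow(ind)
  null_pos <- numeric(n_null); null_neg <- numeric(n_null)
  for (start in seq(1, n_null, by = block)) {
    rows <- start:min(n_null, start + block - 1L)
    res <- welch_t_block(X, ind[rows, , drop = FALSE], n_a, n_b)
    for (j in seq_along(rows)) {
      null_pos[rows[j]] <- max_stats(res$t[j, ], res$df[j, ], TRUE)
      null_neg[rows[j]] <- max_stats(res$t[j, ], res$df[j, ], FALSE)
    }
  }

  # observed clusters per direction
  cluster_rows <- list(); masks <- list(pos = matrix(FALSE, nr, nc),
                                        neg = matrix(FALSE, nr, nc))
  for (dir in c("pos", "neg")) {
    sgn <- if (dir == "pos") t_obs > 0 else t_obs < 0
    supra <- p_obs < pixel_alpha & sgn & !matrix(excl, nr, nc)
    labels <- label_clusters_cpp(supra, connectivity)
    k <- attr(labels, "n_clusters")
    null_max <- if (dir == "pos") null_pos else null_neg
    if (k > 0) {
      for (id in seq_len(k)) {
        pix <- labels == id
        size <- sum(pix)
        mass <- sum(abs(t_obs[pix]))
        stat <- if (use_mass) mass else size
        p_val <- if (enumerate) mean(null_max >= stat)
                 else (1 + sum(null_max >= stat)) / (n_null + 1)
        sig <- p_val <= alpha_per_tail
        if (sig) masks[[dir]] <- masks[[dir]] | pix
        cluster_rows[[length(cluster_rows) + 1L]] <-
          data.frame(direction = dir, id = id, size = size, mass = mass,
                     p_value = p_val, significant = sig)
      }
    }
  }
  clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows)
              else data.frame(direction = character(0), id = integer(0),
                              size = integer(0), mass = numeric(0),
                              p_value = numeric(0), significant = logical(0))
  structure(list(t_obs = t_obs, p_obs = p_obs, clusters = clusters,
                 mask_pos = masks$pos, mask_neg = masks$neg,
                 null_max_pos = null_pos, null_max_neg = null_neg,
                 n_perm = n_null, alpha_per_tail = alpha_per_tail,
                 enumerated = enumerate, seed = seed,
                 config = list(pixel_alpha = pixel_alpha,
                               connectivity = connectivity,
                               cluster_stat = cluster_stat)),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %s, %d %s, alpha/tail = %g\n",
              if (x$enumerated) "exhaustive enumeration" else "Monte Carlo",
              x$n_perm,
              if (x$enumerated) "assignments" else "permutations",
              x$alpha_per_tail))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}

#' Export a cluster test result
#'
#' Writes the cluster list (with bounding boxes in the grid's frequency/
#' time units when available) as JSON and the combined significance mask
#' as CSV.
#'
#' @param result a `cluster_test_result`.
#' @param json_path,mask_path output paths (either may be NULL to skip).
#' @param freqs,times_ms optional axes for bounding boxes.
#' @return Invisibly, the list written to JSON.
#' @export
export_cluster_result <- function(result, json_path = NULL, mask_path = NULL,
                                  freqs = NULL, times_ms = NULL) {
  stopifnot(inherits(result, "cluster_test_result"))
  clusters <- result$clusters
  boxes <- NULL
  if (nrow(clusters)) {
    boxes <- lapply(seq_len(nrow(clusters)), function(i) {
      dir <- clusters$direction[i]
      sgn <- if (dir == "pos") result$t_obs > 0 else result$t_obs < 0
      supra <- result$p_obs < result$config$pixel_alpha & sgn
      labels <- label_clusters_cpp(supra, result$config$connectivity)
      pix <- which(labels == clusters$id[i], arr.ind = TRUE)
      box <- list(row_range = range(pix[, 1]), col_range = range(pix[, 2]))
      if (!is.null(freqs)) box$freq_hz <- range(freqs[pix[, 1]])
      if (!is.null(times_ms)) box$time_ms <- range(times_ms[pix[, 2]])
      box
    })
  }
  out <- list(n_perm = result$n_perm, alpha_per_tail = result$alpha_per_tail,
              enumerated = result$enumerated, seed = result$seed,
              config = result$config,
              clusters = cbind(clusters,
                               data.frame(bbox = I(if (is.null(boxes)) list()
                                                   else boxes))))
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  if (!is.null(mask_path)) {
    m <- matrix(0L, nrow(result$mask_pos), ncol(result$mask_pos))
    m[result$mask_pos] <- 1L
    m[result$mask_neg] <- -1L
    utils::write.table(m, mask_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(out)
}
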