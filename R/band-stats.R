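# Movement-covariate-adjusted group comparisons of resting band powers.
# Per band: ANCOVA (power ~ group + movement) with a Type II F test on the
# group term; Bonferroni control across the five bands via an effective
# per-band alpha of 0.01. A Wilks' lambda omnibus across the five bands is
# reported alongside.

#' Covariate-adjusted band-power test
#'
#' For every channel and band, fits the linear model
#' `power ~ group + covariate` and tests the group term with Type II sums
#' of squares (`car::Anova`). Significance is flagged at the
#' Bonferroni-effective per-band level `alpha` (default 0.01, i.e. 0.05
#' over five bands). A one-way MANCOVA omnibus (Wilks' lambda over the
#' five band powers, movement as covariate) accompanies the per-band
#' table.
#'
#' @param table band-power data.frame ([bin_bands()] rows over subjects)
#'   with columns `subject`, `channel`, `band`, `power`, the grouping
#'   column and the covariate column.
#' @param factor name of the grouping column (default `"genotype"`).
#' @param covariate name of the covariate column (default
#'   `"movement_fraction"`).
#' @param alpha effective per-band significance level (default 0.01).
#' @return An object of class `band_test_result`: list with `per_band`
#'   (data.frame: channel, band, F, df1, df2, p, significant) and `omnibus`
#'   (per channel: Wilks' lambda, approximate F, dfs, p).
#' @export
ancova_band_test <- function(table, factor = "genotype",
                             covariate = "movement_fraction", alpha = 0.01) {
  stopifnot(all(c("subject", "channel", "band", "power", factor, covariate)
                %in% names(table)))
  table[[factor]] <- droplevels(as.factor(table[[factor]]))
  n_groups <- nlevels(table[[factor]])
  if (n_groups < 2) stop("need at least 2 groups in '", factor, "'")
  if (length(unique(table[[covariate]])) < 2)
    stop("covariate '", covariate, "' is constant; the design is singular")
  bands <- unique(table$band)
  channels <- unique(table$channel)
  rows <- list()
  omnibus <- list()
  for (ch in channels) {
    sub <- table[table$channel == ch, ]
    for (bn in bands) {
      d <- sub[sub$band == bn, ]
      if (nrow(d) < n_groups + 2)
        stop("too few subjects for band '", bn, "' on channel '", ch, "'")
      fml <- stats::as.formula(paste("power ~", factor, "+", covariate))
      fit <- lm(fml, data = d)
      a2 <- car::Anova(fit, type = 2)
      i <- match(factor, rownames(a2))
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, band = bn,
        F = a2[i, "F value"], df1 = a2[i, "Df"],
        df2 = a2["Residuals", "Df"], p = a2[i, "Pr(>F)"],
        significant = a2[i, "Pr(>F)"] < alpha)
    }
    # Wilks' lambda omnibus over the five bands jointly
    wide <- stats::reshape(
      sub[, c("subject", "band", "power", factor, covariate)],
      idvar = c("subject", factor, covariate),
      timevar = "band", direction = "wide")
    ycols <- paste0("power.", bands)
    if (length(bands) >= 2 && all(ycols %in% names(wide)) &&
        nrow(wide) > length(bands) + n_groups) {
      Y <- as.matrix(wide[, ycols])
      fml <- stats::as.formula(paste("Y ~", factor, "+", covariate))
      mv <- manova(fml, data = wide)
      sm <- summary(mv, test = "Wilks")$stats
      omnibus[[ch]] <- data.frame(
        channel = ch, wilks = sm[factor, "Wilks"],
        F = sm[factor, "approx F"], df1 = sm[factor, "num Df"],
        df2 = sm[factor, "den Df"], p = sm[factor, "Pr(>F)"])
    }
  }
  per_band <- do.call(rbind, rows)
  rownames(per_band) <- NULL
  structure(list(per_band = per_band,
                 omnibus = if (length(omnibus)) do.call(rbind, omnibus)
                           else NULL,
                 factor = factor, covariate = covariate, alpha = alpha),
            class = "band_test_result")
}

#' @export
print.band_test_result <- function(x, ...) {
  cat(sprintf("<band_test_result> %s adjusted for %s, per-band alpha = %g\n",
              x$factor, x$covariate, x$alpha))
  print(x$per_band, digits = 4)
  invisible(x)
}

#' Movement-fraction summary and group comparison
#'
#' Summarizes the per-subject movement fractions by group and, for exactly
#' two groups with non-zero variance, runs a Welch two-sample t test
#' (mirroring the design check that movement does not differ between
#' groups). With more than two groups a one-way ANOVA is used. Degenerate
#' zero-variance data are reported without a test.
#'
#' @param cohort either a list of subject records from [simulate_cohort()]
#'   or a data.frame with columns `group` and `movement_fraction`.
#' @param group_col grouping column when `cohort` is a data.frame.
#' @return List with `summary` (data.frame: group, n, mean, sd), `test`
#'   (htest or NULL) and `p_value` (NA when no test was possible).
#' @export
movement_summary <- function(cohort, group_col = "genotype_like") {
  if (!is.data.frame(cohort)) {
    cohort <- data.frame(
      group = vapply(cohort, function(s) s$genotype_like, character(1)),
      movement_fraction = vapply(cohort, function(s) s$movement_fraction,
                                 numeric(1)))
    group_col <- "group"
  }
  g <- as.factor(cohort[[group_col]])
  mv <- cohort$movement_fraction
  smry <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(mv, g, mean)),
    sd = as.numeric(tapply(mv, g, sd)))
  test <- NULL; p <- NA_real_
  if (all(smry$sd == 0 | is.na(smry$sd))) {
    # no within-group variance: nothing to test
  } else if (nlevels(g) == 2) {
    test <- t.test(mv ~ g)
    p <- test$p.value
  } else if (nlevels(g) > 2) {
    test <- stats::oneway.test(mv ~ g)
    p <- test$p.value
  }
  list(summary = smry, test = test, p_value = p)
}
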