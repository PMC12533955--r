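# End-to-end pipeline: simulate a cohort, estimate resting PSD and band
# powers, compute evoked ITPC/STP grids, and run the three pre-registered
# contrast types (KO-like vs WT-like pre-treatment; treated-KO vs
# vehicle-WT; treated-KO vs vehicle-KO) through the cluster permutation
# and covariate-adjusted band tests. Every artifact is reproducible from
# (config, seed); a manifest records both.

#' Pipeline configuration
#'
#' @param sim a `sim_config` (ground-truth generator settings).
#' @param seed master seed, recorded in all outputs; overrides `sim$seed`.
#' @param treatments treatment arm labels.
#' @param paradigms which paradigms to analyze: subset of `"resting"`,
#'   `"bbn_train"`, `"assr"`, `"chirp"`.
#' @param segment_s,taper_fraction resting PSD parameters.
#' @param morlet_cycles Morlet parameter m.
#' @param n_wavelet_freqs number of linearly spaced wavelet layers
#'   (1-100 Hz; the canonical analysis uses 100).
#' @param baseline_ms STP baseline window.
#' @param n_time_bins time bins of the cluster-test matrix (canonical 256).
#' @param evoked_trials optional trial-count override for simulated evoked
#'   paradigms (NULL = each stimulus spec's repetition count).
#' @param n_perm,alpha_per_tail,pixel_alpha,connectivity cluster-test
#'   parameters.
#' @param alpha_band per-band significance level (Bonferroni-effective).
#' @param out_dir output directory (created if missing).
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(sim = sim_config(), seed = sim$seed,
                            treatments = c("vehicle", "CTEP"),
                            paradigms = c("resting", "assr"),
                            segment_s = 2, taper_fraction = 0.1,
                            morlet_cycles = 10, n_wavelet_freqs = 100,
                            baseline_ms = c(-250, -150),
                            n_time_bins = 256, evoked_trials = NULL,
                            n_perm = 2000,
                            alpha_per_tail = 0.025, pixel_alpha = 0.05,
                            connectivity = 4, alpha_band = 0.01,
                            out_dir = tempfile("fxeeg_run_")) {
  stopifnot(inherits(sim, "sim_config"), n_perm >= 1,
            alpha_per_tail > 0, alpha_per_tail < 1,
            alpha_band > 0, alpha_band < 1,
            connectivity %in% c(4, 8))
  bad <- setdiff(paradigms, c("resting", "bbn_train", "assr", "chirp"))
  if (length(bad)) stop("unknown paradigm(s): ", paste(bad, collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, seed = as.integer(seed),
                 treatments = treatments, paradigms = paradigms,
                 segment_s = segment_s, taper_fraction = taper_fraction,
                 morlet_cycles = morlet_cycles,
                 n_wavelet_freqs = n_wavelet_freqs,
                 baseline_ms = baseline_ms, n_time_bins = n_time_bins,
                 evoked_trials = evoked_trials,
                 n_perm = n_perm, alpha_per_tail = alpha_per_tail,
                 pixel_alpha = pixel_alpha, connectivity = connectivity,
                 alpha_band = alpha_band, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` block
#' mirrors [sim_config()] arguments (with `band_components` as a list of
#' `center_hz` / `bandwidth_hz` / `amplitude_uV` records).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$band_components))
    sim_args$band_components <-
      do.call(rbind, lapply(sim_args$band_components, as.data.frame))
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  rest <- y[setdiff(names(y), "sim")]
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(rest), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(rest$baseline_ms)) rest$baseline_ms <- unlist(rest$baseline_ms)
  do.call(pipeline_config, c(list(sim = sim), rest))
}

# per-subject evoked time-frequency summary, binned for the cluster test
subject_binned_grid <- function(rec_epochs, config, measure) {
  bank <- morlet_bank(seq(1, 100, length.out = config$n_wavelet_freqs),
                      cycles = config$morlet_cycles, fs = rec_epochs$fs)
  grid <- evoked_measures(rec_epochs, bank, measures = measure,
                          baseline_ms = config$baseline_ms)[[measure]]
  bin_tf(grid, config$n_time_bins)
}

# the three pre-registered contrast types over a cohort's subject labels
pipeline_contrasts <- function(cohort, treatments) {
  geno <- vapply(cohort, function(s) s$genotype_like, character(1))
  trt <- vapply(cohort, function(s) s$treatment, character(1))
  drug <- setdiff(treatments, "vehicle")
  contrasts <- list(
    pre_KO_vs_WT = list(a = which(geno == "KO-like"),
                        b = which(geno == "WT-like")))
  for (d in drug) {
    contrasts[[paste0("KO-", d, "_vs_WT-vehicle")]] <-
      list(a = which(geno == "KO-like" & trt == d),
           b = which(geno == "WT-like" & trt == "vehicle"))
    contrasts[[paste0("KO-", d, "_vs_KO-vehicle")]] <-
      list(a = which(geno == "KO-like" & trt == d),
           b = which(geno == "KO-like" & trt == "vehicle"))
  }
  contrasts
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort from the configured generator, computes resting PSDs
#' and band-power tables, runs the covariate-adjusted band tests for each
#' contrast, computes evoked ITPC/STP grids and cluster permutation tests
#' where evoked paradigms are configured, and writes all tables plus a run
#' manifest (config, seed, package version) to `config$out_dir`.
#'
#' @param config a `pipeline_config`.
#' @param evoked_measure `"itpc"` or `"stp"` for the cluster-test input.
#' @return Invisibly, a list with `band_table`, `band_tests`,
#'   `cluster_tests`, `movement`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, evoked_measure = c("itpc", "stp")) {
  stopifnot(inherits(config, "pipeline_config"))
  evoked_measure <- match.arg(evoked_measure)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message("[fxeeg] ", sprintf(...))

  log_line("simulate: %d arm(s), seed %d", length(config$treatments),
           config$seed)
  cohort <- simulate_cohort(config$sim, treatments = config$treatments,
                            paradigms = config$paradigms,
                            evoked_trials = config$evoked_trials)
  contrasts <- pipeline_contrasts(cohort, config$treatments)

  band_table <- NULL; band_tests <- list()
  if ("resting" %in% config$paradigms) {
    log_line("resting PSD: %d subjects", length(cohort))
    band_table <- do.call(rbind, lapply(cohort, function(s) {
      psd <- resting_psd(s$recordings$resting, config$segment_s,
                         config$taper_fraction)
      bin_bands(psd, subject = s$subject_id, genotype = s$genotype_like,
                treatment = s$treatment,
                movement_fraction = s$movement_fraction)
    }))
    write_psd_csv(band_table, file.path(config$out_dir, "band_powers.csv"))
    for (cn in names(contrasts)) {
      sel <- c(contrasts[[cn]]$a, contrasts[[cn]]$b)
      ids <- vapply(cohort[sel], function(s) s$subject_id, character(1))
      lab <- rep(c("A", "B"), c(length(contrasts[[cn]]$a),
                                length(contrasts[[cn]]$b)))
      d <- band_table[band_table$subject %in% ids, ]
      d$contrast_group <- lab[match(d$subject, ids)]
      if (length(unique(d$movement_fraction)) < 2) next
      bt <- ancova_band_test(d, factor = "contrast_group",
                             alpha = config$alpha_band)
      bt$per_band$contrast <- cn
      band_tests[[cn]] <- bt
    }
    if (length(band_tests)) {
      tidy <- do.call(rbind, lapply(band_tests, function(b) b$per_band))
      utils::write.csv(tidy, file.path(config$out_dir, "band_tests.csv"),
                       row.names = FALSE)
    }
  }

  cluster_tests <- list()
  evoked <- intersect(config$paradigms, c("bbn_train", "assr", "chirp"))
  for (par in evoked) {
    measure <- if (par == "bbn_train") "stp" else evoked_measure
    log_line("%s: %s grids + cluster test", par, measure)
    grids <- lapply(cohort, function(s)
      subject_binned_grid(s$recordings[[par]], config, measure))
    emask <- attr(grids[[1]], "edge_mask")
    grids <- lapply(grids, unclass)
    for (cn in names(contrasts)) {
      ct <- cluster_permutation_test(
        grids[contrasts[[cn]]$a], grids[contrasts[[cn]]$b],
        n_perm = config$n_perm, alpha_per_tail = config$alpha_per_tail,
        pixel_alpha = config$pixel_alpha,
        connectivity = config$connectivity,
        mask = emask,
        seed = config$seed + 17L)
      key <- paste(par, cn, sep = ".")
      cluster_tests[[key]] <- ct
      export_cluster_result(
        ct, json_path = file.path(config$out_dir,
                                  paste0("clusters_", key, ".json")),
        mask_path = file.path(config$out_dir,
                              paste0("mask_", key, ".csv")))
    }
  }

  movement <- movement_summary(cohort)
  manifest <- list(package = "fxeeg",
                   version = as.character(utils::packageVersion("fxeeg")),
                   seed = config$seed,
                   config = config_as_list(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_line("done: %s", config$out_dir)
  invisible(list(band_table = band_table, band_tests = band_tests,
                 cluster_tests = cluster_tests, movement = movement,
                 manifest = manifest, out_dir = config$out_dir))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$band_components <- as.list(out$sim$band_components)
  out
}
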