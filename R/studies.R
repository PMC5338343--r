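#' Low-abundance mutation detection study
#'
#' End-to-end replicated study of rare-SNV counting, mirroring the assay's
#' spike-in design: (1) a WT-only null population is simulated, idealized
#' and filtered, and the bound-time threshold is calibrated on it with the
#' max + 3 sd rule; (2) per-molecule call probabilities (sensitivity on an
#' SNV-only sample, false-positive rate on a second WT-only null) are
#' measured by running the trace-level pipeline; (3) replicate populations
#' at each mutant fraction are counted with [count_experiment()]; (4) a
#' Welch t-test compares the positive counts between the first two
#' fractions.
#'
#' @param rep_seeds one seed per replicate (condition-major), length
#'   `length(fractions) * n_replicates`.
#' @param n_molecules target molecules per replicate.
#' @param fractions mutant fractions; the t-test compares the first two.
#' @param n_replicates replicates per fraction.
#' @param n_cal_train WT null size for threshold calibration. The default
#'   (2000) is sized for rare-fraction counting: with `n_molecules` WT
#'   molecules tested per replicate, the max + 3 sd rule must be calibrated
#'   on a null large enough to push the per-molecule false-positive rate
#'   well below the mutant fraction being detected, otherwise the
#'   false-positive floor swamps the signal.
#' @param cal_seed,rates_seed seeds of the calibration stages.
#' @param n_rates_wt,n_rates_snv trace-level sample sizes for measuring the
#'   false-positive rate and sensitivity.
#' @param mode `"hierarchical"` or `"full"`; see [count_experiment()].
#' @param config_args extra arguments passed to every [sim_config()].
#' @return A list with `threshold`, `rates`, `counts` (tibble) and `test`
#'   (Welch t-test between the first two fractions; `NULL` if only one).
#' @export
run_lod_study <- function(rep_seeds = 1:6, n_molecules = 1e5,
                          fractions = c(1e-4, 0), n_replicates = 3,
                          n_cal_train = 2000, cal_seed = 9001L,
                          rates_seed = 9101L, n_rates_wt = 4000,
                          n_rates_snv = 2000,
                          mode = c("hierarchical", "full"),
                          config_args = list()) {
  mode <- match.arg(mode)
  cfg_tr <- do.call(sim_config, c(list(n_molecules = n_cal_train,
                                       snv_fraction = 0, seed = cal_seed),
                                  config_args))
  s_tr <- summarize_population(simulate_population(cfg_tr))
  thr <- calibrate_threshold(apply_universal_threshold(s_tr)$candidates)
  rates <- if (mode == "hierarchical") {
    measure_assay_rates(thr, n_wt = n_rates_wt, n_snv = n_rates_snv,
                        seed = rates_seed, config_args = config_args)
  }
  counts <- count_experiment(fractions, n_molecules, n_replicates, thr,
                             seeds = rep_seeds, mode = mode, rates = rates,
                             config_args = config_args)
  test <- if (length(fractions) >= 2) {
    compare_fractions_ttest(
      counts$snv_count[counts$fraction == fractions[1]],
      counts$snv_count[counts$fraction == fractions[2]])
  }
  list(threshold = thr, rates = rates, counts = counts, test = test)
}

#' Train/test specificity study on wild-type-only populations
#'
#' Simulates an independent WT-only training and test set, calibrates the
#' bound-time threshold on the training candidates (max + 3 sd rule), runs
#' the full pipeline on the test set, and reports the specificity: the
#' fraction of true-WT test molecules not called SNV (molecules removed by
#' the universal filter are correctly not called).
#'
#' @param n_train,n_test population sizes (target molecules).
#' @param seed_train,seed_test independent seeds.
#' @param config_args extra arguments passed to [sim_config()].
#' @return A list with `threshold`, `specificity` (in `[0, 1]`),
#'   `n_false_positive`, `n_test`.
#' @export
specificity_study <- function(n_train = 500, n_test = 500, seed_train = 1L,
                              seed_test = 2L, config_args = list()) {
  cfg_tr <- do.call(sim_config, c(list(n_molecules = n_train,
                                       snv_fraction = 0, seed = seed_train),
                                  config_args))
  s_tr <- summarize_population(simulate_population(cfg_tr))
  thr <- calibrate_threshold(apply_universal_threshold(s_tr)$candidates)

  cfg_te <- do.call(sim_config, c(list(n_molecules = n_test,
                                       snv_fraction = 0, seed = seed_test),
                                  config_args))
  pop_te <- simulate_population(cfg_te)
  cls <- classify_population(pop_te, thr)
  m <- merge(cls, pop_te$truth[, c("molecule_id", "class")],
             by = "molecule_id")
  wt <- m[m$class == "WT", ]
  n_fp <- sum(wt$label == "SNV")
  list(threshold = thr, specificity = 1 - n_fp / nrow(wt),
       n_false_positive = n_fp, n_test = nrow(wt))
}
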