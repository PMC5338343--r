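test_that("digital counts tally labels exactly and ignore row order", {
  labels <- c(rep("WT", 5), rep("SNV", 2), "background")
  cnt <- count_positives(labels, condition = "0.01%")
  expect_equal(cnt$snv_count, 2L)
  expect_equal(cnt$wt_count, 5L)
  expect_equal(cnt$background_count, 1L)
  expect_equal(cnt$snv_count + cnt$wt_count + cnt$background_count,
               cnt$n_total)
  expect_equal(count_positives(sample(labels))$snv_count, 2L)
  expect_equal(count_positives(rep("WT", 4))$snv_count, 0L)
})

test_that("fraction calibration recovers exact and noisy linear relationships", {
  f <- c(0, 1e-4, 1e-3, 1e-2)
  fit <- fit_fraction_calibration(f, 1000 * f + 2)
  expect_equal(fit$slope, 1000)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_fraction_calibration(c(0, 0, 0), c(1, 2, 3)),
               "3 distinct")

  # Poisson-noised counts: slope recovered within 10%
  set.seed(85)
  slope_true <- 8e4  # n_molecules x sensitivity
  counts <- rpois(length(f) * 3, lambda = rep(slope_true * f + 1, 3))
  fit2 <- fit_fraction_calibration(rep(f, 3), counts)
  expect_lt(abs(fit2$slope - slope_true) / slope_true, 0.10)
})

test_that("Welch test matches stats::t.test and the permutation oracle", {
  a <- c(10, 12, 11); b <- c(0, 0, 1)
  w <- compare_fractions_ttest(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p_value, ref$p.value)
  expect_lt(w$p_value, 0.01)
  # the observed split is the most extreme of all relabelings
  expect_equal(oracle_permutation_p(a, b), 1 / choose(6, 3) * 2)

  # symmetry
  w_swap <- compare_fractions_ttest(b, a)
  expect_equal(w_swap$p_value, w$p_value)
  expect_equal(w_swap$statistic, -w$statistic)

  # degenerate inputs
  expect_equal(compare_fractions_ttest(c(5, 5), c(5, 5))$p_value, 1)
  expect_equal(compare_fractions_ttest(c(5, 5), c(7, 7))$p_value, 0)
  expect_error(compare_fractions_ttest(5, c(1, 2)), "2 replicates")
})

test_that("classify_population gives every molecule exactly one label", {
  cfg <- sim_config(n_molecules = 60, snv_fraction = 0.5, seed = 87)
  pop <- simulate_population(cfg)
  cls <- classify_population(pop, threshold_rule(6.8))
  expect_equal(nrow(cls), nrow(pop$truth))
  expect_setequal(cls$molecule_id, pop$truth$molecule_id)
  expect_true(all(cls$label %in% c("SNV", "WT", "background")))
})

test_that("hierarchical and full count experiments agree at the count level", {
  thr <- threshold_rule(6.8)
  rates <- measure_assay_rates(thr, n_wt = 400, n_snv = 400, seed = 89)
  expect_gt(rates$sensitivity, 0.5)
  expect_lt(rates$fp_rate, 0.02)

  n <- 3000; f <- 0.02
  hier <- count_experiment(f, n, n_replicates = 6, threshold = thr,
                           seeds = 101:106, rates = rates)
  full <- count_experiment(f, n, n_replicates = 2, threshold = thr,
                           seeds = 201:202, mode = "full")
  lam_hier <- mean(hier$snv_count)
  lam_full <- mean(full$snv_count)
  expected <- n * f * rates$sensitivity + n * (1 - f) * rates$fp_rate
  # both modes track the expected count within Poisson-scale error
  expect_lt(abs(lam_hier - expected), 4 * sqrt(expected / 6))
  expect_lt(abs(lam_full - expected), 4 * sqrt(expected / 2) + 0.1 * expected)
})

test_that("replicate counts stay inside Poisson envelopes across many seeds", {
  thr <- threshold_rule(6.8)
  rates <- measure_assay_rates(thr, n_wt = 600, n_snv = 400, seed = 91)
  n <- 1e5; f <- 1e-3
  cnts <- count_experiment(f, n, n_replicates = 50, threshold = thr,
                           seeds = 301:350, rates = rates)$snv_count
  lambda <- n * f * rates$sensitivity + n * (1 - f) * rates$fp_rate
  lo <- qpois(0.005, lambda); hi <- qpois(0.995, lambda)
  # ~Binomial(50, 0.01) excursions expected
  expect_lte(sum(cnts < lo | cnts > hi), 3)
})

test_that("run reports are complete, valid and byte-identical on regeneration", {
  dir <- withr::local_tempdir()
  thr <- threshold_rule(6.8)
  counts <- tibble::tibble(fraction = c(1e-4, 0), replicate = c(1L, 1L),
                           seed = c(1L, 2L), snv_count = c(9L, 0L))
  res <- list(seeds = c(1L, 2L), filter = filter_rule(), threshold = thr,
              counts = counts,
              tests = list(`1e-4_vs_0` = compare_fractions_ttest(
                c(9, 11, 10), c(0, 1, 0))))
  p1 <- generate_report(res, dir, name = "run1")
  p2 <- generate_report(res, dir, name = "run2")
  expect_identical(readLines(p1["json"]), readLines(p2["json"]))
  expect_identical(readLines(p1["md"]), readLines(p2["md"]))
  parsed <- jsonlite::read_json(p1[["json"]], simplifyVector = TRUE)
  expect_equal(parsed$seeds, c(1L, 2L))          # every seed recorded
  expect_equal(parsed$threshold$threshold, 6.8)
  expect_equal(parsed$filter$min_transitions, 12)

  # empty run still produces a valid report
  p0 <- generate_report(list(), dir, name = "empty")
  parsed0 <- jsonlite::read_json(p0[["json"]], simplifyVector = TRUE)
  expect_length(parsed0$seeds, 0)
})
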