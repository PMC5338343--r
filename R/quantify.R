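#' Tally classified molecules for one condition
#'
#' Digital counting: each molecule contributes exactly one count to its
#' label ("SNV", "WT" or "background"), never intensity-weighted. The
#' tallies are invariant to input row order.
#'
#' @param labels character vector of per-molecule labels, or a tibble with
#'   a `label` column.
#' @param condition condition identifier carried through to the result.
#' @param replicate replicate identifier.
#' @return A one-row tibble: `condition`, `replicate`, `snv_count`,
#'   `wt_count`, `background_count`, `n_total`.
#' @export
count_positives <- function(labels, condition = NA, replicate = NA) {
  if (is.data.frame(labels)) labels <- labels$label
  tibble::tibble(condition = condition, replicate = replicate,
                 snv_count = sum(labels == "SNV"),
                 wt_count = sum(labels == "WT"),
                 background_count = sum(labels == "background"),
                 n_total = length(labels))
}

#' Linear calibration of positive counts against mutant fraction
#'
#' Ordinary least squares of positive SNV counts on the spiked mutant
#' fraction; the intercept estimates the false-positive count floor at
#' fraction 0.
#'
#' @param fractions mutant fractions (>= 3 distinct levels).
#' @param counts positive SNV counts at each fraction.
#' @return A list of class `kinfp_calibration`: `slope` (counts per unit
#'   fraction), `intercept` (counts), `r_squared`, `fit`.
#' @export
fit_fraction_calibration <- function(fractions, counts) {
  if (length(fractions) != length(counts)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (length(unique(fractions)) < 3L) {
    stop("calibration needs at least 3 distinct fraction levels",
         call. = FALSE)
  }
  fit <- stats::lm(counts ~ fractions)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "kinfp_calibration")
}

#' Welch two-sample t-test between replicate count sets
#'
#' Two-sided Welch (unequal variance) t-test comparing positive counts
#' between two conditions. Degenerate inputs are handled explicitly: if
#' both groups have zero variance, p is 1 for equal means and 0 otherwise;
#' if one group has zero variance the Welch statistic is still defined.
#'
#' @param counts_a,counts_b replicate counts (>= 2 each).
#' @return A list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
compare_fractions_ttest <- function(counts_a, counts_b) {
  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("each condition needs at least 2 replicates", call. = FALSE)
  }
  na <- length(counts_a); nb <- length(counts_b)
  ma <- mean(counts_a); mb <- mean(counts_b)
  va <- stats::var(counts_a); vb <- stats::var(counts_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    return(list(statistic = if (ma == mb) 0 else Inf,
                df = na + nb - 2,
                p_value = if (ma == mb) 1 else 0,
                mean_a = ma, mean_b = mb, method = "Welch two-sample t"))
  }
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  list(statistic = stat, df = df, p_value = p, mean_a = ma, mean_b = mb,
       method = "Welch two-sample t")
}

#' Classify every molecule of a simulated or measured population
#'
#' One-call pipeline stage: idealize all traces, apply the universal
#' background filter, and classify the surviving candidates with the
#' bound-time threshold. Every input molecule receives exactly one label:
#' `"background"`, `"WT"` or `"SNV"`.
#'
#' @param pop a `kinfp_population` (or anything [summarize_population()]
#'   accepts, plus `frame_dt`).
#' @param threshold a [threshold_rule()].
#' @param filter a [filter_rule()].
#' @param frame_dt frame interval for non-population input.
#' @return A tibble: the population summary plus a `label` column.
#' @export
classify_population <- function(pop, threshold, filter = filter_rule(),
                                frame_dt = NULL) {
  summaries <- summarize_population(pop, frame_dt = frame_dt)
  split <- apply_universal_threshold(summaries, filter)
  cand <- classify_by_threshold(split$candidates, threshold)
  bg <- split$background
  if (nrow(bg) > 0) bg$label <- "background"
  out <- rbind(cand, bg)
  out[order(match(out$molecule_id, summaries$molecule_id)), , drop = FALSE]
}

#' Measure per-molecule classification rates on labeled simulations
#'
#' Runs the trace-level pipeline on a WT-only null and an SNV-only sample
#' and measures, per true target molecule, the probability of an SNV call:
#' the false-positive rate (WT null) and the sensitivity (SNV sample).
#' Denominators are all simulated target molecules of the class, so
#' molecules removed by the universal filter count as "not called SNV".
#'
#' @param threshold a [threshold_rule()].
#' @param n_wt,n_snv null/sample sizes (target molecules).
#' @param seed integer seed.
#' @param config_args extra arguments passed to [sim_config()].
#' @return A list with `fp_rate`, `sensitivity`, `n_wt`, `n_snv`.
#' @export
measure_assay_rates <- function(threshold, n_wt = 2000, n_snv = 1000,
                                seed = 1L, config_args = list()) {
  run <- function(n, frac, sd) {
    cfg <- do.call(sim_config, c(list(n_molecules = n, snv_fraction = frac,
                                      seed = sd), config_args))
    pop <- simulate_population(cfg)
    cls <- classify_population(pop, threshold)
    merge(cls, pop$truth[, c("molecule_id", "class")], by = "molecule_id")
  }
  wt <- run(n_wt, 0, seed)
  snv <- run(n_snv, 1, seed + 1L)
  list(fp_rate = sum(wt$label == "SNV" & wt$class == "WT") /
         sum(wt$class == "WT"),
       sensitivity = sum(snv$label == "SNV" & snv$class == "SNV") /
         sum(snv$class == "SNV"),
       n_wt = n_wt, n_snv = n_snv)
}

#' Simulate a replicated digital counting experiment
#'
#' For each mutant fraction and replicate, draws a population of
#' `n_molecules` target molecules and counts SNV-positive calls at the
#' given threshold. Two modes:
#' \describe{
#'   \item{`"full"`}{every replicate runs the complete trace-level pipeline
#'     (simulate, idealize, filter, classify) on all `n_molecules`
#'     molecules, in memory-bounded chunks.}
#'   \item{`"hierarchical"`}{per-molecule call probabilities (sensitivity
#'     and false-positive rate) are first measured with
#'     [measure_assay_rates()] on trace-level calibration samples, then
#'     each replicate's count is drawn at the molecule level as
#'     `Binomial(n_SNV, sensitivity) + Binomial(n_WT, fp_rate)` with
#'     `n_SNV ~ Binomial(n_molecules, fraction)`. Because molecules are
#'     statistically independent, this is distributionally equivalent to
#'     the full pipeline at the count level while scaling to very large
#'     populations.}
#' }
#'
#' @param fractions mutant fractions to simulate, one condition each.
#' @param n_molecules target molecules per replicate.
#' @param n_replicates replicates per condition.
#' @param threshold a [threshold_rule()].
#' @param seeds integer matrix/vector of per-replicate seeds, filled
#'   condition-major; defaults to `1:(length(fractions) * n_replicates)`.
#' @param mode `"hierarchical"` (default) or `"full"`.
#' @param rates optional precomputed result of [measure_assay_rates()]
#'   (hierarchical mode).
#' @param cal_seed calibration seed (hierarchical mode).
#' @param config_args extra arguments passed to [sim_config()].
#' @param chunk_size molecules per chunk in full mode.
#' @return A tibble with one row per replicate: `fraction`, `replicate`,
#'   `seed`, `snv_count`, `wt_count`, `background_count`, `n_total`.
#' @export
count_experiment <- function(fractions, n_molecules, n_replicates, threshold,
                             seeds = NULL,
                             mode = c("hierarchical", "full"),
                             rates = NULL, cal_seed = 1000L,
                             config_args = list(), chunk_size = 20000L) {
  mode <- match.arg(mode)
  n_runs <- length(fractions) * n_replicates
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  seeds <- as.integer(seeds)
  stopifnot(length(seeds) == n_runs)
  if (mode == "hierarchical" && is.null(rates)) {
    rates <- measure_assay_rates(threshold, seed = cal_seed,
                                 config_args = config_args)
  }
  rows <- list()
  run <- 0L
  for (ci in seq_along(fractions)) {
    f <- fractions[ci]
    for (r in seq_len(n_replicates)) {
      run <- run + 1L
      sd_r <- seeds[run]
      if (mode == "hierarchical") {
        set.seed(sd_r)
        n_snv <- rbinom(1, n_molecules, f)
        snv_pos <- rbinom(1, n_snv, rates$sensitivity)
        wt_pos <- rbinom(1, n_molecules - n_snv, rates$fp_rate)
        rows[[run]] <- tibble::tibble(
          fraction = f, replicate = r, seed = sd_r,
          snv_count = snv_pos + wt_pos,
          wt_count = NA_integer_, background_count = NA_integer_,
          n_total = n_molecules)
      } else {
        cnt <- c(SNV = 0L, WT = 0L, background = 0L)
        n_total <- 0L
        chunk_seeds <- molecule_seeds(sd_r, ceiling(n_molecules / chunk_size))
        left <- n_molecules
        ch <- 0L
        while (left > 0L) {
          ch <- ch + 1L
          n_ch <- min(chunk_size, left)
          cfg <- do.call(sim_config,
                         c(list(n_molecules = n_ch, snv_fraction = f,
                                seed = chunk_seeds[ch]), config_args))
          pop <- simulate_population(cfg)
          cls <- classify_population(pop, threshold)
          tab <- table(cls$label)
          for (nm in names(tab)) cnt[nm] <- cnt[nm] + tab[[nm]]
          n_total <- n_total + nrow(cls)
          left <- left - n_ch
        }
        rows[[run]] <- tibble::tibble(
          fraction = f, replicate = r, seed = sd_r,
          snv_count = as.integer(cnt[["SNV"]]),
          wt_count = as.integer(cnt[["WT"]]),
          background_count = as.integer(cnt[["background"]]),
          n_total = n_total)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rates") <- rates
  attr(out, "mode") <- mode
  out
}

#' Write a machine- and human-readable run report
#'
#' Serializes a run's provenance (configs, seeds, filter and threshold
#' rules) and its results (counts, calibration fit, significance tests)
#' as one JSON file and one Markdown file. Regenerating the report from
#' the same inputs is byte-identical.
#'
#' @param results a named list; recognized elements are `config` (list),
#'   `seeds` (integer vector), `filter` ([filter_rule()]), `threshold`
#'   ([threshold_rule()]), `counts` (tibble), `calibration`
#'   ([fit_fraction_calibration()] result), `tests` (list of
#'   [compare_fractions_ttest()] results). Missing elements produce valid
#'   empty sections.
#' @param dir output directory.
#' @param name base file name.
#' @return Invisibly, `c(json = path, md = path)`.
#' @export
generate_report <- function(results, dir, name = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, paste0(name, ".json"))
  md_path <- file.path(dir, paste0(name, ".md"))

  ser <- list(
    config = if (!is.null(results$config)) results$config else list(),
    seeds = if (!is.null(results$seeds)) as.integer(results$seeds)
            else integer(0),
    filter = if (!is.null(results$filter)) unclass(results$filter)
             else list(),
    threshold = if (!is.null(results$threshold))
      unclass(results$threshold) else list(),
    counts = if (!is.null(results$counts))
      as.data.frame(results$counts) else data.frame(),
    calibration = if (!is.null(results$calibration))
      results$calibration[c("slope", "intercept", "r_squared")] else list(),
    tests = if (!is.null(results$tests)) lapply(results$tests, function(tt)
      tt[c("statistic", "df", "p_value", "method")]) else list())
  jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  lines <- c("# Digital counting run report", "")
  lines <- c(lines, "## Seeds", "",
             if (length(ser$seeds)) paste0("- ", ser$seeds) else "- (none)",
             "")
  lines <- c(lines, "## Filter / threshold", "",
             paste0("- filter: ", jsonlite::toJSON(ser$filter,
                                                   auto_unbox = TRUE)),
             paste0("- threshold: ", jsonlite::toJSON(ser$threshold,
                                                      auto_unbox = TRUE)),
             "")
  lines <- c(lines, "## Counts", "")
  if (nrow(ser$counts)) {
    hdr <- paste(names(ser$counts), collapse = " | ")
    sep <- paste(rep("---", ncol(ser$counts)), collapse = " | ")
    body <- apply(ser$counts, 1, function(rw) paste(rw, collapse = " | "))
    lines <- c(lines, paste0("| ", hdr, " |"), paste0("| ", sep, " |"),
               paste0("| ", body, " |"))
  } else {
    lines <- c(lines, "(none)")
  }
  lines <- c(lines, "", "## Calibration", "",
             if (length(ser$calibration)) {
               sprintf("- slope = %s counts/unit fraction, intercept = %s, R^2 = %s",
                       format(ser$calibration$slope),
                       format(ser$calibration$intercept),
                       format(ser$calibration$r_squared))
             } else "(none)",
             "", "## Tests", "")
  if (length(ser$tests)) {
    for (nm in names(ser$tests)) {
      tt <- ser$tests[[nm]]
      lines <- c(lines, sprintf("- %s: t = %s, df = %s, p = %s", nm,
                                format(tt$statistic), format(tt$df),
                                format(tt$p_value)))
    }
  } else {
    lines <- c(lines, "(none)")
  }
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}
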