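#' Universal background filter rule
#'
#' Non-specific surface binders show many fewer productive events and much
#' shorter dwells than true targets. The universal filter keeps a molecule
#' as a candidate only if it has at least `min_transitions` binding +
#' dissociation events AND mean bound and unbound dwells of at least
#' `min_tau_bound` / `min_tau_unbound` seconds (boundaries inclusive).
#' Defaults are 12 transitions and 3 s / 3 s.
#'
#' @param min_transitions minimum number of state changes.
#' @param min_tau_bound,min_tau_unbound minimum mean dwell times, seconds.
#' @return A list of class `kinfp_filter_rule`.
#' @export
filter_rule <- function(min_transitions = 12, min_tau_bound = 3,
                        min_tau_unbound = 3) {
  structure(list(min_transitions = min_transitions,
                 min_tau_bound = min_tau_bound,
                 min_tau_unbound = min_tau_unbound),
            class = "kinfp_filter_rule")
}

#' Apply the universal background filter to a population summary
#'
#' Molecules whose dwell statistics fail any of the filter's three
#' conditions -- including molecules with missing mean dwells because they
#' never changed state -- are labeled background; the rest are candidates
#' for classification.
#'
#' @param summaries tibble from [summarize_population()].
#' @param rule a [filter_rule()].
#' @return A list with tibbles `candidates` and `background`.
#' @export
apply_universal_threshold <- function(summaries, rule = filter_rule()) {
  stopifnot(inherits(rule, "kinfp_filter_rule"))
  ok <- !is.na(summaries$tau_bound_mean) &
    !is.na(summaries$tau_unbound_mean) &
    summaries$n_transitions >= rule$min_transitions &
    summaries$tau_bound_mean >= rule$min_tau_bound &
    summaries$tau_unbound_mean >= rule$min_tau_unbound
  list(candidates = summaries[ok, , drop = FALSE],
       background = summaries[!ok, , drop = FALSE])
}

#' Bound-time classification threshold
#'
#' @param threshold bound-dwell mean threshold, seconds (> 0).
#' @param provenance `"fixed"` or `"calibrated-from-WT-null"`.
#' @param n_train number of molecules the calibration used, if any.
#' @return A list of class `kinfp_threshold_rule`.
#' @export
threshold_rule <- function(threshold, provenance = "fixed", n_train = NA) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  structure(list(threshold = threshold, provenance = provenance,
                 n_train = n_train),
            class = "kinfp_threshold_rule")
}

#' Calibrate the bound-time threshold from a wild-type-only null
#'
#' The stringent threshold rule places the decision boundary at the maximum
#' per-molecule mean bound dwell observed in a WT-only sample plus three
#' standard deviations of those per-molecule means:
#' `threshold = max(tau_bound_mean) + n_sd * sd(tau_bound_mean)`
#' (sample, n-1, standard deviation). Molecules with missing bound means
#' are ignored; at least two informative molecules are required.
#'
#' @param wt_summaries summary tibble of WT-only candidate molecules.
#' @param n_sd number of standard deviations above the observed maximum.
#' @return A [threshold_rule()] with provenance `"calibrated-from-WT-null"`.
#' @export
calibrate_threshold <- function(wt_summaries, n_sd = 3) {
  tb <- wt_summaries$tau_bound_mean
  tb <- tb[!is.na(tb)]
  if (length(tb) < 2L) {
    stop("threshold calibration needs at least 2 WT molecules", call. = FALSE)
  }
  threshold_rule(max(tb) + n_sd * stats::sd(tb),
                 provenance = "calibrated-from-WT-null",
                 n_train = length(tb))
}

#' Classify candidate molecules by their mean bound dwell
#'
#' A candidate is called SNV iff its mean bound dwell strictly exceeds the
#' threshold (a molecule exactly at the threshold is called WT; the strict
#' rule is conservative toward specificity).
#'
#' @param candidates candidate tibble from [apply_universal_threshold()].
#' @param rule a [threshold_rule()].
#' @return The input tibble with a `label` column (`"SNV"`/`"WT"`).
#' @export
classify_by_threshold <- function(candidates, rule) {
  stopifnot(inherits(rule, "kinfp_threshold_rule"))
  out <- candidates
  out$label <- ifelse(out$tau_bound_mean > rule$threshold, "SNV", "WT")
  out
}

#' Sensitivity/specificity of the bound-time threshold over a grid
#'
#' For each threshold, molecules with mean bound dwell above it are called
#' positive (SNV). Sensitivity is `TP/(TP+FN)` over the true-SNV bound
#' means, specificity `TN/(TN+FP)` over the true-WT ones; accuracy is the
#' overall fraction of correct calls. Empty classes give `NA` for their
#' metric.
#'
#' @param snv_tau_bound,wt_tau_bound per-molecule mean bound dwells of
#'   ground-truth SNV and WT molecules, seconds.
#' @param thresholds numeric vector of thresholds, seconds.
#' @return A tibble with `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
sensitivity_specificity_curve <- function(snv_tau_bound, wt_tau_bound,
                                          thresholds) {
  snv_tau_bound <- snv_tau_bound[!is.na(snv_tau_bound)]
  wt_tau_bound <- wt_tau_bound[!is.na(wt_tau_bound)]
  n_s <- length(snv_tau_bound)
  n_w <- length(wt_tau_bound)
  sens <- spec <- acc <- rep(NA_real_, length(thresholds))
  for (i in seq_along(thresholds)) {
    tp <- sum(snv_tau_bound > thresholds[i])
    tn <- sum(wt_tau_bound <= thresholds[i])
    if (n_s > 0) sens[i] <- tp / n_s
    if (n_w > 0) spec[i] <- tn / n_w
    if (n_s + n_w > 0) acc[i] <- (tp + tn) / (n_s + n_w)
  }
  tibble::tibble(threshold = thresholds, sensitivity = sens,
                 specificity = spec, accuracy = acc)
}

#' Two-cluster k-means on per-molecule bound times
#'
#' One-dimensional k-means on the candidates' mean bound dwells; the
#' cluster with the larger center is labeled SNV. The clustering is
#' deterministic given `seed`. If all bound times are identical the result
#' collapses to a single effective cluster and is flagged degenerate.
#'
#' @param candidates candidate tibble (needs `tau_bound_mean`).
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means starts.
#' @return A list with `labels` (`"SNV"`/`"WT"` for k = 2, else cluster
#'   index), `centers` (sorted increasing), `cluster` (integer vector into
#'   `centers`) and `degenerate`.
#' @export
kmeans_bound_times <- function(candidates, k = 2, seed = 1L) {
  x <- candidates$tau_bound_mean
  if (anyNA(x)) stop("`tau_bound_mean` contains NA", call. = FALSE)
  if (length(x) < k) {
    stop(sprintf("k-means with k = %d needs at least %d molecules", k, k),
         call. = FALSE)
  }
  if (length(unique(x)) == 1L) {
    return(list(labels = rep("WT", length(x)), centers = unique(x),
                cluster = rep(1L, length(x)), degenerate = TRUE))
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = min(k, length(unique(x))), nstart = 10)
  ord <- order(km$centers)
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  cl <- remap[km$cluster]
  centers <- sort(as.vector(km$centers))
  labels <- if (k == 2) ifelse(cl == 2L, "SNV", "WT") else as.character(cl)
  list(labels = labels, centers = centers, cluster = cl,
       degenerate = length(centers) < k)
}
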