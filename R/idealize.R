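#' Idealize one intensity trace with a two-state hidden Markov model
#'
#' Fits a two-state HMM with Gaussian emissions by Baum-Welch, starting from
#' a deterministic two-way split of the intensities, and recovers the most
#' probable state path by Viterbi. The state with the higher fitted emission
#' mean is labeled bound (ties broken by smaller standard deviation, then
#' state index). A trace with zero intensity range carries no state
#' information and is returned as a flagged single-state (degenerate)
#' idealization; so is a trace whose two fitted emission levels are not
#' resolvable against the emission noise (separation below
#' `min_separation` pooled standard deviations), since a forced two-state
#' fit of effectively one-state data produces spurious long dwells from
#' noise alone.
#'
#' @param intensity numeric vector of per-frame intensities (>= 20 frames).
#' @param frame_dt frame interval, seconds.
#' @param max_iter,tol Baum-Welch iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param min_separation minimum resolvable distance between the two state
#'   means, in units of the pooled emission standard deviation.
#' @param seed unused (the fit is deterministic); accepted for interface
#'   stability.
#' @return An object of class `kinfp_ideal`: `bound` (logical per frame),
#'   `frame_dt`, emission parameters `mu_unbound`, `mu_bound`, `sd_unbound`,
#'   `sd_bound`, `loglik`, `converged`, `degenerate`.
#' @export
fit_two_state_hmm <- function(intensity, frame_dt, max_iter = 100,
                              tol = 1e-6, min_separation = 2, seed = NULL) {
  if (!is.numeric(intensity) || length(intensity) < 20L) {
    stop("`intensity` must be numeric with at least 20 frames", call. = FALSE)
  }
  if (anyNA(intensity)) stop("`intensity` contains NA", call. = FALSE)
  if (frame_dt <= 0) stop("`frame_dt` must be positive", call. = FALSE)
  fit <- fit_hmm2_cpp(as.numeric(intensity), as.integer(max_iter), tol)
  if (isTRUE(fit$degenerate)) {
    return(structure(list(bound = rep(FALSE, length(intensity)),
                          frame_dt = frame_dt,
                          mu_unbound = fit$mu[1], mu_bound = fit$mu[2],
                          sd_unbound = 0, sd_bound = 0,
                          loglik = NA_real_, converged = TRUE,
                          degenerate = TRUE),
                     class = "kinfp_ideal"))
  }
  # label the bound state: higher mean, then smaller sd, then lower index
  if (fit$mu[1] > fit$mu[2] ||
      (fit$mu[1] == fit$mu[2] && fit$sd[1] < fit$sd[2])) {
    bound_state <- 0L
  } else {
    bound_state <- 1L
  }
  bound <- fit$states == bound_state
  idx <- if (bound_state == 1L) c(1L, 2L) else c(2L, 1L)  # (unbound, bound)
  sep <- abs(diff(fit$mu)) / sqrt(mean(fit$sd^2))
  if (is.finite(sep) && sep < min_separation) {
    # unresolvable emission levels: treat as a flagged single-state trace
    return(structure(list(bound = rep(FALSE, length(intensity)),
                          frame_dt = frame_dt,
                          mu_unbound = fit$mu[idx[1]],
                          mu_bound = fit$mu[idx[2]],
                          sd_unbound = fit$sd[idx[1]],
                          sd_bound = fit$sd[idx[2]],
                          loglik = fit$loglik, converged = fit$converged,
                          degenerate = TRUE),
                     class = "kinfp_ideal"))
  }
  structure(list(bound = bound, frame_dt = frame_dt,
                 mu_unbound = fit$mu[idx[1]], mu_bound = fit$mu[idx[2]],
                 sd_unbound = fit$sd[idx[1]], sd_bound = fit$sd[idx[2]],
                 loglik = fit$loglik, converged = fit$converged,
                 degenerate = FALSE),
            class = "kinfp_ideal")
}

#' Extract dwell times from an idealized trace
#'
#' Runs of identical state become dwells; a dwell's duration is its run
#' length times the frame interval (half-open frame intervals, so durations
#' are positive multiples of `frame_dt`). The first and last dwells of a
#' trace are truncated by the acquisition window; with `censor_edges = TRUE`
#' (default) they are excluded from the mean dwell estimates but still
#' counted in `fraction_bound`.
#'
#' @param ideal a `kinfp_ideal` from [fit_two_state_hmm()].
#' @param censor_edges exclude edge dwells from mean-dwell estimates.
#' @return A list of class `kinfp_dwell_summary`: `dwells` (tibble with
#'   `state`, `start_s`, `end_s`, `duration`, `censored`), `n_transitions`,
#'   `tau_bound_mean`, `tau_unbound_mean` (NA when no eligible dwell),
#'   `fraction_bound`, `bound_dwells`, `unbound_dwells` (uncensored-only
#'   duration vectors), `degenerate`.
#' @export
extract_dwells <- function(ideal, censor_edges = TRUE) {
  stopifnot(inherits(ideal, "kinfp_ideal"))
  r <- rle(ideal$bound)
  k <- length(r$lengths)
  dt <- ideal$frame_dt
  end <- cumsum(r$lengths) * dt
  start <- end - r$lengths * dt
  censored <- seq_len(k) %in% c(1L, k)
  dwells <- tibble::tibble(
    state = ifelse(r$values, "bound", "unbound"),
    start_s = start, end_s = end, duration = r$lengths * dt,
    censored = censored)
  eligible <- if (censor_edges) !censored else rep(TRUE, k)
  b <- dwells$duration[eligible & r$values]
  u <- dwells$duration[eligible & !r$values]
  structure(list(
    dwells = dwells,
    n_transitions = k - 1L,
    tau_bound_mean = if (length(b)) mean(b) else NA_real_,
    tau_unbound_mean = if (length(u)) mean(u) else NA_real_,
    fraction_bound = sum(dwells$duration[r$values]) / sum(dwells$duration),
    bound_dwells = b, unbound_dwells = u,
    degenerate = isTRUE(ideal$degenerate)),
    class = "kinfp_dwell_summary")
}

#' Idealize and summarize a whole trace population
#'
#' Applies [fit_two_state_hmm()] and [extract_dwells()] to every molecule
#' and returns one tidy row per molecule. Per-molecule fit failures are
#' recorded (with a warning) and excluded rather than aborting the run.
#'
#' @param traces a frames-by-molecules intensity matrix, a
#'   `kinfp_population`, or a long trace table with columns `molecule_id`,
#'   `frame`, `intensity` (see [read_trace_table()]).
#' @param frame_dt frame interval in seconds (taken from the population
#'   object when one is supplied).
#' @param censor_edges see [extract_dwells()].
#' @param molecule_ids optional ids for matrix input (default `1:ncol`).
#' @inheritParams fit_two_state_hmm
#' @return A tibble with one row per molecule: `molecule_id`, `n_frames`,
#'   `n_transitions`, `n_bound_dwells`, `n_unbound_dwells`,
#'   `tau_bound_mean`, `tau_unbound_mean`, `fraction_bound`, `degenerate`.
#' @export
summarize_population <- function(traces, frame_dt = NULL, censor_edges = TRUE,
                                 molecule_ids = NULL, max_iter = 100,
                                 tol = 1e-6) {
  if (inherits(traces, "kinfp_population")) {
    frame_dt <- traces$frame_dt
    traces <- traces$intensity
  } else if (is.data.frame(traces)) {
    stopifnot(!is.null(frame_dt))
    traces <- traces_to_matrix(traces)
  }
  if (is.null(frame_dt)) stop("`frame_dt` is required for matrix input",
                              call. = FALSE)
  n <- ncol(traces)
  if (is.null(molecule_ids)) molecule_ids <- colnames(traces)
  if (is.null(molecule_ids)) molecule_ids <- seq_len(n)
  n_frames_v <- n_trans <- n_bd <- n_ud <- integer(n)
  tau_b <- tau_u <- frac_b <- numeric(n)
  degen <- ok <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      ideal <- fit_two_state_hmm(traces[, i], frame_dt,
                                 max_iter = max_iter, tol = tol)
      r <- rle(ideal$bound)
      k <- length(r$lengths)
      dt <- frame_dt
      eligible <- if (censor_edges && k > 1L) {
        !(seq_len(k) %in% c(1L, k))
      } else if (censor_edges) {
        FALSE
      } else {
        rep(TRUE, k)
      }
      b <- r$lengths[eligible & r$values] * dt
      u <- r$lengths[eligible & !r$values] * dt
      n_frames_v[i] <- length(ideal$bound)
      n_trans[i] <- k - 1L
      n_bd[i] <- length(b)
      n_ud[i] <- length(u)
      tau_b[i] <- if (length(b)) mean(b) else NA_real_
      tau_u[i] <- if (length(u)) mean(u) else NA_real_
      frac_b[i] <- sum(r$lengths[r$values]) / sum(r$lengths)
      degen[i] <- isTRUE(ideal$degenerate)
      TRUE
    }, error = function(e) FALSE)
    ok[i] <- isTRUE(res)
  }
  if (any(!ok)) {
    warning(sprintf("%d molecule(s) failed idealization and were excluded",
                    sum(!ok)), call. = FALSE)
  }
  tibble::tibble(molecule_id = molecule_ids, n_frames = n_frames_v,
                 n_transitions = n_trans, n_bound_dwells = n_bd,
                 n_unbound_dwells = n_ud, tau_bound_mean = tau_b,
                 tau_unbound_mean = tau_u, fraction_bound = frac_b,
                 degenerate = degen)[ok, , drop = FALSE]
}
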