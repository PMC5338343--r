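#' Gamma model of the per-molecule total bound time
#'
#' Over an acquisition of `t` seconds, a molecule with mean bound dwell
#' `tau_bound` and mean unbound dwell `tau_unbound` completes on average
#' `k = t / (tau_bound + tau_unbound)` binding events. The total bound time
#' accumulated over those events -- a sum of k exponential dwells of mean
#' `tau_bound` -- follows a gamma distribution with shape `k` and rate
#' `theta = 1 / tau_bound`, so the per-molecule *mean* bound dwell (total
#' bound time divided by k) has mean `tau_bound` and standard deviation
#' `tau_bound / sqrt(k)`. `k` is treated as continuous (it is an expected
#' count).
#'
#' @param tau_bound,tau_unbound mean dwell times, seconds.
#' @param t acquisition time, seconds.
#' @return A list of class `kinfp_gamma_model` with `k`, `theta`
#'   (rate of the total-bound-time gamma, per second), `tau_bound`,
#'   `tau_unbound`, `t`, and `sd_mean_bound = tau_bound / sqrt(k)`.
#' @export
gamma_model <- function(tau_bound, tau_unbound, t) {
  if (tau_bound <= 0 || tau_unbound <= 0 || t <= 0) {
    stop("`tau_bound`, `tau_unbound` and `t` must be positive", call. = FALSE)
  }
  k <- expected_event_count(tau_bound, tau_unbound, t)
  structure(list(k = k, theta = 1 / tau_bound, tau_bound = tau_bound,
                 tau_unbound = tau_unbound, t = t,
                 sd_mean_bound = tau_bound / sqrt(k)),
            class = "kinfp_gamma_model")
}

#' Gamma density of a state dwell-time sum
#'
#' Standard gamma density with shape `k` and rate `theta`; with `k = 1` it
#' reduces to the exponential density `theta * exp(-theta * x)`.
#'
#' @param x dwell time(s), seconds (>= 0).
#' @param model a [gamma_model()], or `NULL` if `k` and `theta` are given.
#' @param k,theta shape (dimensionless) and rate (per second) overriding
#'   `model`.
#' @return Density values.
#' @export
gamma_dwell_pdf <- function(x, model = NULL, k = model$k,
                            theta = model$theta) {
  if (is.null(k) || is.null(theta) || k <= 0 || theta <= 0) {
    stop("`k` and `theta` must be positive", call. = FALSE)
  }
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  dgamma(x, shape = k, rate = theta)
}

#' Expected number of binding events in an acquisition
#'
#' `k = t / (tau_bound + tau_unbound)`: the mean number of binding (and
#' dissociation) events a molecule completes in `t` seconds at equilibrium.
#'
#' @inheritParams gamma_model
#' @return Expected event count (dimensionless; 0 when `t = 0`).
#' @export
expected_event_count <- function(tau_bound, tau_unbound, t) {
  if (tau_bound <= 0 || tau_unbound <= 0 || t < 0) {
    stop("dwell means must be positive and `t` non-negative", call. = FALSE)
  }
  t / (tau_bound + tau_unbound)
}

#' Named dwell-mean pair for one target class
#'
#' @param tau_bound,tau_unbound mean dwell times, seconds.
#' @return Named numeric vector `c(tau_bound=, tau_unbound=)`.
#' @export
dwell_means <- function(tau_bound, tau_unbound) {
  if (tau_bound <= 0 || tau_unbound <= 0) {
    stop("dwell means must be positive", call. = FALSE)
  }
  c(tau_bound = tau_bound, tau_unbound = tau_unbound)
}

as_dwell_means <- function(x) {
  if (inherits(x, "kinfp_rates")) {
    return(dwell_means(tau_bound(x), tau_unbound(x)))
  }
  x <- unlist(x)
  if (length(x) != 2L) stop("expected (tau_bound, tau_unbound)", call. = FALSE)
  if (is.null(names(x)) || !all(c("tau_bound", "tau_unbound") %in% names(x))) {
    names(x) <- c("tau_bound", "tau_unbound")
  }
  dwell_means(x[["tau_bound"]], x[["tau_unbound"]])
}

sigma_combine <- function(s_snv, s_wt, rule) {
  switch(rule,
         sum = s_snv + s_wt,
         max = max(s_snv, s_wt),
         pooled = sqrt((s_snv^2 + s_wt^2) / 2))
}

#' Discrimination capability factor n
#'
#' The number of (combined) standard deviations separating the SNV and WT
#' per-molecule mean bound dwell distributions under the gamma model after
#' `t` seconds of acquisition:
#' `n = (tau_b_SNV - tau_b_WT) / (sigma_SNV + sigma_WT)` with
#' `sigma_i = tau_b_i / sqrt(k_i)` and `k_i = t / (tau_b_i + tau_u_i)`.
#' `n` grows as `sqrt(t)` for fixed kinetics and is 0 when the two classes
#' share a mean bound dwell. If the WT bound dwell exceeds the SNV one the
#' classes are swapped with a warning (n is reported as a magnitude).
#'
#' @param snv,wt dwell means of each class: a [dwell_means()] pair, a
#'   2-vector `(tau_bound, tau_unbound)`, or a [rate_set()].
#' @param t acquisition time, seconds (> 0).
#' @param sigma_rule how to combine the two class standard deviations:
#'   `"sum"` (default; yields the closed-form acquisition-time inversion),
#'   `"max"`, or `"pooled"`.
#' @return n (dimensionless, >= 0).
#' @export
discrimination_factor <- function(snv, wt, t,
                                  sigma_rule = c("sum", "max", "pooled")) {
  sigma_rule <- match.arg(sigma_rule)
  if (!is.numeric(t) || length(t) != 1L || t <= 0) {
    stop("`t` must be a single positive number", call. = FALSE)
  }
  s <- as_dwell_means(snv)
  w <- as_dwell_means(wt)
  if (s[["tau_bound"]] == w[["tau_bound"]]) return(0)
  if (s[["tau_bound"]] < w[["tau_bound"]]) {
    warning("SNV bound dwell below WT; classes swapped, n reported as a ",
            "magnitude", call. = FALSE)
    tmp <- s; s <- w; w <- tmp
  }
  k_s <- expected_event_count(s[["tau_bound"]], s[["tau_unbound"]], t)
  k_w <- expected_event_count(w[["tau_bound"]], w[["tau_unbound"]], t)
  sig_s <- s[["tau_bound"]] / sqrt(k_s)
  sig_w <- w[["tau_bound"]] / sqrt(k_w)
  (s[["tau_bound"]] - w[["tau_bound"]]) / sigma_combine(sig_s, sig_w,
                                                        sigma_rule)
}

#' Acquisition time required for a target discrimination factor
#'
#' Closed-form inversion of [discrimination_factor()] (with the `"sum"`
#' sigma rule):
#' `t = (n * (tau_bS * sqrt(tau_bS + tau_uS) + tau_bW * sqrt(tau_bW + tau_uW))
#'        / (tau_bS - tau_bW))^2`.
#' Round-trips with `discrimination_factor()` to machine precision. Equal
#' bound dwells cannot be separated in finite time and raise an error;
#' `n_target = 0` needs no time at all.
#'
#' @inheritParams discrimination_factor
#' @param n_target target discrimination factor (>= 0).
#' @return Required acquisition time, seconds.
#' @export
required_acquisition_time <- function(snv, wt, n_target) {
  if (n_target < 0) stop("`n_target` must be non-negative", call. = FALSE)
  if (n_target == 0) return(0)
  s <- as_dwell_means(snv)
  w <- as_dwell_means(wt)
  if (s[["tau_bound"]] == w[["tau_bound"]]) {
    stop("equal bound dwells cannot be discriminated in finite time",
         call. = FALSE)
  }
  if (s[["tau_bound"]] < w[["tau_bound"]]) { tmp <- s; s <- w; w <- tmp }
  num <- s[["tau_bound"]] * sqrt(s[["tau_bound"]] + s[["tau_unbound"]]) +
    w[["tau_bound"]] * sqrt(w[["tau_bound"]] + w[["tau_unbound"]])
  (n_target * num / (s[["tau_bound"]] - w[["tau_bound"]]))^2
}

#' Poisson model of the binding event count
#'
#' The number of binding events a molecule completes in `t` seconds is
#' described as Poisson with mean `lambda = t / (tau_bound + tau_unbound)`.
#' (The Poisson description is an approximation of the underlying
#' alternating renewal process that is accurate when `tau_bound` is small
#' relative to `tau_unbound`.)
#'
#' @inheritParams gamma_model
#' @return A list of class `kinfp_poisson_model` with `lambda`, `tau_bound`,
#'   `tau_unbound`, `t`.
#' @export
poisson_event_model <- function(tau_bound, tau_unbound, t) {
  lambda <- expected_event_count(tau_bound, tau_unbound, t)
  structure(list(lambda = lambda, tau_bound = tau_bound,
                 tau_unbound = tau_unbound, t = t),
            class = "kinfp_poisson_model")
}

#' Acquisition time for event-count-only discrimination
#'
#' If only the number of binding events is used to tell the classes apart,
#' their Poisson means must separate by `n` combined standard deviations:
#' `|lambda_S - lambda_W| = n * (sqrt(lambda_S) + sqrt(lambda_W))`, giving
#' `t = n^2 / (1/sqrt(T_S) - 1/sqrt(T_W))^2` with `T_i` the mean cycle
#' times. Equal cycle times can never be separated by counts alone and
#' return `Inf`.
#'
#' @inheritParams discrimination_factor
#' @param n_target target separation in combined standard deviations.
#' @return Required acquisition time, seconds (possibly `Inf`).
#' @export
poisson_required_time <- function(snv, wt, n_target) {
  if (n_target < 0) stop("`n_target` must be non-negative", call. = FALSE)
  if (n_target == 0) return(0)
  s <- as_dwell_means(snv)
  w <- as_dwell_means(wt)
  cyc_s <- sum(s)
  cyc_w <- sum(w)
  d <- abs(1 / sqrt(cyc_s) - 1 / sqrt(cyc_w))
  if (d == 0) return(Inf)
  (n_target / d)^2
}

#' Estimate the dissociation rate from bound dwells
#'
#' Exponential maximum-likelihood estimate `k_off = 1 / mean(dwells)` over
#' uncensored bound dwells, with a bootstrap standard error.
#'
#' @param bound_dwells uncensored bound dwell times, seconds (>= 10 values).
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed integer seed for the bootstrap.
#' @return A list with `k_off` (per second), `se`, `n`.
#' @export
estimate_koff <- function(bound_dwells, n_boot = 200, seed = 1L) {
  bound_dwells <- bound_dwells[!is.na(bound_dwells)]
  if (length(bound_dwells) < 10L) {
    stop("k_off estimation needs at least 10 uncensored bound dwells",
         call. = FALSE)
  }
  if (any(bound_dwells <= 0)) stop("dwells must be positive", call. = FALSE)
  k_off <- 1 / mean(bound_dwells)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    1 / mean(sample(bound_dwells, replace = TRUE))
  }, numeric(1))
  list(k_off = k_off, se = stats::sd(boots), n = length(bound_dwells))
}

#' Estimate the association rate constant by concentration regression
#'
#' The pseudo-first-order binding constant `1 / tau_unbound` is linear in
#' probe concentration with slope `k_on`; a through-origin least-squares
#' fit over two or more concentrations recovers `k_on` and its standard
#' error.
#'
#' @param tau_unbound_means mean unbound dwell at each concentration,
#'   seconds.
#' @param concentrations probe concentrations, molar (>= 2 distinct).
#' @return A list with `k_on` (per molar per second), `se`, and the fitted
#'   `pseudo_rates`.
#' @export
estimate_kon <- function(tau_unbound_means, concentrations) {
  if (length(tau_unbound_means) != length(concentrations)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (length(unique(concentrations)) < 2L) {
    stop("k_on regression needs at least 2 distinct concentrations",
         call. = FALSE)
  }
  pseudo <- 1 / tau_unbound_means
  fit <- stats::lm(pseudo ~ 0 + concentrations)
  k_on <- unname(coef(fit)[1])
  if (!is.finite(k_on) || k_on <= 0) {
    stop("fitted k_on slope is non-positive (unphysical)", call. = FALSE)
  }
  # exact input data trigger a harmless "perfect fit" warning in summary()
  se <- suppressWarnings(summary(fit)$coefficients[1, 2])
  list(k_on = k_on, se = unname(se), pseudo_rates = pseudo)
}

#' Equilibrium dissociation constant
#'
#' `K_d = k_off / k_on` (molar).
#'
#' @param k_on association rate constant, per molar per second.
#' @param k_off dissociation rate constant, per second.
#' @return `K_d` in molar.
#' @export
dissociation_constant <- function(k_on, k_off) {
  if (k_on <= 0 || k_off <= 0) stop("rates must be positive", call. = FALSE)
  k_off / k_on
}
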