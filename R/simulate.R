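#' Emission (camera noise) model for trace simulation
#'
#' Background-subtracted aperture intensities are modeled as Gaussian around
#' a state-dependent level. Frames that straddle a binding or dissociation
#' event take the occupancy-weighted mean level and an occupancy-weighted
#' variance, mimicking camera integration over the frame exposure.
#'
#' @param bound_mean,unbound_mean emission levels (arbitrary units).
#' @param bound_sd,unbound_sd per-state standard deviations.
#' @return A list of class `kinfp_noise`.
#' @export
noise_model <- function(bound_mean = 1, unbound_mean = 0,
                        bound_sd = 0.2, unbound_sd = 0.2) {
  if (bound_mean <= unbound_mean) {
    stop("`bound_mean` must exceed `unbound_mean`", call. = FALSE)
  }
  if (bound_sd < 0 || unbound_sd < 0) {
    stop("state standard deviations must be non-negative", call. = FALSE)
  }
  structure(list(bound_mean = bound_mean, unbound_mean = unbound_mean,
                 bound_sd = bound_sd, unbound_sd = unbound_sd),
            class = "kinfp_noise")
}

#' Simulation configuration for a trace population
#'
#' Defines the study conditions of one simulated field of molecules: the
#' acquisition (10 min at 2 Hz by default, i.e. 1200 frames), the number of
#' target molecules and the mutant (SNV) fraction among them, the kinetic
#' rate sets of each class, the camera noise model, and the density of
#' non-specific background binders.
#'
#' @param n_molecules number of target molecules.
#' @param snv_fraction fraction of target molecules carrying the mutation,
#'   in `[0, 1]`; each molecule's class is an independent Bernoulli draw.
#' @param duration acquisition time, seconds.
#' @param frame_rate frames per second; `duration * frame_rate` must be a
#'   whole number of frames.
#' @param snv_rates,wt_rates,bg_rates [rate_set()]s for mutant, wild-type
#'   and non-specific background molecules.
#' @param noise a [noise_model()].
#' @param background_rate expected number of non-specific background
#'   molecules per target molecule (Poisson draw appended to the field).
#' @param seed integer seed controlling all randomness of the population.
#' @return A list of class `kinfp_config`.
#' @export
sim_config <- function(n_molecules, snv_fraction = 0, duration = 600,
                       frame_rate = 2, snv_rates = kinfp::snv_rates(),
                       wt_rates = kinfp::wt_rates(),
                       bg_rates = kinfp::background_rates(),
                       noise = noise_model(), background_rate = 0.05,
                       seed = 1L) {
  if (n_molecules < 0 || n_molecules != round(n_molecules)) {
    stop("`n_molecules` must be a non-negative integer", call. = FALSE)
  }
  if (snv_fraction < 0 || snv_fraction > 1) {
    stop("`snv_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (duration <= 0 || frame_rate <= 0) {
    stop("`duration` and `frame_rate` must be positive", call. = FALSE)
  }
  n_frames <- duration * frame_rate
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("`duration * frame_rate` must be a whole number of frames",
         call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 snv_fraction = snv_fraction, duration = duration,
                 frame_rate = frame_rate, snv_rates = snv_rates,
                 wt_rates = wt_rates, bg_rates = bg_rates, noise = noise,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "kinfp_config")
}

#' Simulate a continuous-time two-state dwell sequence
#'
#' Draws an alternating sequence of unbound/bound dwell times for one
#' molecule observed for `duration` seconds. Dwells are exponential with
#' means `1/(k_on * probe_conc)` (unbound) and `1/k_off` (bound); the
#' initial state is drawn from the stationary distribution (molecules are
#' observed at binding equilibrium), and the final dwell is truncated at
#' the end of the acquisition so the dwells sum to `duration` exactly.
#'
#' @param rates a [rate_set()].
#' @param duration observation time, seconds (> 0).
#' @param seed optional integer seed; same seed and rates give an identical
#'   dwell list.
#' @param initial_state `"stationary"` (default), `"unbound"` or `"bound"`.
#' @return A list with `durations` (numeric vector, seconds), `first_bound`
#'   (logical: state of the first dwell), and `duration`.
#' @export
simulate_dwell_sequence <- function(rates, duration, seed = NULL,
                                    initial_state = c("stationary",
                                                      "unbound", "bound")) {
  if (!inherits(rates, "kinfp_rates")) {
    stop("`rates` must be a rate_set()", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  initial_state <- match.arg(initial_state)
  if (!is.null(seed)) set.seed(seed)

  tb <- tau_bound(rates)
  tu <- tau_unbound(rates)
  first_bound <- switch(initial_state,
                        stationary = runif(1) < tb / (tb + tu),
                        unbound = FALSE,
                        bound = TRUE)

  # draw dwells in blocks until the acquisition window is covered
  mean_cycle <- tb + tu
  block <- max(16L, 2L * ceiling(duration / mean_cycle) + 8L)
  durations <- numeric(0)
  total <- 0
  bound <- first_bound
  while (total < duration) {
    n_b <- ceiling(block / 2)
    d_u <- rexp(n_b, rate = 1 / tu)
    d_b <- rexp(n_b, rate = 1 / tb)
    dd <- numeric(2 * n_b)
    if (bound) {
      dd[seq(1, 2 * n_b, by = 2)] <- d_b
      dd[seq(2, 2 * n_b, by = 2)] <- d_u
    } else {
      dd[seq(1, 2 * n_b, by = 2)] <- d_u
      dd[seq(2, 2 * n_b, by = 2)] <- d_b
    }
    durations <- c(durations, dd)
    total <- total + sum(dd)
    # dd has even length, so the next block starts in the same state
  }
  cum <- cumsum(durations)
  last <- which(cum >= duration)[1]
  durations <- durations[seq_len(last)]
  durations[last] <- durations[last] - (cum[last] - duration)
  # guard: drop a trailing zero-length dwell created by exact truncation
  if (durations[last] <= 0 && last > 1L) durations <- durations[-last]
  list(durations = durations, first_bound = first_bound, duration = duration)
}

#' Discretize a dwell sequence into a camera trace
#'
#' Converts a continuous-time dwell sequence into per-frame intensities.
#' Each frame's noiseless level is the occupancy-weighted mixture of the
#' bound and unbound emission levels (integrated state occupancy within the
#' frame, not point sampling, so sub-frame events leave a partial-intensity
#' footprint as they do on a real camera). Gaussian noise with
#' occupancy-weighted variance is then added.
#'
#' @param dwells result of [simulate_dwell_sequence()].
#' @param frame_rate frames per second.
#' @param noise a [noise_model()]; use `NULL` for a noiseless trace.
#' @param seed optional integer seed for the noise draw.
#' @return A list of class `kinfp_trajectory` with `intensity` (one value
#'   per frame), `occupancy` (fraction of each frame spent bound),
#'   `frame_dt` (seconds) and `n_frames`.
#' @export
discretize_trajectory <- function(dwells, frame_rate, noise = noise_model(),
                                  seed = NULL) {
  if (frame_rate <= 0) stop("`frame_rate` must be positive", call. = FALSE)
  n_frames <- round(dwells$duration * frame_rate)
  if (abs(n_frames - dwells$duration * frame_rate) > 1e-9) {
    stop("dwell duration is not a whole number of frames at this frame rate",
         call. = FALSE)
  }
  dt <- 1 / frame_rate
  occ <- frame_occupancy_cpp(dwells$durations, dwells$first_bound,
                             as.integer(n_frames), dt)
  if (is.null(noise)) {
    intensity <- occ
  } else {
    if (!is.null(seed)) set.seed(seed)
    level <- noise$bound_mean * occ + noise$unbound_mean * (1 - occ)
    v <- noise$bound_sd^2 * occ + noise$unbound_sd^2 * (1 - occ)
    intensity <- level + rnorm(n_frames, sd = sqrt(v))
  }
  structure(list(intensity = intensity, occupancy = occ,
                 frame_dt = dt, n_frames = as.integer(n_frames)),
            class = "kinfp_trajectory")
}

# Deterministic per-molecule substream seeds: one upfront draw from the
# population seed, so results do not depend on chunking or evaluation order.
molecule_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

#' Simulate a labeled population of binding trajectories
#'
#' Generates `n_molecules` target molecules whose class (SNV or WT) is an
#' independent Bernoulli(`snv_fraction`) draw, appends a Poisson number of
#' non-specific background binders, simulates each molecule's dwell
#' sequence and camera trace, and returns the traces together with the
#' ground truth needed to score every downstream stage.
#'
#' @param config a [sim_config()].
#' @param keep_states keep the true per-frame state matrix (majority
#'   occupancy per frame); memory-heavy for large populations.
#' @param keep_dwells keep the true continuous-time dwell sequences.
#' @return A list of class `kinfp_population`: `intensity` (frames x
#'   molecules matrix), `frame_dt`, `truth` (tibble: `molecule_id`, `class`,
#'   `n_events_true`, `fraction_bound_true`, `tau_bound_true`,
#'   `tau_unbound_true` -- the per-molecule realized means), and optionally
#'   `states` / `dwells`.
#' @export
simulate_population <- function(config, keep_states = FALSE,
                                keep_dwells = FALSE) {
  stopifnot(inherits(config, "kinfp_config"))
  set.seed(config$seed)
  n_t <- config$n_molecules
  classes <- if (n_t > 0) {
    ifelse(rbinom(n_t, 1L, config$snv_fraction) == 1L, "SNV", "WT")
  } else character(0)
  n_bg <- if (config$background_rate > 0 && n_t > 0) {
    rpois(1, config$background_rate * n_t)
  } else 0L
  classes <- c(classes, rep("background", n_bg))
  n <- length(classes)
  n_frames <- as.integer(round(config$duration * config$frame_rate))
  dt <- 1 / config$frame_rate

  intensity <- matrix(NA_real_, nrow = n_frames, ncol = n)
  states <- if (keep_states) matrix(FALSE, nrow = n_frames, ncol = n)
  dwell_list <- if (keep_dwells) vector("list", n)
  n_events <- integer(n)
  frac_b <- tau_b <- tau_u <- numeric(n)

  seeds <- if (n > 0) molecule_seeds(config$seed, n) else integer(0)
  rates_for <- list(SNV = config$snv_rates, WT = config$wt_rates,
                    background = config$bg_rates)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    dw <- simulate_dwell_sequence(rates_for[[classes[i]]], config$duration)
    tr <- discretize_trajectory(dw, config$frame_rate, config$noise)
    intensity[, i] <- tr$intensity
    if (keep_states) states[, i] <- tr$occupancy >= 0.5
    if (keep_dwells) dwell_list[[i]] <- dw
    st <- dwell_states(dw)
    n_events[i] <- length(dw$durations) - 1L
    frac_b[i] <- sum(dw$durations[st]) / dw$duration
    tau_b[i] <- if (any(st)) mean(dw$durations[st]) else NA_real_
    tau_u[i] <- if (any(!st)) mean(dw$durations[!st]) else NA_real_
  }
  ids <- seq_len(n)
  out <- list(intensity = intensity, frame_dt = dt,
              truth = tibble::tibble(molecule_id = ids, class = classes,
                                     n_events_true = n_events,
                                     fraction_bound_true = frac_b,
                                     tau_bound_true = tau_b,
                                     tau_unbound_true = tau_u))
  if (keep_states) out$states <- states
  if (keep_dwells) out$dwells <- dwell_list
  structure(out, class = "kinfp_population")
}

# logical vector: is each dwell in the sequence a bound dwell?
dwell_states <- function(dwells) {
  n <- length(dwells$durations)
  if (dwells$first_bound) (seq_len(n) %% 2L) == 1L else (seq_len(n) %% 2L) == 0L
}

#' @export
print.kinfp_population <- function(x, ...) {
  cat(sprintf("<kinfp_population> %d molecules x %d frames (dt = %g s)\n",
              ncol(x$intensity), nrow(x$intensity), x$frame_dt))
  print(table(x$truth$class))
  invisible(x)
}
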