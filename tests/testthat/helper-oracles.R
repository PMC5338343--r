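# Independent oracles used to freeze expected values. These deliberately do
# not reuse the package's simulation or fitting code paths.

# Brute-force two-threshold segmentation of a noiseless two-level trace:
# frames above the midpoint of the two levels are bound.
oracle_segment <- function(y) {
  lv <- range(y)
  if (diff(lv) == 0) return(rep(FALSE, length(y)))
  y > mean(lv)
}

# Alternating-renewal draw of one molecule observed for t seconds starting
# unbound: returns completed (uncensored) bound dwells and the number of
# binding events.
oracle_renewal <- function(t, tau_b, tau_u) {
  dwell_b <- numeric(0)
  n_bind <- 0L
  now <- 0
  repeat {
    now <- now + rexp(1, 1 / tau_u)
    if (now >= t) break
    n_bind <- n_bind + 1L
    d <- rexp(1, 1 / tau_b)
    if (now + d > t) break
    dwell_b <- c(dwell_b, d)
    now <- now + d
  }
  list(bound_dwells = dwell_b, n_binding_events = n_bind)
}

# Exhaustive two-sided permutation test on the difference of group means.
oracle_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  obs <- abs(mean(a) - mean(b))
  stats <- apply(idx, 2, function(ii) {
    abs(mean(pooled[ii]) - mean(pooled[-ii]))
  })
  mean(stats >= obs - 1e-12)
}

# Dwell sequence with durations aligned to the frame grid (so the noiseless
# discretized trace is exactly two-level).
aligned_dwells <- function(n_dwells, dt, duration, seed) {
  set.seed(seed)
  lens <- pmax(1L, rpois(n_dwells, 6)) * dt
  total <- sum(lens)
  if (total < duration) {
    lens <- c(lens, duration - total)
  } else {
    cum <- cumsum(lens)
    last <- which(cum >= duration)[1]
    lens <- lens[seq_len(last)]
    lens[last] <- lens[last] - (cum[last] - duration)
    if (lens[last] <= 0) lens <- lens[-last]
  }
  list(durations = lens, first_bound = FALSE, duration = duration)
}
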