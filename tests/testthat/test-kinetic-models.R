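test_that("gamma dwell model has the stated shape, rate, and moments", {
  m <- gamma_model(tau_bound = 10, tau_unbound = 50, t = 600)
  expect_equal(m$k, 10)                    # t / (tau_b + tau_u)
  expect_equal(m$theta, 0.1)
  expect_equal(m$sd_mean_bound, 10 / sqrt(10))

  # shape-1 gamma reduces to the exponential density
  x <- seq(0, 20, by = 0.5)
  expect_equal(gamma_dwell_pdf(x, k = 1, theta = 0.3), 0.3 * exp(-0.3 * x))
  # normalization
  integ <- stats::integrate(function(z) gamma_dwell_pdf(z, k = m$k,
                                                        theta = m$theta),
                            0, Inf)
  expect_lt(abs(integ$value - 1), 1e-6)
  expect_error(gamma_dwell_pdf(1, k = -1, theta = 1), "positive")
})

test_that("expected event count follows the renewal mean", {
  expect_equal(expected_event_count(10, 50, 600), 10)
  expect_equal(expected_event_count(10, 50, 0), 0)
  # Monte-Carlo: mean binding-event count over many molecules within 3%
  set.seed(73)
  counts <- vapply(1:4000, function(i) {
    oracle_renewal(600, tau_b = 8.4, tau_u = 12.5)$n_binding_events
  }, numeric(1))
  k <- expected_event_count(8.4, 12.5, 600)
  expect_lt(abs(mean(counts) - k) / k, 0.03)
})

test_that("per-molecule total bound time follows the gamma model", {
  # k dwells at rate 1/tau_b: total bound time ~ Gamma(k, 1/tau_b), so the
  # per-molecule mean bound dwell ~ Gamma(k, k/tau_b)
  k <- 12; tau_b <- 8.4
  set.seed(75)
  means <- vapply(1:1500, function(i) mean(rexp(k, 1 / tau_b)), numeric(1))
  p <- suppressWarnings(
    stats::ks.test(means, "pgamma", shape = k, rate = k / tau_b)$p.value)
  expect_gt(p, 0.01)
  # moment identities of the modeled mean bound dwell
  m <- gamma_model(tau_b, 12.5, t = k * (8.4 + 12.5))
  expect_lt(abs(mean(means) - m$tau_bound) / m$tau_bound, 0.02)
  expect_lt(abs(sd(means) - m$sd_mean_bound) / m$sd_mean_bound, 0.06)
})

test_that("discrimination factor behaves as the gamma model predicts", {
  snv <- dwell_means(8.4, 12.5)
  wt <- dwell_means(3.0, 32.1)
  expect_equal(discrimination_factor(snv, snv, 600), 0)
  n1 <- discrimination_factor(snv, wt, 600)
  # sqrt(t) scaling
  expect_equal(discrimination_factor(snv, wt, 1200), n1 * sqrt(2))
  # swapped classes warn and report the magnitude
  expect_warning(n_swap <- discrimination_factor(wt, snv, 600), "swapped")
  expect_equal(n_swap, n1)
  expect_error(discrimination_factor(snv, wt, -1), "positive")

  # Monte-Carlo self-consistency: empirical class separation matches
  # n x (sum of empirical sds) within 10%
  set.seed(77)
  mb <- function(tau_b, tau_u) {
    reps <- vapply(1:1200, function(i) {
      d <- oracle_renewal(600, tau_b, tau_u)$bound_dwells
      if (length(d) < 1) NA_real_ else mean(d)
    }, numeric(1))
    reps[!is.na(reps)]
  }
  s_mc <- mb(8.4, 12.5); w_mc <- mb(3.0, 32.1)
  sep_emp <- (mean(s_mc) - mean(w_mc)) / (sd(s_mc) + sd(w_mc))
  expect_lt(abs(sep_emp - n1) / n1, 0.10)
})

test_that("required acquisition time inverts the discrimination factor exactly", {
  snv <- dwell_means(8.4, 12.5)
  wt <- dwell_means(3.0, 32.1)
  for (n in c(0.5, 1, 3, 7)) {
    t_req <- required_acquisition_time(snv, wt, n)
    expect_equal(discrimination_factor(snv, wt, t_req), n,
                 tolerance = 1e-12)
  }
  expect_equal(required_acquisition_time(snv, wt, 0), 0)
  expect_error(required_acquisition_time(dwell_means(5, 10),
                                         dwell_means(5, 20), 3),
               "finite time")
})

test_that("Poisson event-count model and its required time behave correctly", {
  m <- poisson_event_model(10, 50, 600)
  expect_equal(m$lambda, 10)
  # identical cycle times can never be separated by counts alone
  expect_equal(poisson_required_time(dwell_means(10, 50),
                                     dwell_means(20, 40), 3), Inf)
  expect_equal(poisson_required_time(dwell_means(10, 50),
                                     dwell_means(10, 50), 0), 0)

  # dispersion check in the Poisson regime (tau_b << tau_u): variance/mean
  # of simulated event counts in [0.9, 1.1] for lambda >= 5
  set.seed(79)
  counts <- vapply(1:3000, function(i) {
    oracle_renewal(300, tau_b = 0.5, tau_u = 50)$n_binding_events
  }, numeric(1))
  expect_gte(mean(counts), 5)
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, 0.9); expect_lt(disp, 1.1)
})

test_that("dwell-based rate estimators recover the simulated truth", {
  expect_equal(estimate_koff(rep(10, 20))$k_off, 0.1)
  expect_error(estimate_koff(rep(10, 5)), "at least 10")

  set.seed(81)
  d <- rexp(10000, rate = 0.2)
  est <- estimate_koff(d, seed = 82)
  expect_lt(abs(est$k_off - 0.2), 3 * est$se)
  expect_gt(est$se, 0)

  # exact through-origin regression on noiseless points
  conc <- c(10, 25, 50) * 1e-9
  est_kon <- estimate_kon(1 / (3.2e6 * conc), conc)
  expect_equal(est_kon$k_on, 3.2e6, tolerance = 1e-9)
  expect_error(estimate_kon(c(10, 12), c(25e-9, 25e-9)), "distinct")

  expect_equal(dissociation_constant(1e6, 0.1), 100e-9)
  kd <- dissociation_constant(3.2e6, 1 / 8.4)
  expect_equal(kd * 3.2e6, 1 / 8.4)
})

test_that("a more stable duplex yields a smaller dissociation constant in simulation", {
  # longer probe: slower off, faster on (at fixed concentration)
  stable <- rate_set(k_on = 5e6, k_off = 0.05, probe_conc = 25e-9)
  weak <- rate_set(k_on = 1e6, k_off = 0.5, probe_conc = 25e-9)
  est_kd <- function(r, seed) {
    dw <- simulate_dwell_sequence(r, 2e4, seed = seed)
    st <- kinfp:::dwell_states(dw)
    n <- length(dw$durations)
    b <- dw$durations[st & seq_len(n) < n]
    u <- dw$durations[!st & seq_len(n) < n]
    k_off <- 1 / mean(b)
    k_on <- (1 / mean(u)) / r$probe_conc
    dissociation_constant(k_on, k_off)
  }
  expect_lt(est_kd(stable, 83), est_kd(weak, 84))
})

test_that("gamma-model acquisition times undercut count-only times across the separated regime", {
  # kinetics grids with clearly separated bound dwells
  for (tb_w in c(2, 3, 4)) {
    for (tu_w in c(20, 32.1)) {
      snv <- dwell_means(8.4, 12.5)
      wt <- dwell_means(tb_w, tu_w)
      expect_lt(required_acquisition_time(snv, wt, 3),
                poisson_required_time(snv, wt, 3))
    }
  }
})
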