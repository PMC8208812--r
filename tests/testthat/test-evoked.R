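test_that("a silent unit has zero firing probability everywhere", {
  s <- make_evoked_session(3)
  s$spikes <- s$spikes[0, ]
  s$spikes <- rbind(s$spikes,
                    data.frame(unit_id = "u1", trial_id = 1, time_ms = 1))
  pr <- peristim_probability(s, "u1", "delay", window = c(4, 20))
  expect_true(all(pr$p_stim == 0))
  expect_true(all(pr$p_nonstim == 0))
})

test_that("a deterministic evoked spike occupies exactly its bin", {
  # evoked at exactly 6.0 ms after every delay pulse, nothing else
  tr <- make_trials(3)
  offs <- setNames(rep(list(numeric(0)), nrow(tr)), tr$trial_id)
  for (i in which(tr$stimulated)) offs[[as.character(i)]] <- 6.0
  s <- make_evoked_session(3, evoked_offsets = offs)
  pr <- peristim_probability(s, "u1", "delay", window = c(0, 20))
  expect_equal(pr$p_stim[pr$bin == 6], 1)
  expect_true(all(pr$p_stim[pr$bin != 6] == 0))
  expect_true(all(pr$p_nonstim == 0))
  expect_true(all(pr$masked[pr$bin < 3]) && !any(pr$masked[pr$bin >= 3]))
})

test_that("homogeneous Poisson background gives ~rate*dt per bin on both arms", {
  u <- unit_config("u1", "non_activated", baseline_rate = 10,
                   epoch_gains = flat_gains())
  s <- simulate_session(simulation_config(list(u), n_trials = 150, seed = 17))
  pr <- peristim_probability(s, "u1", "delay", window = c(0, 20))
  # oracle: per-bin occupancy of a 10 Hz process, 1 - exp(-rate * 1ms) ~ 0.01
  p0 <- 1 - exp(-10 / 1000)
  n <- attr(pr, "n_stim")
  se <- sqrt(p0 * (1 - p0) / (n * nrow(pr)))
  expect_lt(abs(mean(pr$p_stim) - p0), 3 * se + 1e-4)
  expect_lt(abs(mean(pr$p_nonstim) - p0), 3 * se + 1e-4)
})

test_that("detect_latency returns absent under the null and the true bin under signal", {
  # identical stim and non-stim: no bin can be significant
  u <- unit_config("u1", "non_activated", baseline_rate = 15,
                   epoch_gains = flat_gains())
  s <- simulate_session(simulation_config(list(u), n_trials = 100, seed = 23))
  d <- detect_latency(s, "u1", "delay")
  expect_true(is.na(d$latency_ms))
  expect_equal(nrow(d$p_values), 16)  # searchable bins 4..19 ms
  # strong evoked response at 6 ms
  u2 <- unit_config("u2", baseline_rate = 10, epoch_gains = flat_gains(),
                    evoked_prob = 0.6, evoked_latency_mean = 6.3,
                    evoked_latency_sd = 0.4)
  s2 <- simulate_session(simulation_config(list(u2), n_trials = 100, seed = 24))
  d2 <- detect_latency(s2, "u2", "delay")
  expect_true(d2$latency_ms %in% c(5, 6, 7))
})

test_that("the per-bin exact test equals fisher.test one-sided", {
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(20:80, 1); n2 <- sample(20:80, 1)
    k1 <- rbinom(1, n1, 0.3); k2 <- rbinom(1, n2, 0.1)
    p_pkg <- wmgating:::.prop_test_greater(k1, n1, k2, n2)
    p_ref <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2),
                         alternative = "greater")$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("activation classes follow the 10 ms latency boundary", {
  expect_equal(classify_activation(c(6.5, 12.7, NA)),
               c("visual_recipient", "slow_input", "non_activated"))
})

test_that("adjusted spike count recovers the evoked probability", {
  # evoked spikes land inside [5,9) with prob 0.25; quiet background
  u <- quiet_unit("u1", evoked_prob = 0.25, evoked_latency_mean = 6.8,
                  evoked_latency_sd = 0.35)
  s <- simulate_session(simulation_config(list(u), n_trials = 300, seed = 29))
  a_in <- evoked_spike_count(s, "u1", "In")
  expect_lt(abs(a_in - 0.25), 3 * sqrt(0.25 * 0.75 / 300))
  # same evoked probability but latency ~12 ms: spikes fall outside [5,9)
  u2 <- quiet_unit("u2", activation_type = "slow_input", evoked_prob = 0.25)
  s2 <- simulate_session(simulation_config(list(u2), n_trials = 300, seed = 30))
  expect_lt(abs(evoked_spike_count(s2, "u2", "In")), 0.02)
})

test_that("adjusted spike count is unbiased under a stationary background", {
  u <- unit_config("u1", "non_activated", baseline_rate = 25,
                   epoch_gains = flat_gains())
  s <- simulate_session(simulation_config(list(u), n_trials = 500, seed = 31))
  a <- evoked_spike_count(s, "u1", "In")
  # per-trial window counts are ~Bernoulli(0.1); SE of the difference
  se <- sqrt(2 * 0.1 / 500)
  expect_lt(abs(a), 3 * se + 1e-3)
})

test_that("response magnitude matches its closed form and is scale invariant", {
  expect_equal(log_ratio_magnitude(20, 10, 10, 10, 0), log10(2))
  expect_equal(round(log_ratio_magnitude(20, 10, 10, 10, 0), 4), 0.3010)
  # doubling every count leaves the statistic unchanged
  expect_equal(log_ratio_magnitude(40, 20, 20, 20, 0),
               log_ratio_magnitude(20, 10, 10, 10, 0))
  # zero counts engage the 0.5 pseudocount and stay finite
  expect_true(is.finite(log_ratio_magnitude(3, 0, 1, 2)))
})

test_that("response magnitude is ~0 for stimulation-free statistics", {
  u <- unit_config("u1", "non_activated", baseline_rate = 30,
                   epoch_gains = flat_gains())
  s <- simulate_session(simulation_config(list(u), n_trials = 400, seed = 37))
  expect_lt(abs(response_magnitude(s, "u1", "In")), 0.1)
})

test_that("evoked latency by condition averages first evoked-window spikes", {
  tr <- make_trials(2)  # In stim trials are 1 and 2
  offs <- list("1" = c(5.5, 8.5), "2" = 6.5)
  s <- make_evoked_session(2, evoked_offsets = offs)
  expect_equal(evoked_latency_by_condition(s, "u1", "In"), 6.0)
  offs3 <- list("1" = 5.5, "2" = 6.5, "5" = 8.0)  # trial 5 = Out stim
  s3 <- make_evoked_session(2, evoked_offsets = offs3)
  expect_equal(evoked_latency_by_condition(s3, "u1", "Out"), 8.0)
  expect_equal(evoked_latency_by_condition(s3, "u1", "In"), 6.0)
  # three In trials with first-spike latencies 5.5, 6.5, 8.0 -> 6.667
  tr4 <- make_trials(3)
  offs4 <- list("1" = 5.5, "2" = 6.5, "3" = 8.0)
  s4 <- make_evoked_session(3, evoked_offsets = offs4)
  expect_equal(evoked_latency_by_condition(s4, "u1", "In"), 20 / 3,
               tolerance = 1e-9)
  # no qualifying trial -> NA
  expect_true(is.na(evoked_latency_by_condition(s4, "u1", "Out")))
})

test_that("sparse background first arrivals average near the window midpoint", {
  # low-rate background only: conditional first arrival in [5,9) ~ uniform
  u <- unit_config("u1", "non_activated", baseline_rate = 5,
                   epoch_gains = flat_gains())
  s <- simulate_session(simulation_config(
    list(u), n_trials = c(In_stim = 1500, In_nonstim = 2,
                          Out_stim = 2, Out_nonstim = 2), seed = 41))
  m <- evoked_latency_by_condition(s, "u1", "In")
  expect_lt(abs(m - 7.0), 0.45)
})

test_that("normalized evoked time course behaves as an average of unit traces", {
  tr <- make_trials(3)
  offs <- setNames(rep(list(numeric(0)), nrow(tr)), tr$trial_id)
  for (i in which(tr$stimulated)) offs[[as.character(i)]] <- 6.0
  s <- make_evoked_session(3, evoked_offsets = offs)
  # single unit, single evoked bin: 1 at that bin, 0 elsewhere
  tc <- normalized_evoked_timecourse(s, "u1", "delay", window = c(0, 20))
  expect_equal(tc$mean_normalized[tc$bin == 6], 1)
  expect_true(all(tc$mean_normalized[tc$bin != 6] == 0))
  # a duplicated unit leaves the population trace unchanged
  sp2 <- s$spikes; sp2$unit_id <- "u2"
  s$spikes <- rbind(s$spikes, sp2)
  tc2 <- normalized_evoked_timecourse(s, c("u1", "u2"), "delay",
                                      window = c(0, 20))
  expect_equal(tc2$mean_normalized, tc$mean_normalized)
})

test_that("excitation followed by suppression yields a biphasic trace", {
  # excitation at 6 ms then silenced bins 10-16 relative to background
  u <- unit_config("u1", baseline_rate = 40, epoch_gains = flat_gains(),
                   evoked_prob = 0.9, evoked_latency_mean = 6,
                   evoked_latency_sd = 0.3, refractory_ms = 8)
  s <- simulate_session(simulation_config(list(u), n_trials = 150, seed = 43))
  tc <- normalized_evoked_timecourse(s, "u1", "delay", window = c(0, 20))
  expect_gt(tc$mean_normalized[tc$bin == 6], 0.5)
  # refractoriness after the evoked spike suppresses the following bins
  expect_lt(mean(tc$mean_normalized[tc$bin %in% 8:12]), 0)
})
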