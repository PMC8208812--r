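test_that("epoch rates are count over window length", {
  tr <- make_trials(1)
  # 9 spikes in the 900 ms visual window [1100, 2000) -> 10 Hz
  s <- wm_session(tr, make_spikes("u1", setNames(
    list(seq(1150, 1950, length.out = 9)), 2)))
  expect_equal(epoch_rate(s, "u1", "visual_epoch", 2)$rate, 10)
  # empty train -> 0 Hz
  expect_equal(epoch_rate(s, "u1", "visual_epoch", 4)$rate, 0)
  # 2 spikes in the 125 ms presaccadic window -> 16 Hz
  s2 <- wm_session(tr, make_spikes("u1", setNames(list(c(3100, 3150)), 2)))
  expect_equal(epoch_rate(s2, "u1", "motor_epoch", 2)$rate, 16)
})

test_that("activity significance requires enhancement, not just difference", {
  set.seed(61)
  mk_session <- function(gain) {
    u <- unit_config("u1", "non_activated", baseline_rate = 12,
                     epoch_gains = list(fixation = c(In = 1, Out = 1),
                                        visual = c(In = gain, Out = 1),
                                        delay = c(In = 1, Out = 1),
                                        presaccadic = c(In = 1, Out = 1)))
    simulate_session(simulation_config(list(u), n_trials = 50,
                                       seed = round(gain * 100)))
  }
  # flat profile: no flag
  a0 <- activity_significance(mk_session(1), "u1", "visual_epoch")
  expect_false(a0$flag)
  # 3x enhancement: flagged
  a1 <- activity_significance(mk_session(3), "u1", "visual_epoch")
  expect_true(a1$flag)
  expect_lt(a1$p, 0.001)
  # strong suppression: significant difference but not an enhancement
  a2 <- activity_significance(mk_session(0.25), "u1", "visual_epoch")
  expect_false(a2$flag)
  expect_lt(a2$p, 0.05)
})

test_that("identical epoch and baseline rates give p = 1 and no flag", {
  tr <- make_trials(6)
  # 10 Hz in both the visual window (9 spikes / 900 ms) and the fixation
  # baseline (3 spikes / 300 ms) on every trial: all paired differences zero
  times <- lapply(seq_len(nrow(tr)),
                  function(i) c(750, 800, 850, seq(1150, 1950, length.out = 9)))
  names(times) <- tr$trial_id
  s <- wm_session(tr, make_spikes("u1", times))
  a <- activity_significance(s, "u1", "visual_epoch")
  expect_false(a$flag)
  expect_equal(a$p, 1)
})

test_that("ROC selectivity matches the pair-counting oracle", {
  expect_equal(roc_selectivity(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_selectivity(c(10, 11, 12), c(1, 2, 3)), 1.0)
  expect_equal(roc_selectivity(c(2, 4), c(1, 3)), 0.75)
  expect_equal(roc_selectivity(c(1, 2, 3), c(10, 11, 12)), 0)
})

test_that("ROC equals tie-corrected Mann-Whitney U/(n1 n2) on random samples", {
  set.seed(63)
  for (i in 1:60) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    # integer rates induce plenty of ties
    x <- sample(0:6, n1, replace = TRUE); y <- sample(0:6, n2, replace = TRUE)
    u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(roc_selectivity(x, y), u / (n1 * n2), tolerance = 1e-12)
    # complement property
    expect_equal(roc_selectivity(x, y) + roc_selectivity(y, x), 1,
                 tolerance = 1e-12)
  }
})

test_that("permutation selectivity p-values behave and are reproducible", {
  x <- rep(c(1, 2, 3), 4); y <- x
  expect_gt(selectivity_significance(x, y, 1000, seed = 3), 0.9)
  p_sep <- selectivity_significance(1:10 + 100, 1:10, 2000, seed = 3)
  expect_lt(p_sep, 0.01)
  expect_identical(selectivity_significance(1:10 + 100, 1:10, 2000, seed = 3),
                   p_sep)
})

test_that("functional classes follow the two selectivity flags", {
  expect_equal(classify_functional(TRUE, FALSE), "visual")
  expect_equal(classify_functional(TRUE, TRUE), "visuomotor")
  expect_equal(classify_functional(FALSE, TRUE), "motor")
  expect_equal(classify_functional(FALSE, FALSE), "unclassified")
})

test_that("proportion test equals the hand chi-square and is symmetric", {
  # identical proportions: chi-square 0, p 1
  pt0 <- proportion_test(10, 10, 40, 40)
  expect_equal(pt0$chisq, 0)
  expect_equal(pt0$p, 1)
  # [[30,20],[15,35]]: hand Sum (O-E)^2/E = 9.0909...
  pt <- proportion_test(c(30, 20), c(15, 35))
  expect_equal(pt$chisq, 100 / 11, tolerance = 1e-9)
  expect_equal(pt$df, 1)
  # oracle equivalence on random tables, and symmetry under group swap
  set.seed(67)
  for (i in 1:30) {
    k <- sample(2:3, 1)
    a <- rmultinom(1, 60, runif(k) + 0.2)[, 1]
    b <- rmultinom(1, 80, runif(k) + 0.2)[, 1]
    if (any(a + b == 0)) next
    tab <- rbind(a, b)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    hand <- sum((tab - E)^2 / E)
    expect_equal(proportion_test(a, b)$chisq, hand, tolerance = 1e-10)
    expect_equal(proportion_test(b, a)$chisq, proportion_test(a, b)$chisq)
  }
})

test_that("ANCOVA group effect equals the extra-sum-of-squares F", {
  set.seed(71)
  n <- 40
  x <- runif(2 * n)
  g <- rep(c("A", "B"), each = n)
  y <- 0.3 + 0.5 * x + 0.2 * (g == "B") + rnorm(2 * n, 0, 0.1)
  res <- ancova_group_effect(x, y, g)
  rss <- function(fit) sum(residuals(fit)^2)
  f0 <- lm(y ~ x); f1 <- lm(y ~ x + factor(g))
  Fref <- (rss(f0) - rss(f1)) / (rss(f1) / (2 * n - 3))
  expect_equal(res$F, Fref, tolerance = 1e-10)
  expect_lt(res$p, 1e-6)
  expect_error(ancova_group_effect(rep(1, 2 * n), y, g), "constant")
})

test_that("ANCOVA null rejections occur at about the nominal rate", {
  set.seed(73)
  rej <- mean(replicate(400, {
    x <- runif(30); g <- rep(c("A", "B"), 15)
    y <- x + rnorm(30, 0, 0.1)
    ancova_group_effect(x, y, g)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("Pearson correlation behaves on exact and rescaled inputs", {
  x <- c(0.1, 0.2, 0.5, 0.7, 0.9)
  r1 <- efficacy_delay_correlation(x, x)
  expect_equal(r1$r, 1)
  y <- c(0.3, 0.1, 0.6, 0.4, 0.8)
  expect_equal(efficacy_delay_correlation(x, y)$r,
               efficacy_delay_correlation(10 * x - 2, 0.5 * y + 3)$r,
               tolerance = 1e-12)
  expect_error(efficacy_delay_correlation(rep(1, 5), y), "variance")
})

test_that("functional classification recovers configured gain profiles", {
  mk <- function(id, vis_gain, mot_gain) unit_config(
    id, "non_activated", baseline_rate = 10,
    epoch_gains = list(fixation = c(In = 1, Out = 1),
                       visual = c(In = vis_gain, Out = 1),
                       delay = c(In = 1, Out = 1),
                       presaccadic = c(In = mot_gain, Out = 1)))
  units <- c(lapply(1:3, function(i) mk(paste0("vis", i), 3.5, 1)),
             lapply(1:3, function(i) mk(paste0("mot", i), 1, 3.5)),
             lapply(1:2, function(i) mk(paste0("vm", i), 3, 3)),
             lapply(1:2, function(i) mk(paste0("none", i), 1, 1)))
  s <- simulate_session(simulation_config(units, n_trials = 60, seed = 79))
  sel <- selectivity_table(s, n_perm = 1000, seed = 5)
  cls <- setNames(sel$functional_class, sel$unit_id)
  truth <- c(rep("visual", 3), rep("motor", 3), rep("visuomotor", 2),
             rep("unclassified", 2))
  names(truth) <- vapply(units, function(u) u$unit_id, character(1))
  # >= 90% of the configured classes are recovered
  expect_gte(mean(cls[names(truth)] == truth), 0.9)
})
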