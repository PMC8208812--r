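#' Per-trial firing rates in a task epoch
#'
#' Spike count in the epoch window divided by the window length, in Hz.
#' Epoch windows are resolved per trial from the task events (see
#' [analysis_windows()]).
#'
#' @param session a [wm_session()].
#' @param unit_id unit to analyse.
#' @param epoch one of `"visual_epoch"`, `"delay_epoch"`, `"motor_epoch"`,
#'   `"fixation_baseline"`, `"motor_baseline"`.
#' @param trial_ids optional trial filter.
#' @param windows an [analysis_windows()] list.
#' @return data.frame `trial_id`, `rate` (Hz), in trial-table order.
#' @export
epoch_rate <- function(session, unit_id, epoch, trial_ids = NULL,
                       windows = analysis_windows()) {
  stopifnot(inherits(session, "wm_session"))
  tr <- session$trials
  if (!is.null(trial_ids)) tr <- tr[tr$trial_id %in% trial_ids, , drop = FALSE]
  w <- epoch_window(tr, epoch, windows)
  if (any(w$lo < 0))
    stop("epoch window extends before trial start for trial(s) ",
         paste(utils::head(w$trial_id[w$lo < 0], 5), collapse = ", "))
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  counts <- .window_counts(sp, w$trial_id, w$lo, w$hi)
  data.frame(trial_id = w$trial_id, rate = counts / ((w$hi - w$lo) / 1000))
}

#' Task-epoch activity significance (sign-rank against baseline)
#'
#' Tests whether a unit's activity in a task epoch is significantly
#' enhanced over its own baseline on In-condition trials, with the paired
#' Wilcoxon sign-rank test (p < 0.05 by default). Visual and delay epochs
#' are compared with the pre-cue fixation baseline; the motor epoch with
#' saccade-aligned activity earlier in the trial (450-250 ms before
#' saccade onset). Only enhancement counts: the flag requires both
#' significance and epoch median rate above baseline median rate.
#'
#' @param session,unit_id as in [epoch_rate()].
#' @param epoch epoch to test.
#' @param baseline baseline epoch (default chosen by `epoch`:
#'   `motor_baseline` for the motor epoch, else `fixation_baseline`).
#' @param condition trials to use (default `"In"`).
#' @param use_stimulated include stimulated trials (default FALSE: epoch
#'   rates on stimulated trials are contaminated by evoked spikes).
#' @param alpha significance level.
#' @param windows an [analysis_windows()] list.
#' @return list `flag`, `p`, `epoch_median`, `baseline_median`, `n`.
#' @export
activity_significance <- function(session, unit_id, epoch, baseline = NULL,
                                  condition = "In", use_stimulated = FALSE,
                                  alpha = 0.05, windows = analysis_windows()) {
  if (is.null(baseline))
    baseline <- if (epoch == "motor_epoch") "motor_baseline" else "fixation_baseline"
  tr <- session$trials[session$trials$condition %in% condition, , drop = FALSE]
  if (!use_stimulated) tr <- tr[!tr$stimulated, , drop = FALSE]
  if (nrow(tr) < 6)
    stop("at least 6 trials are required for the sign-rank test")
  x <- epoch_rate(session, unit_id, epoch, tr$trial_id, windows)$rate
  y <- epoch_rate(session, unit_id, baseline, tr$trial_id, windows)$rate
  d <- x - y
  if (all(d == 0)) {
    return(list(flag = FALSE, p = 1, epoch_median = median(x),
                baseline_median = median(y), n = length(d)))
  }
  p <- suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
  list(flag = (p < alpha) && (median(x) > median(y)), p = p,
       epoch_median = median(x), baseline_median = median(y), n = length(d))
}

#' ROC selectivity between memory conditions
#'
#' Area under the ROC curve separating the firing-rate distributions of In
#' and Out trials, computed by the criterion-sweep construction: the
#' criterion is stepped through all observed rates (plus a supremum point),
#' the probability of exceeding each criterion is computed for both
#' conditions, and the curve is integrated trapezoidally. Ties contribute
#' half weight, so the AUC equals the tie-corrected Mann-Whitney
#' U / (n_In * n_Out). 0.5 is no selectivity; 1 means every In rate
#' exceeds every Out rate.
#'
#' @param rates_in,rates_out numeric vectors of per-trial rates.
#' @return AUC in `[0, 1]`.
#' @export
roc_selectivity <- function(rates_in, rates_out) {
  stopifnot(length(rates_in) > 0, length(rates_out) > 0)
  crit <- sort(unique(c(rates_in, rates_out)))
  # P(rate > c) for each criterion, plus the (0,0) supremum point
  px <- c(vapply(crit, function(cc) mean(rates_in > cc), numeric(1)), 0)
  py <- c(vapply(crit, function(cc) mean(rates_out > cc), numeric(1)), 0)
  # prepend the all-pass point (criterion below every rate)
  px <- c(1, px); py <- c(1, py)
  # trapezoidal area under x = P_out (false alarms), y = P_in (hits)
  auc <- 0
  for (i in seq_len(length(px) - 1)) {
    auc <- auc + (py[i] - py[i + 1]) * (px[i] + px[i + 1]) / 2
  }
  auc
}

#' Permutation significance of ROC selectivity
#'
#' Two-sided permutation p-value for `|AUC - 0.5|` under exchange of the
#' In/Out labels; `p = (1 + #{|AUC_perm - 0.5| >= |AUC_obs - 0.5|}) /
#' (n_perm + 1)`.
#'
#' @param rates_in,rates_out numeric vectors of per-trial rates.
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer seed.
#' @return p-value.
#' @export
selectivity_significance <- function(rates_in, rates_out, n_perm = 2000,
                                     seed = 1) {
  stopifnot(n_perm >= 1000)
  obs <- abs(roc_selectivity(rates_in, rates_out) - 0.5)
  pooled <- c(rates_in, rates_out)
  n1 <- length(rates_in)
  n2 <- length(rates_out)
  # inside the loop the AUC is evaluated through the tie-corrected
  # Mann-Whitney identity on fixed midranks (identical to the sweep)
  r <- rank(pooled)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n1 + n2, n1)
    a <- abs((sum(r[idx]) - n1 * (n1 + 1) / 2) / (n1 * n2) - 0.5)
    if (a >= obs - 1e-12) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

#' Functional classification from epoch selectivity
#'
#' Maps the pair of selectivity flags to the functional class: visual-only
#' selectivity gives `visual`, motor-only gives `motor`, both give
#' `visuomotor`, neither gives `unclassified`.
#'
#' @param visual_sig,motor_sig logical flags.
#' @return character class.
#' @export
classify_functional <- function(visual_sig, motor_sig) {
  ifelse(visual_sig & motor_sig, "visuomotor",
         ifelse(visual_sig, "visual",
                ifelse(motor_sig, "motor", "unclassified")))
}

#' Selectivity profile of one unit
#'
#' Epoch rates, activity significance (vs baseline, In condition), ROC
#' selectivity (In vs Out) with permutation p-values for the visual, delay
#' (memory) and motor epochs, and the functional class derived from the
#' visual/motor selectivity flags. Computed on non-stimulated trials.
#'
#' @param session,unit_id as in [epoch_rate()].
#' @param n_perm,alpha permutation count and significance level.
#' @param seed seed for the permutation tests.
#' @param windows an [analysis_windows()] list.
#' @return one-row data.frame (see `selectivity_table` columns).
#' @export
selectivity_profile <- function(session, unit_id, n_perm = 2000, alpha = 0.05,
                                seed = 1, windows = analysis_windows()) {
  tr <- session$trials[!session$trials$stimulated, , drop = FALSE]
  rates <- function(epoch, cnd)
    epoch_rate(session, unit_id, epoch,
               tr$trial_id[tr$condition == cnd], windows)$rate
  epochs <- c(visual = "visual_epoch", memory = "delay_epoch",
              motor = "motor_epoch")
  out <- data.frame(unit_id = unit_id)
  aucs <- numeric(3); names(aucs) <- names(epochs)
  flags <- logical(3); names(flags) <- names(epochs)
  sel_p <- numeric(3); names(sel_p) <- names(epochs)
  for (k in names(epochs)) {
    act <- activity_significance(session, unit_id, epochs[[k]],
                                 alpha = alpha, windows = windows)
    rin <- rates(epochs[[k]], "In"); rout <- rates(epochs[[k]], "Out")
    aucs[k] <- roc_selectivity(rin, rout)
    sel_p[k] <- selectivity_significance(rin, rout, n_perm, seed)
    flags[k] <- act$flag
    out[[paste0("rate_in_", k)]] <- mean(rin)
    out[[paste0("rate_out_", k)]] <- mean(rout)
    out[[paste0(k, "_activity_p")]] <- act$p
    out[[paste0(k, "_activity_sig")]] <- act$flag
    out[[paste0("auc_", k)]] <- aucs[k]
    out[[paste0(k, "_selectivity_p")]] <- sel_p[k]
  }
  out$functional_class <- classify_functional(sel_p["visual"] < alpha,
                                              sel_p["motor"] < alpha)
  out
}

#' Selectivity table for a set of units
#'
#' @param session a [wm_session()].
#' @param unit_ids units to profile (default all).
#' @param n_perm,alpha,seed as in [selectivity_profile()].
#' @return data.frame, one row per unit.
#' @export
selectivity_table <- function(session, unit_ids = NULL, n_perm = 2000,
                              alpha = 0.05, seed = 1) {
  if (is.null(unit_ids)) unit_ids <- session_units(session)
  out <- do.call(rbind, lapply(seq_along(unit_ids), function(i)
    selectivity_profile(session, unit_ids[i], n_perm, alpha,
                        seed = seed + i)))
  rownames(out) <- NULL
  out
}

#' Compare category proportions between two populations
#'
#' Pearson chi-square test (no continuity correction) on the 2 x k
#' contingency table of category counts for populations A and B. For a
#' single binary property, pass the count of units with the property and
#' the population size; the complement is filled in.
#'
#' @param counts_a,counts_b category counts (length k >= 1); a scalar is
#'   interpreted as the count with a binary property.
#' @param n_a,n_b population sizes (required for the scalar form; otherwise
#'   must equal `sum(counts)` when supplied).
#' @return list `chisq`, `df`, `p`, `table`.
#' @export
proportion_test <- function(counts_a, counts_b, n_a = NULL, n_b = NULL) {
  if (length(counts_a) != length(counts_b))
    stop("counts_a and counts_b must have the same length")
  if (length(counts_a) == 1) {
    if (is.null(n_a) || is.null(n_b))
      stop("population sizes are required with scalar counts")
    counts_a <- c(counts_a, n_a - counts_a)
    counts_b <- c(counts_b, n_b - counts_b)
  } else {
    if (!is.null(n_a) && sum(counts_a) != n_a)
      stop("counts_a do not sum to n_a")
    if (!is.null(n_b) && sum(counts_b) != n_b)
      stop("counts_b do not sum to n_b")
  }
  tab <- rbind(A = counts_a, B = counts_b)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' ANCOVA group effect with parallel slopes
#'
#' F-test of the group main effect in the linear model `y ~ x + group`,
#' i.e. the extra-sum-of-squares comparison of `y ~ x` against
#' `y ~ x + group`. Used to compare, e.g., motor selectivity across
#' populations at matched levels of visual selectivity.
#'
#' @param x covariate (e.g. visual AUC).
#' @param y response (e.g. motor AUC).
#' @param group factor of population labels (>= 3 points per group).
#' @return list `F`, `df1`, `df2`, `p`.
#' @export
ancova_group_effect <- function(x, y, group) {
  group <- factor(group)
  keep <- complete.cases(x, y, group)
  x <- x[keep]; y <- y[keep]; group <- droplevels(group[keep])
  if (any(table(group) < 3)) stop("at least 3 points per group are required")
  if (sd(x) == 0) stop("covariate is constant")
  fit0 <- lm(y ~ x)
  fit1 <- lm(y ~ x + group)
  a <- anova(fit0, fit1)
  list(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2], p = a$`Pr(>F)`[2])
}

#' Correlation of efficacy change with delay selectivity
#'
#' Pearson correlation (two-sided t-based p) between each unit's change in
#' evoked efficacy across memory conditions and its delay-period ROC
#' selectivity.
#'
#' @param delta_efficacy per-unit efficacy difference (In - Out).
#' @param delay_auc per-unit delay-period AUC.
#' @return list `r`, `p`, `n`.
#' @export
efficacy_delay_correlation <- function(delta_efficacy, delay_auc) {
  keep <- complete.cases(delta_efficacy, delay_auc)
  x <- delta_efficacy[keep]; y <- delay_auc[keep]
  if (length(x) < 3) stop("at least 3 units are required")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in an input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
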