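#' Peristimulation firing probabilities
#'
#' For one unit, computes the probability of firing in each 1 ms bin around
#' the stimulation pulse on stimulated trials, and in time-matched windows
#' on non-stimulated trials. Non-stimulated trials are evaluated at the
#' virtual stimulation time their epoch schedule implies; when several
#' stimulation epochs are pooled, every non-stimulated trial contributes one
#' matched window per pooled epoch. Bins inside the artifact blank are
#' flagged `masked` (their stimulated-trial probabilities are contaminated
#' by the artifact blanking and are never searched for a latency).
#'
#' @param session a [wm_session()].
#' @param unit_id unit to analyse.
#' @param stim_epochs stimulation epochs to pool (default: visual, delay and
#'   saccade pulses, the set used for identifying activated units).
#' @param window peristimulation range `c(lo, hi)` in ms (half-open bins
#'   with left edges `lo, lo+bin_ms, ..., hi-bin_ms`).
#' @param bin_ms bin width (ms).
#' @param artifact_end end of the artifact blank (ms post-stimulation).
#' @param condition optional condition filter (`"In"`/`"Out"`).
#' @return data.frame with columns `bin` (left edge, ms post-stimulation),
#'   `p_stim`, `p_nonstim`, `k_stim`, `k_nonstim`, `masked`; attributes
#'   `n_stim` and `n_nonstim` give the number of (trial x epoch) windows.
#' @export
peristim_probability <- function(session, unit_id,
                                 stim_epochs = c("visual", "delay", "saccade"),
                                 window = c(0, 20), bin_ms = 1,
                                 artifact_end = 3, condition = NULL) {
  stopifnot(inherits(session, "wm_session"))
  tr <- session$trials
  if (!is.null(condition)) tr <- tr[tr$condition %in% condition, , drop = FALSE]
  stim <- tr[tr$stimulated & tr$stim_epoch %in% stim_epochs, , drop = FALSE]
  nonstim <- tr[!tr$stimulated, , drop = FALSE]
  if (nrow(stim) == 0) stop("no stimulated trials in the requested epochs")
  epochs_present <- sort(unique(stim$stim_epoch))
  if (nrow(nonstim) == 0)
    stop("no non-stimulated trials available as a time-matched null")
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  edges <- seq(window[1], window[2] - bin_ms, by = bin_ms)

  occ_s <- .bin_occupancy(sp, stim$trial_id, stim$stim_time, edges, bin_ms)
  occ_n_list <- lapply(epochs_present, function(e)
    .bin_occupancy(sp, nonstim$trial_id, virtual_stim_time(nonstim, e),
                   edges, bin_ms))
  occ_n <- do.call(rbind, occ_n_list)

  out <- data.frame(
    bin = edges,
    p_stim = colMeans(occ_s),
    p_nonstim = colMeans(occ_n),
    k_stim = colSums(occ_s),
    k_nonstim = colSums(occ_n),
    masked = edges >= 0 & edges < artifact_end)
  attr(out, "n_stim") <- nrow(occ_s)
  attr(out, "n_nonstim") <- nrow(occ_n)
  out
}

# One-sided exact two-proportion test (Fisher): probability of >= k_s
# successes in the stimulated margin under the hypergeometric null.
.prop_test_greater <- function(k_s, n_s, k_n, n_n) {
  phyper(k_s - 1, k_s + k_n, n_s + n_n - k_s - k_n, n_s, lower.tail = FALSE)
}

#' Detect the latency of stimulation-evoked spikes
#'
#' Scans the post-stimulation 1 ms bins and returns the left edge of the
#' earliest unmasked bin in which the firing probability on stimulated
#' trials significantly exceeds the time-matched non-stimulated probability
#' (one-sided Fisher exact two-proportion test at level `alpha`, no
#' multiplicity correction). The search is restricted to bins with left
#' edges in `(artifact_end, search_max)`; with the 3 ms default blank this
#' is the 16 bins at 4..19 ms.
#'
#' @param session,unit_id,stim_epochs,condition,bin_ms,artifact_end as in
#'   [peristim_probability()].
#' @param alpha per-bin significance level.
#' @param search_max end of the search range (ms post-stimulation).
#' @param prob optional precomputed [peristim_probability()] table (with
#'   `n_stim`/`n_nonstim` attributes); when supplied the session is not
#'   touched.
#' @return list with `latency_ms` (NA when no bin qualifies), `p_values`
#'   (per searched bin), `n_stim`, `n_nonstim`.
#' @export
detect_latency <- function(session = NULL, unit_id = NULL,
                           stim_epochs = c("visual", "delay", "saccade"),
                           condition = NULL, alpha = 0.05, bin_ms = 1,
                           artifact_end = 3, search_max = 20, prob = NULL) {
  if (is.null(prob)) {
    prob <- peristim_probability(session, unit_id, stim_epochs,
                                 window = c(0, search_max), bin_ms = bin_ms,
                                 artifact_end = artifact_end,
                                 condition = condition)
  }
  n_s <- attr(prob, "n_stim"); n_n <- attr(prob, "n_nonstim")
  if (is.null(n_s) || is.null(n_n) || n_s == 0 || n_n == 0)
    stop("detect_latency requires stimulated and non-stimulated trial counts")
  search <- prob[!prob$masked & prob$bin > artifact_end &
                 prob$bin < search_max, , drop = FALSE]
  pv <- mapply(.prop_test_greater, search$k_stim, n_s, search$k_nonstim, n_n)
  hit <- which(pv < alpha)
  latency <- if (length(hit)) search$bin[hit[1]] else NA_real_
  list(latency_ms = latency,
       p_values = data.frame(bin = search$bin, p = pv),
       n_stim = n_s, n_nonstim = n_n)
}

#' Classify a unit's activation from its evoked latency
#'
#' Absent latency: `non_activated`; latency < 10 ms: `visual_recipient`
#' (fast, putatively monosynaptic input); latency >= 10 ms: `slow_input`.
#'
#' @param latency_ms numeric vector of latencies (NA = not activated).
#' @return character vector of activation classes.
#' @export
classify_activation <- function(latency_ms) {
  ifelse(is.na(latency_ms), "non_activated",
         ifelse(latency_ms < 10, "visual_recipient", "slow_input"))
}

#' Stimulation-evoked spike count, adjusted for background
#'
#' Mean spike count in the evoked window (5-9 ms post-stimulation) on
#' stimulated trials of one condition, minus the same measure in
#' time-matched windows on non-stimulated trials of that condition.
#'
#' @param session a [wm_session()].
#' @param unit_id unit to analyse.
#' @param condition `"In"` or `"Out"`.
#' @param stim_epoch stimulation epoch (default `"delay"`, the epoch used to
#'   measure the influence of working memory).
#' @param window evoked window `c(lo, hi)` ms post-stimulation (half-open).
#' @param as_probability clip each trial's windowed count at 1, yielding the
#'   per-trial probability of at least one evoked-window spike instead of
#'   the mean count.
#' @return adjusted spike count (a single number).
#' @export
evoked_spike_count <- function(session, unit_id, condition,
                               stim_epoch = "delay", window = c(5, 9),
                               as_probability = FALSE) {
  cells <- .condition_cells(session, condition, stim_epoch)
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  cs <- .window_counts(sp, cells$stim$trial_id,
                       cells$stim$stim_time + window[1],
                       cells$stim$stim_time + window[2])
  vt <- virtual_stim_time(cells$nonstim, stim_epoch)
  cn <- .window_counts(sp, cells$nonstim$trial_id,
                       vt + window[1], vt + window[2])
  if (as_probability) { cs <- pmin(cs, 1); cn <- pmin(cn, 1) }
  mean(cs) - mean(cn)
}

.condition_cells <- function(session, condition, stim_epoch) {
  tr <- session$trials[session$trials$condition == condition, , drop = FALSE]
  stim <- tr[tr$stimulated & tr$stim_epoch == stim_epoch, , drop = FALSE]
  nonstim <- tr[!tr$stimulated, , drop = FALSE]
  if (nrow(stim) == 0)
    stop("no stimulated ", stim_epoch, "-epoch trials in condition ", condition)
  if (nrow(nonstim) == 0)
    stop("no non-stimulated trials in condition ", condition)
  list(stim = stim, nonstim = nonstim)
}

#' Evoked response magnitude (log-ratio statistic)
#'
#' Quantifies the efficacy of stimulation as the log10 ratio of summed
#' spike counts after versus before the pulse, minus the same measure in
#' time-matched windows on non-stimulated trials:
#' `log10((A_s + e)/(B_s + e)) - log10((A_n + e)/(B_n + e))`,
#' where A/B are the after/before counts summed over stimulated (s) and
#' non-stimulated (n) trials. The default after window is the evoked window
#' 5-9 ms; the before window mirrors it at -9 to -5 ms. The pseudocount `e`
#' defaults to 0.5 when any of the four counts is zero, else 0.
#'
#' @param session,unit_id,condition,stim_epoch as in [evoked_spike_count()].
#' @param before,after count windows in ms relative to the (virtual)
#'   stimulation time, half-open.
#' @param pseudocount pseudocount `e`; NULL for the adaptive default.
#' @return response magnitude (a single number).
#' @export
response_magnitude <- function(session, unit_id, condition,
                               stim_epoch = "delay",
                               before = c(-9, -5), after = c(5, 9),
                               pseudocount = NULL) {
  cells <- .condition_cells(session, condition, stim_epoch)
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  st <- cells$stim$stim_time
  vt <- virtual_stim_time(cells$nonstim, stim_epoch)
  A_s <- sum(.window_counts(sp, cells$stim$trial_id, st + after[1], st + after[2]))
  B_s <- sum(.window_counts(sp, cells$stim$trial_id, st + before[1], st + before[2]))
  A_n <- sum(.window_counts(sp, cells$nonstim$trial_id, vt + after[1], vt + after[2]))
  B_n <- sum(.window_counts(sp, cells$nonstim$trial_id, vt + before[1], vt + before[2]))
  log_ratio_magnitude(A_s, B_s, A_n, B_n, pseudocount)
}

#' Closed form of the response-magnitude statistic
#'
#' @param A_s,B_s after/before summed counts on stimulated trials.
#' @param A_n,B_n after/before summed counts on non-stimulated trials.
#' @param pseudocount pseudocount; NULL for 0.5 if any count is zero, else 0.
#' @return `log10((A_s+e)/(B_s+e)) - log10((A_n+e)/(B_n+e))`.
#' @export
log_ratio_magnitude <- function(A_s, B_s, A_n, B_n, pseudocount = NULL) {
  e <- if (is.null(pseudocount)) {
    if (any(c(A_s, B_s, A_n, B_n) == 0)) 0.5 else 0
  } else pseudocount
  log10((A_s + e) / (B_s + e)) - log10((A_n + e) / (B_n + e))
}

#' Mean evoked-spike latency by condition
#'
#' Mean over stimulated trials of the time of the first spike falling in
#' the evoked window (5-9 ms post-stimulation), in ms after the pulse.
#' Trials without an evoked-window spike are excluded.
#'
#' @param session,unit_id,condition,stim_epoch,window as in
#'   [evoked_spike_count()].
#' @return mean latency in ms, or NA when no trial has an evoked-window
#'   spike.
#' @export
evoked_latency_by_condition <- function(session, unit_id, condition,
                                        stim_epoch = "delay",
                                        window = c(5, 9)) {
  cells <- .condition_cells(session, condition, stim_epoch)
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  stim <- cells$stim
  idx <- match(sp$trial_id, stim$trial_id)
  keep <- !is.na(idx)
  if (!any(keep)) return(NA_real_)
  rel <- sp$time_ms[keep] - stim$stim_time[idx[keep]]
  i <- idx[keep]
  inwin <- rel >= window[1] & rel < window[2]
  if (!any(inwin)) return(NA_real_)
  firsts <- tapply(rel[inwin], i[inwin], min)
  mean(firsts)
}

#' Population-normalized evoked time course
#'
#' For each unit, the per-bin stimulated-trial firing probability minus the
#' time-matched non-stimulated probability, scaled by the unit's peak
#' absolute deviation; the population trace is the across-unit mean. Units
#' whose peak deviation is zero are skipped with a warning.
#'
#' @param session a [wm_session()].
#' @param unit_ids units to average (typically the visual-recipient
#'   population).
#' @param stim_epochs,window,bin_ms,artifact_end as in
#'   [peristim_probability()].
#' @return data.frame `bin`, `mean_normalized`, `n_units`; attribute
#'   `per_unit` holds the unit x bin matrix of normalized deviations.
#' @export
normalized_evoked_timecourse <- function(session, unit_ids,
                                         stim_epochs = c("visual", "delay", "saccade"),
                                         window = c(-20, 20), bin_ms = 1,
                                         artifact_end = 3) {
  if (!length(unit_ids)) stop("at least one unit is required")
  traces <- list()
  for (u in unit_ids) {
    pr <- peristim_probability(session, u, stim_epochs, window, bin_ms,
                               artifact_end)
    dev <- pr$p_stim - pr$p_nonstim
    peak <- max(abs(dev))
    if (peak == 0) {
      warning("unit ", u, " has zero peak deviation; skipped")
      next
    }
    traces[[u]] <- dev / peak
  }
  if (!length(traces)) stop("no unit with non-zero evoked deviation")
  m <- do.call(rbind, traces)
  edges <- seq(window[1], window[2] - bin_ms, by = bin_ms)
  out <- data.frame(bin = edges, mean_normalized = colMeans(m),
                    n_units = nrow(m))
  attr(out, "per_unit") <- m
  out
}

#' Activation table for all units of a session
#'
#' Runs [detect_latency()] and [classify_activation()] on every unit,
#' pooling the stimulation epochs used for identification.
#'
#' @param session a [wm_session()].
#' @param stim_epochs epochs pooled for identification.
#' @param alpha,artifact_end,search_max as in [detect_latency()].
#' @return data.frame `unit_id`, `latency_ms`, `activation_class`,
#'   `n_stim`, `n_nonstim`.
#' @export
activation_table <- function(session,
                             stim_epochs = c("visual", "delay", "saccade"),
                             alpha = 0.05, artifact_end = 3,
                             search_max = 20) {
  units <- session_units(session)
  rows <- lapply(units, function(u) {
    d <- detect_latency(session, u, stim_epochs, alpha = alpha,
                        artifact_end = artifact_end, search_max = search_max)
    data.frame(unit_id = u, latency_ms = d$latency_ms,
               activation_class = classify_activation(d$latency_ms),
               n_stim = d$n_stim, n_nonstim = d$n_nonstim)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evoked efficacy table by unit and condition
#'
#' Adjusted spike count, adjusted per-trial evoked-spike probability,
#' log-ratio response magnitude and mean evoked latency for each unit and
#' memory condition, using the delay-period stimulation trials.
#'
#' @param session a [wm_session()].
#' @param unit_ids units to tabulate (default all).
#' @param stim_epoch stimulation epoch (default `"delay"`).
#' @return data.frame `unit_id`, `condition`, `adjusted_spike_count`,
#'   `adjusted_spike_prob`, `response_magnitude`, `evoked_latency_ms`.
#' @export
evoked_efficacy_table <- function(session, unit_ids = NULL,
                                  stim_epoch = "delay") {
  if (is.null(unit_ids)) unit_ids <- session_units(session)
  if (!length(unit_ids)) {
    return(data.frame(unit_id = character(0), condition = character(0),
                      adjusted_spike_count = numeric(0),
                      adjusted_spike_prob = numeric(0),
                      response_magnitude = numeric(0),
                      evoked_latency_ms = numeric(0)))
  }
  grid <- expand.grid(unit_id = unit_ids, condition = .conditions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    u <- grid$unit_id[i]; cnd <- grid$condition[i]
    data.frame(
      unit_id = u, condition = cnd,
      adjusted_spike_count = evoked_spike_count(session, u, cnd, stim_epoch),
      adjusted_spike_prob = evoked_spike_count(session, u, cnd, stim_epoch,
                                               as_probability = TRUE),
      response_magnitude = response_magnitude(session, u, cnd, stim_epoch),
      evoked_latency_ms = evoked_latency_by_condition(session, u, cnd,
                                                      stim_epoch))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$unit_id, out$condition), ]
  rownames(out) <- NULL
  out
}
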