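# Per-trial bin occupancy for both members of a pair, for the 1 ms bins of
# the evoked window, on a given trial set aligned to (virtual) stim times.
.pair_occupancy <- function(session, unit_a, unit_b, trials, anchor,
                            window = c(5, 9), bin_ms = 1) {
  # bins with left edges window[1]..window[2] inclusive (5 bins by default:
  # the joint statistic is "averaged between 5 and 9 ms")
  edges <- seq(window[1], window[2], by = bin_ms)
  sp <- session$spikes
  spa <- sp[sp$unit_id == unit_a, , drop = FALSE]
  spb <- sp[sp$unit_id == unit_b, , drop = FALSE]
  list(A = .bin_occupancy(spa, trials$trial_id, anchor, edges, bin_ms),
       B = .bin_occupancy(spb, trials$trial_id, anchor, edges, bin_ms),
       edges = edges)
}

.joint_from_occ <- function(A, B) mean(colMeans(A & B))

#' Raw joint-spike proportion of a pair
#'
#' For each 1 ms bin of the evoked window (left edges 5..8 ms
#' post-stimulation by default), the fraction of trials on which both units
#' of a pair spike in the same bin; the statistic is the mean over bins.
#' Coincidence is operationalized as co-occupancy of the same 1 ms bin.
#'
#' @param session a [wm_session()].
#' @param unit_a,unit_b the pair.
#' @param condition memory condition (`"In"`/`"Out"`).
#' @param stimulated use stimulated trials (TRUE) or non-stimulated trials
#'   evaluated at virtual stimulation times (FALSE).
#' @param stim_epoch stimulation epoch (default `"delay"`).
#' @param window evoked window (ms post-stimulation, half-open bins).
#' @param bin_ms coincidence bin width.
#' @return the raw joint-spike proportion.
#' @export
joint_spike_proportion <- function(session, unit_a, unit_b, condition,
                                   stimulated = TRUE, stim_epoch = "delay",
                                   window = c(5, 9), bin_ms = 1) {
  tr <- .synchrony_trials(session, condition, stimulated, stim_epoch)
  occ <- .pair_occupancy(session, unit_a, unit_b, tr$trials, tr$anchor,
                         window, bin_ms)
  .joint_from_occ(occ$A, occ$B)
}

.synchrony_trials <- function(session, condition, stimulated, stim_epoch) {
  tr <- session$trials[session$trials$condition == condition, , drop = FALSE]
  if (stimulated) {
    trials <- tr[tr$stimulated & tr$stim_epoch == stim_epoch, , drop = FALSE]
    if (!nrow(trials))
      stop("no stimulated ", stim_epoch, "-epoch trials in condition ",
           condition)
    anchor <- trials$stim_time
  } else {
    trials <- tr[!tr$stimulated, , drop = FALSE]
    if (!nrow(trials))
      stop("no non-stimulated trials in condition ", condition)
    anchor <- virtual_stim_time(trials, stim_epoch)
  }
  list(trials = trials, anchor = anchor)
}

#' Shuffle-corrected joint-spike proportion
#'
#' Controls the joint-spike proportion for firing rate by subtracting the
#' mean proportion obtained after randomly permuting the trial assignment
#' of the second unit within the same condition and stimulation status:
#' `corrected = raw - mean over shuffles`. Seeded and reproducible.
#'
#' @param session,unit_a,unit_b,condition,stimulated,stim_epoch,window,bin_ms
#'   as in [joint_spike_proportion()].
#' @param n_shuffles number of trial shuffles (>= 100).
#' @param seed integer seed.
#' @return list `raw`, `shuffle_mean`, `corrected`, `n_trials`.
#' @export
shuffle_corrected_joint <- function(session, unit_a, unit_b, condition,
                                    stimulated = TRUE, stim_epoch = "delay",
                                    n_shuffles = 1000, seed = 1,
                                    window = c(5, 9), bin_ms = 1) {
  stopifnot(n_shuffles >= 100)
  tr <- .synchrony_trials(session, condition, stimulated, stim_epoch)
  n <- nrow(tr$trials)
  if (n < 2) stop("at least 2 trials are required to shuffle")
  occ <- .pair_occupancy(session, unit_a, unit_b, tr$trials, tr$anchor,
                         window, bin_ms)
  raw <- .joint_from_occ(occ$A, occ$B)
  set.seed(seed)
  sh <- numeric(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    perm <- sample.int(n)
    sh[i] <- .joint_from_occ(occ$A, occ$B[perm, , drop = FALSE])
  }
  list(raw = raw, shuffle_mean = mean(sh), corrected = raw - mean(sh),
       n_trials = n)
}

#' Fully adjusted joint-spike proportion of a pair
#'
#' The stimulation-evoked synchrony statistic: the shuffle-corrected joint
#' proportion on stimulated trials minus the same quantity on time-matched
#' non-stimulated trials,
#' `adjusted = (raw - shuffle)_stim - (raw - shuffle)_nonstim`.
#' The shuffle correction removes rate-driven coincidences within each
#' trial set; the non-stimulation subtraction removes background synchrony
#' and rate changes due to the memory condition, leaving only the change in
#' synchronous firing attributable to stimulation.
#'
#' @param session,unit_a,unit_b,condition,stim_epoch,window,bin_ms as in
#'   [joint_spike_proportion()].
#' @param n_shuffles,seed as in [shuffle_corrected_joint()].
#' @return one-row data.frame: `unit_a`, `unit_b`, `condition`,
#'   `raw_joint`, `shuffle_mean`, `nonstim_joint`, `nonstim_shuffle_mean`,
#'   `adjusted_joint`.
#' @export
adjusted_joint_proportion <- function(session, unit_a, unit_b, condition,
                                      stim_epoch = "delay", n_shuffles = 1000,
                                      seed = 1, window = c(5, 9), bin_ms = 1) {
  s <- shuffle_corrected_joint(session, unit_a, unit_b, condition,
                               stimulated = TRUE, stim_epoch = stim_epoch,
                               n_shuffles = n_shuffles, seed = seed,
                               window = window, bin_ms = bin_ms)
  n <- shuffle_corrected_joint(session, unit_a, unit_b, condition,
                               stimulated = FALSE, stim_epoch = stim_epoch,
                               n_shuffles = n_shuffles, seed = seed + 1,
                               window = window, bin_ms = bin_ms)
  data.frame(unit_a = unit_a, unit_b = unit_b, condition = condition,
             raw_joint = s$raw, shuffle_mean = s$shuffle_mean,
             nonstim_joint = n$raw, nonstim_shuffle_mean = n$shuffle_mean,
             adjusted_joint = s$corrected - n$corrected)
}

#' Synchrony table for the pairs of a session
#'
#' [adjusted_joint_proportion()] for every listed pair and both memory
#' conditions.
#'
#' @param session a [wm_session()].
#' @param pairs data.frame `unit_a`, `unit_b` (default `session$pairs`).
#' @param stim_epoch,n_shuffles,seed,window,bin_ms as in
#'   [adjusted_joint_proportion()].
#' @return data.frame, two rows (conditions) per pair.
#' @export
synchrony_table <- function(session, pairs = NULL, stim_epoch = "delay",
                            n_shuffles = 1000, seed = 1, window = c(5, 9),
                            bin_ms = 1) {
  if (is.null(pairs)) pairs <- session$pairs
  if (!nrow(pairs)) {
    return(data.frame(unit_a = character(0), unit_b = character(0),
                      condition = character(0), raw_joint = numeric(0),
                      shuffle_mean = numeric(0), nonstim_joint = numeric(0),
                      nonstim_shuffle_mean = numeric(0),
                      adjusted_joint = numeric(0)))
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (cnd in .conditions) {
      rows[[length(rows) + 1]] <- adjusted_joint_proportion(
        session, pairs$unit_a[i], pairs$unit_b[i], cnd, stim_epoch,
        n_shuffles, seed = seed + 7 * i + (cnd == "Out"), window, bin_ms)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population contrast of evoked synchrony between memory conditions
#'
#' Paired sign-rank test across pairs of the adjusted joint proportion in
#' the In versus Out condition, with per-condition means and the percent
#' change from Out to In.
#'
#' @param synchrony a [synchrony_table()] result.
#' @return list `mean_in`, `mean_out`, `percent_change`, `p`
#'   (sign-rank), `n_pairs`, `differences` (per-pair In - Out).
#' @export
synchrony_condition_contrast <- function(synchrony) {
  key <- paste(synchrony$unit_a, synchrony$unit_b)
  a_in <- synchrony$adjusted_joint[synchrony$condition == "In"]
  a_out <- synchrony$adjusted_joint[synchrony$condition == "Out"]
  key_in <- key[synchrony$condition == "In"]
  key_out <- key[synchrony$condition == "Out"]
  a_out <- a_out[match(key_in, key_out)]
  keep <- complete.cases(a_in, a_out)
  a_in <- a_in[keep]; a_out <- a_out[keep]
  if (length(a_in) < 6)
    stop("at least 6 pairs are required for the population contrast")
  p <- suppressWarnings(wilcox.test(a_in, a_out, paired = TRUE)$p.value)
  list(mean_in = mean(a_in), mean_out = mean(a_out),
       percent_change = 100 * (mean(a_in) - mean(a_out)) / mean(a_out),
       p = p, n_pairs = length(a_in), differences = a_in - a_out)
}
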