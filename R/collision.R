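#' Collision test for antidromic activation
#'
#' Separates antidromically activated units (whose axons project to the
#' stimulated site) from orthodromically activated units. When the pulse
#' arrives within a few milliseconds of a spontaneously generated spike, an
#' antidromic spike is annihilated by collision in the axon, whereas an
#' orthodromic (synaptically driven) response survives.
#'
#' Stimulated trials are partitioned by the presence of a spontaneous spike
#' in `[stim_time - collision_window_ms, stim_time)`. Evoked-spike presence
#' is assessed in `[latency - 1, latency + 1]` ms post-stimulation. The
#' verdict is `antidromic` when the clear-trial evoked probability
#' significantly exceeds the matched non-stimulated rate (one-sided Fisher
#' exact, level `alpha`) and the collision-trial probability is at most
#' `elimination_ratio` times the clear-trial probability; `orthodromic`
#' when the clear-trial response is significant and collision leaves the
#' evoked probability statistically indistinguishable (two-sided Fisher
#' exact, level `alpha`); otherwise, or when either trial class has fewer
#' than `min_trials` trials, `indeterminate`.
#'
#' @param session a [wm_session()].
#' @param unit_id unit to test; must have a detected latency.
#' @param latency_ms the unit's detected evoked latency (e.g. from
#'   [detect_latency()]).
#' @param stim_epochs stimulation epochs pooled for the test.
#' @param collision_window_ms length of the pre-pulse collision window.
#' @param elimination_ratio maximal collision/clear probability ratio
#'   compatible with annihilation.
#' @param min_trials minimum number of trials per class.
#' @param alpha significance level for the Fisher tests.
#' @return data.frame row: `unit_id`, `p_evoked_collision`,
#'   `p_evoked_clear`, `n_collision`, `n_clear`, `verdict`.
#' @export
collision_test <- function(session, unit_id, latency_ms,
                           stim_epochs = c("visual", "delay", "saccade"),
                           collision_window_ms = 4, elimination_ratio = 0.25,
                           min_trials = 10, alpha = 0.05) {
  stopifnot(inherits(session, "wm_session"))
  if (is.na(latency_ms))
    stop("collision_test requires an activated unit (non-missing latency)")
  tr <- session$trials
  stim <- tr[tr$stimulated & tr$stim_epoch %in% stim_epochs, , drop = FALSE]
  nonstim <- tr[!tr$stimulated, , drop = FALSE]
  if (!nrow(stim)) stop("no stimulated trials in the requested epochs")
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]

  # spontaneous spike in the pre-pulse collision window?
  pre <- .window_counts(sp, stim$trial_id,
                        stim$stim_time - collision_window_ms,
                        stim$stim_time) > 0
  win_lo <- latency_ms - 1; win_hi <- latency_ms + 1
  evoked <- .window_counts(sp, stim$trial_id,
                           stim$stim_time + win_lo,
                           stim$stim_time + win_hi) > 0
  n_coll <- sum(pre); n_clear <- sum(!pre)
  k_coll <- sum(evoked[pre]); k_clear <- sum(evoked[!pre])
  p_coll <- if (n_coll > 0) k_coll / n_coll else NA_real_
  p_clear <- if (n_clear > 0) k_clear / n_clear else NA_real_

  verdict <- "indeterminate"
  if (n_coll >= min_trials && n_clear >= min_trials) {
    # null rate from time-matched non-stimulated windows (pooled epochs)
    ep <- sort(unique(stim$stim_epoch))
    k_null <- 0; n_null <- 0
    for (e in ep) {
      vt <- virtual_stim_time(nonstim, e)
      k_null <- k_null + sum(.window_counts(sp, nonstim$trial_id,
                                            vt + win_lo, vt + win_hi) > 0)
      n_null <- n_null + nrow(nonstim)
    }
    clear_sig <- .prop_test_greater(k_clear, n_clear, k_null, n_null) < alpha
    diff_p <- fisher.test(matrix(c(k_coll, n_coll - k_coll,
                                   k_clear, n_clear - k_clear), nrow = 2))$p.value
    if (clear_sig && p_coll <= elimination_ratio * p_clear) {
      verdict <- "antidromic"
    } else if (clear_sig && diff_p >= alpha) {
      verdict <- "orthodromic"
    }
  }
  data.frame(unit_id = unit_id, p_evoked_collision = p_coll,
             p_evoked_clear = p_clear, n_collision = n_coll,
             n_clear = n_clear, verdict = verdict)
}

#' Partition a population into activation classes
#'
#' Combines latency-based activation classes with the collision test:
#' units with an antidromic verdict are removed from the visual-recipient
#' pool (the antidromic label takes precedence over the latency class)
#' before any efficacy or selectivity analysis.
#'
#' @param session a [wm_session()].
#' @param activation optional precomputed [activation_table()].
#' @param stim_epochs,collision_window_ms,elimination_ratio,min_trials,alpha
#'   passed to [collision_test()].
#' @return data.frame `unit_id`, `latency_ms`, `label` (one of
#'   `antidromic`, `visual_recipient`, `slow_input`, `non_activated`),
#'   plus the collision-test columns for tested units; attribute `counts`
#'   holds the per-label table.
#' @export
partition_population <- function(session, activation = NULL,
                                 stim_epochs = c("visual", "delay", "saccade"),
                                 collision_window_ms = 4,
                                 elimination_ratio = 0.25, min_trials = 10,
                                 alpha = 0.05) {
  if (is.null(activation)) activation <- activation_table(session, stim_epochs)
  rows <- lapply(seq_len(nrow(activation)), function(i) {
    a <- activation[i, ]
    out <- data.frame(unit_id = a$unit_id, latency_ms = a$latency_ms,
                      label = a$activation_class,
                      p_evoked_collision = NA_real_,
                      p_evoked_clear = NA_real_, verdict = NA_character_)
    if (!is.na(a$latency_ms)) {
      ct <- collision_test(session, a$unit_id, a$latency_ms, stim_epochs,
                           collision_window_ms, elimination_ratio,
                           min_trials, alpha)
      out$p_evoked_collision <- ct$p_evoked_collision
      out$p_evoked_clear <- ct$p_evoked_clear
      out$verdict <- ct$verdict
      if (ct$verdict == "antidromic") out$label <- "antidromic"
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- table(factor(out$label,
    levels = c("antidromic", "visual_recipient", "slow_input", "non_activated")))
  out
}
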