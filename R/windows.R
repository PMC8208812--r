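#' Analysis windows and binning conventions
#'
#' Returns the fixed analysis grid used throughout the package. All windows
#' are half-open intervals `[a, b)` in ms; spike binning uses half-open 1 ms
#' bins `[t, t+1)`.
#'
#' * `evoked_window`: 5-9 ms post-stimulation, the period over which evoked
#'   responses are measured (consistent with the latency of fast,
#'   putatively monosynaptic activation).
#' * `artifact_blank`: `[0, artifact_end)` ms post-stimulation, blanked for
#'   the electrical artifact.
#' * `visual_epoch`: 100-1000 ms after cue onset.
#' * `delay_epoch`: 300-1000 ms after cue offset.
#' * `motor_epoch`: 125 ms before saccade onset.
#' * `fixation_baseline`: 300 ms before cue onset.
#' * `motor_baseline`: 450-250 ms before saccade onset.
#'
#' @param artifact_end end of the post-stimulation artifact blank in ms.
#' @param bin_ms analysis bin width in ms.
#' @return list of window definitions; epoch windows are given as
#'   `(anchor event, offset_lo, offset_hi)`.
#' @export
analysis_windows <- function(artifact_end = 3, bin_ms = 1) {
  stopifnot(artifact_end >= 0, artifact_end < 5, bin_ms > 0)
  list(
    bin_ms = bin_ms,
    artifact_end = artifact_end,
    evoked_window = c(5, 9),
    artifact_blank = c(0, artifact_end),
    visual_epoch = list(anchor = "cue_on", lo = 100, hi = 1000),
    delay_epoch = list(anchor = "cue_off", lo = 300, hi = 1000),
    motor_epoch = list(anchor = "saccade_onset", lo = -125, hi = 0),
    fixation_baseline = list(anchor = "cue_on", lo = -300, hi = 0),
    motor_baseline = list(anchor = "saccade_onset", lo = -450, hi = -250)
  )
}

#' Resolve an epoch window to absolute trial times
#'
#' @param trials trial table (or one-row subset).
#' @param epoch one of `"visual_epoch"`, `"delay_epoch"`, `"motor_epoch"`,
#'   `"fixation_baseline"`, `"motor_baseline"`.
#' @param windows an [analysis_windows()] list.
#' @return data.frame `trial_id`, `lo`, `hi` (absolute ms, half-open).
#' @export
epoch_window <- function(trials, epoch, windows = analysis_windows()) {
  w <- windows[[epoch]]
  if (is.null(w) || !is.list(w)) stop("unknown epoch: ", epoch)
  anchor <- trials[[w$anchor]]
  data.frame(trial_id = trials$trial_id, lo = anchor + w$lo, hi = anchor + w$hi)
}

#' Virtual stimulation times for non-stimulated trials
#'
#' Non-stimulated trials serve as the time-matched null for every evoked
#' measure; they are evaluated at the stimulation time their epoch schedule
#' would imply (500 ms after fixation onset, cue onset or cue offset; 150 ms
#' after the go cue).
#'
#' @param trials trial table.
#' @param stim_epoch epoch label.
#' @return numeric vector of virtual stimulation times (ms from trial start).
#' @export
virtual_stim_time <- function(trials, stim_epoch) {
  if (!stim_epoch %in% names(.epoch_stim_offsets))
    stop("unknown stimulation epoch: ", stim_epoch)
  trials[[.epoch_stim_anchor[[stim_epoch]]]] + .epoch_stim_offsets[[stim_epoch]]
}

# Count spikes of one unit per trial within [lo, hi) absolute windows.
# `spikes` is the session spike table already filtered to one unit.
.window_counts <- function(spikes, trial_ids, lo, hi) {
  counts <- numeric(length(trial_ids))
  if (nrow(spikes)) {
    idx <- match(spikes$trial_id, trial_ids)
    keep <- !is.na(idx)
    if (any(keep)) {
      t <- spikes$time_ms[keep]
      i <- idx[keep]
      inwin <- t >= lo[i] & t < hi[i]
      if (any(inwin)) {
        tab <- tabulate(i[inwin], nbins = length(trial_ids))
        counts <- tab
      }
    }
  }
  counts
}

# Per-trial bin occupancy matrix: rows = trials, cols = 1 ms bins with left
# edges `bin_edges` (relative to per-trial anchor times `anchor`), entries
# TRUE if the unit spiked in [edge, edge + bin_ms) on that trial.
.bin_occupancy <- function(spikes, trial_ids, anchor, bin_edges, bin_ms = 1) {
  nb <- length(bin_edges)
  occ <- matrix(FALSE, nrow = length(trial_ids), ncol = nb)
  if (!nrow(spikes)) return(occ)
  idx <- match(spikes$trial_id, trial_ids)
  keep <- !is.na(idx)
  if (!any(keep)) return(occ)
  rel <- spikes$time_ms[keep] - anchor[idx[keep]]
  i <- idx[keep]
  # bins are contiguous when edges are an arithmetic grid; use floor lookup
  b <- floor((rel - bin_edges[1]) / bin_ms) + 1
  ok <- b >= 1 & b <= nb & (rel - bin_edges[1]) >= 0
  if (any(ok)) occ[cbind(i[ok], b[ok])] <- TRUE
  occ
}
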