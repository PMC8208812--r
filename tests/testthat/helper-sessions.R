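# Hand-built fixtures: deterministic MGS trial tables and spike tables with
# known content, used wherever a test needs exact expected values.

make_trials <- function(n_per_cell = 2, stim_epoch = "delay",
                        saccade_rt = 200) {
  cond <- rep(c("In", "In", "Out", "Out"), each = n_per_cell)
  stim <- rep(c(TRUE, FALSE, TRUE, FALSE), each = n_per_cell)
  nt <- length(cond)
  anchor <- c(fixation = 0, visual = 1000, delay = 2000, saccade = 3000)
  offset <- c(fixation = 500, visual = 500, delay = 500, saccade = 150)
  data.frame(
    trial_id = seq_len(nt), condition = cond, stimulated = stim,
    stim_epoch = ifelse(stim, stim_epoch, "none"),
    fix_on = 0, cue_on = 1000, cue_off = 2000, go_cue = 3000,
    saccade_onset = 3000 + saccade_rt,
    stim_time = ifelse(stim, anchor[[stim_epoch]] + offset[[stim_epoch]],
                       NA_real_))
}

make_spikes <- function(unit_id, trial_times) {
  rows <- lapply(seq_along(trial_times), function(i) {
    tt <- trial_times[[i]]
    if (!length(tt)) return(NULL)
    data.frame(unit_id = unit_id, trial_id = as.numeric(names(trial_times)[i]),
               time_ms = sort(tt))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(unit_id = character(0), trial_id = numeric(0),
                      time_ms = numeric(0))
  out
}

# session with one unit spiking at fixed offsets after the (virtual) stim
# time on the given trials
make_evoked_session <- function(n_per_cell = 2, stim_epoch = "delay",
                                evoked_offsets = list()) {
  tr <- make_trials(n_per_cell, stim_epoch)
  vt <- ifelse(tr$stimulated, tr$stim_time,
               wmgating::virtual_stim_time(tr, stim_epoch))
  times <- lapply(seq_len(nrow(tr)), function(i) {
    off <- evoked_offsets[[as.character(i)]]
    if (is.null(off)) numeric(0) else vt[i] + off
  })
  names(times) <- tr$trial_id
  wm_session(tr, make_spikes("u1", times))
}

quiet_unit <- function(...) {
  unit_config(..., baseline_rate = 0,
              epoch_gains = list(fixation = c(In = 1, Out = 1),
                                 visual = c(In = 1, Out = 1),
                                 delay = c(In = 1, Out = 1),
                                 presaccadic = c(In = 1, Out = 1)))
}

flat_gains <- function(g = 1) {
  list(fixation = c(In = g, Out = g), visual = c(In = g, Out = g),
       delay = c(In = g, Out = g), presaccadic = c(In = g, Out = g))
}
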