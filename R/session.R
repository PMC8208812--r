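#' Assemble a recording session
#'
#' A session bundles the trial table of a memory-guided saccade (MGS)
#' experiment with the spike-event table of the simultaneously recorded
#' units and the list of unit pairs to analyse for joint spiking.
#'
#' All times are in milliseconds from trial start. The trial table must
#' contain one row per trial with the task events `fix_on`, `cue_on`,
#' `cue_off`, `go_cue` and `saccade_onset`, the cue `condition`
#' (`"In"`/`"Out"` of the response field), the `stimulated` flag, the
#' `stim_epoch` (`"fixation"`, `"visual"`, `"delay"`, `"saccade"`, or
#' `"none"`) and `stim_time` (NA on non-stimulated trials).
#'
#' @param trials data.frame with columns `trial_id`, `condition`,
#'   `stimulated`, `stim_epoch`, `fix_on`, `cue_on`, `cue_off`, `go_cue`,
#'   `saccade_onset`, `stim_time`.
#' @param spikes data.frame with columns `unit_id`, `trial_id`, `time_ms`.
#' @param pairs data.frame with columns `unit_a`, `unit_b`, or NULL for no
#'   pairs.
#' @param time_resolution_ms positive sampling resolution of the spike times.
#' @return An object of class `wm_session`.
#' @seealso [validate_session()], [simulate_session()], [read_session()]
#' @export
wm_session <- function(trials, spikes, pairs = NULL, time_resolution_ms = 1) {
  trials <- as.data.frame(trials)
  spikes <- as.data.frame(spikes)
  req_tr <- c("trial_id", "condition", "stimulated", "stim_epoch",
              "fix_on", "cue_on", "cue_off", "go_cue", "saccade_onset",
              "stim_time")
  miss <- setdiff(req_tr, names(trials))
  if (length(miss))
    stop("trials table is missing column(s): ", paste(miss, collapse = ", "))
  req_sp <- c("unit_id", "trial_id", "time_ms")
  miss <- setdiff(req_sp, names(spikes))
  if (length(miss))
    stop("spikes table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(pairs)) {
    pairs <- data.frame(unit_a = character(0), unit_b = character(0))
  }
  pairs <- as.data.frame(pairs)
  if (!all(c("unit_a", "unit_b") %in% names(pairs)))
    stop("pairs table is missing column(s): unit_a, unit_b")
  trials$condition <- as.character(trials$condition)
  trials$stim_epoch <- as.character(trials$stim_epoch)
  spikes$unit_id <- as.character(spikes$unit_id)
  pairs$unit_a <- as.character(pairs$unit_a)
  pairs$unit_b <- as.character(pairs$unit_b)
  spikes <- spikes[order(spikes$unit_id, spikes$trial_id, spikes$time_ms), ,
                   drop = FALSE]
  rownames(spikes) <- NULL
  structure(
    list(trials = trials, spikes = spikes, pairs = pairs,
         time_resolution_ms = time_resolution_ms),
    class = "wm_session")
}

#' @export
print.wm_session <- function(x, ...) {
  n_units <- length(unique(x$spikes$unit_id))
  cat("<wm_session>\n")
  cat(sprintf("  %d trials (%d stimulated), %d units, %d pairs\n",
              nrow(x$trials), sum(x$trials$stimulated), n_units,
              nrow(x$pairs)))
  tab <- table(x$trials$condition, ifelse(x$trials$stimulated, "stim", "no-stim"))
  print(tab)
  invisible(x)
}

#' List the units of a session
#' @param session a `wm_session`.
#' @return character vector of unit ids.
#' @export
session_units <- function(session) {
  sort(unique(session$spikes$unit_id))
}

#' Validate the invariants of a session
#'
#' Checks the task-event ordering of every trial, the consistency of the
#' stimulation metadata (`stim_time` present iff `stimulated`, `stim_epoch`
#' of non-stimulated trials equal to `"none"`, `stim_time` matching the
#' epoch's nominal offset within `stim_tol_ms`), the spike table (times
#' non-negative, strictly increasing within unit x trial, trial ids known),
#' the pair table (distinct members, known units), and the presence of at
#' least one stimulated and one non-stimulated trial per condition.
#'
#' Nominal stimulation offsets are 500 ms after fixation onset, cue onset or
#' cue offset (fixation/visual/delay epochs) and 150 ms after the go cue
#' (saccade epoch).
#'
#' Violations are reported, not raised.
#'
#' @param session a `wm_session`.
#' @param stim_tol_ms tolerance for the stimulation-time check (default 1 ms,
#'   allowing hardware jitter).
#' @return list with elements `ok` (logical) and `issues` (data.frame with
#'   columns `scope`, `id`, `issue`).
#' @export
validate_session <- function(session, stim_tol_ms = 1) {
  stopifnot(inherits(session, "wm_session"))
  issues <- list()
  add <- function(scope, id, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      scope = scope, id = as.character(id), issue = issue)
  }
  tr <- session$trials
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    ev <- c(t$fix_on, t$cue_on, t$cue_off, t$go_cue, t$saccade_onset)
    if (anyNA(ev) || any(diff(ev) <= 0))
      add("trial", t$trial_id,
          "event times not strictly ordered (fix_on < cue_on < cue_off < go_cue < saccade_onset)")
    if (!t$condition %in% .conditions)
      add("trial", t$trial_id, sprintf("condition '%s' not in {In, Out}", t$condition))
    if (isTRUE(t$stimulated)) {
      if (is.na(t$stim_time))
        add("trial", t$trial_id, "stimulated trial without stim_time")
      if (!t$stim_epoch %in% names(.epoch_stim_offsets)) {
        add("trial", t$trial_id,
            sprintf("stimulated trial with stim_epoch '%s'", t$stim_epoch))
      } else if (!is.na(t$stim_time)) {
        anchor <- t[[.epoch_stim_anchor[[t$stim_epoch]]]]
        nominal <- anchor + .epoch_stim_offsets[[t$stim_epoch]]
        if (abs(t$stim_time - nominal) > stim_tol_ms + 1e-9)
          add("trial", t$trial_id,
              sprintf("stim_time %.3f differs from nominal %s offset %.3f",
                      t$stim_time, t$stim_epoch, nominal))
      }
    } else {
      if (!is.na(t$stim_time))
        add("trial", t$trial_id, "non-stimulated trial with stim_time")
      if (!identical(t$stim_epoch, "none"))
        add("trial", t$trial_id, "non-stimulated trial with stim_epoch != 'none'")
    }
  }
  sp <- session$spikes
  if (nrow(sp)) {
    unknown <- !sp$trial_id %in% tr$trial_id
    for (id in unique(sp$trial_id[unknown]))
      add("spikes", id, "spike references unknown trial_id")
    if (any(sp$time_ms < 0, na.rm = TRUE))
      for (u in unique(sp$unit_id[sp$time_ms < 0]))
        add("unit", u, "negative spike time")
    key <- paste(sp$unit_id, sp$trial_id)
    ord <- unlist(tapply(sp$time_ms, factor(key, levels = unique(key)),
                         function(v) any(diff(v) <= 0)), use.names = TRUE)
    for (k in names(ord)[which(ord)])
      add("unit", k, "spike times not strictly increasing within trial")
  }
  pr <- session$pairs
  units <- unique(sp$unit_id)
  for (i in seq_len(nrow(pr))) {
    if (pr$unit_a[i] == pr$unit_b[i])
      add("pair", paste(pr$unit_a[i], pr$unit_b[i], sep = "-"),
          "pair members are not distinct")
    for (u in c(pr$unit_a[i], pr$unit_b[i]))
      if (!u %in% units)
        add("pair", u, "pair references unknown unit")
  }
  for (cnd in intersect(.conditions, tr$condition)) {
    sub <- tr[tr$condition == cnd, ]
    if (!any(sub$stimulated))
      add("session", cnd, "condition has no stimulated trials")
    if (!any(!sub$stimulated))
      add("session", cnd, "condition has no non-stimulated trials")
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(scope = character(0), id = character(0), issue = character(0))
  list(ok = nrow(issues) == 0L, issues = issues)
}

#' Re-express spike times relative to a task event
#'
#' @param session a `wm_session`.
#' @param anchor one of `"fix_on"`, `"cue_on"`, `"cue_off"`, `"go_cue"`,
#'   `"saccade_onset"`, or `"stim_time"`. With `anchor = "stim_time"` only
#'   stimulated trials can be aligned; non-stimulated trials are dropped and
#'   listed in the `errors` attribute of the result.
#' @param unit_id optional unit filter.
#' @param trial_ids optional trial filter.
#' @return data.frame `unit_id`, `trial_id`, `time` (ms relative to the
#'   anchor), ordered as the input; attribute `errors` holds a data.frame of
#'   trials that could not be aligned.
#' @export
align_spikes <- function(session, anchor, unit_id = NULL, trial_ids = NULL) {
  stopifnot(inherits(session, "wm_session"))
  valid <- c("fix_on", "cue_on", "cue_off", "go_cue", "saccade_onset", "stim_time")
  if (!anchor %in% valid)
    stop("anchor must be one of: ", paste(valid, collapse = ", "))
  tr <- session$trials
  sp <- session$spikes
  if (!is.null(unit_id)) sp <- sp[sp$unit_id %in% unit_id, , drop = FALSE]
  if (!is.null(trial_ids)) {
    tr <- tr[tr$trial_id %in% trial_ids, , drop = FALSE]
    sp <- sp[sp$trial_id %in% trial_ids, , drop = FALSE]
  }
  errors <- data.frame(trial_id = numeric(0), issue = character(0))
  if (anchor == "stim_time") {
    bad <- tr$trial_id[!tr$stimulated]
    if (length(bad))
      errors <- data.frame(trial_id = bad,
                           issue = "stim_time alignment requested on non-stimulated trial")
    tr <- tr[tr$stimulated, , drop = FALSE]
    sp <- sp[sp$trial_id %in% tr$trial_id, , drop = FALSE]
  }
  anchor_times <- tr[[anchor]][match(sp$trial_id, tr$trial_id)]
  out <- data.frame(unit_id = sp$unit_id, trial_id = sp$trial_id,
                    time = sp$time_ms - anchor_times)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}
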