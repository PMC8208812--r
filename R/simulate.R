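#' Configure a simulated unit
#'
#' Defines the generative parameters of one unit: a piecewise-constant
#' background rate (baseline times per-epoch, per-condition gain), the
#' per-pulse probability and latency distribution of stimulation-evoked
#' spikes, the activation type, and the refractory period.
#'
#' Default latency parameters follow the two empirically observed activation
#' groups: fast input near 6.5 ms (SD 0.67 ms, consistent with monosynaptic
#' transmission) and slow input near 12.7 ms (SD 1.40 ms). Evoked spikes are
#' slightly more probable and slightly earlier when the remembered location
#' falls in the response field (`In` condition).
#'
#' @param unit_id unit identifier.
#' @param activation_type one of `"visual_recipient"`, `"slow_input"`,
#'   `"non_activated"`, `"antidromic"`.
#' @param baseline_rate background firing rate in Hz.
#' @param epoch_gains named list (`fixation`, `visual`, `delay`,
#'   `presaccadic`) of length-2 vectors `c(In =, Out =)` of multiplicative
#'   rate gains.
#' @param evoked_prob per-pulse evoked-spike probability, `c(In =, Out =)`.
#' @param evoked_latency_mean,evoked_latency_sd latency distribution (ms),
#'   `c(In =, Out =)`; defaults depend on `activation_type`.
#' @param refractory_ms absolute refractory period (>= 1 ms).
#' @param collision_window_ms collision window for antidromic units: an
#'   evoked spike is annihilated when a spontaneous spike occurred within
#'   this many ms before the pulse.
#' @return list of class `wm_unit_config`.
#' @export
unit_config <- function(unit_id,
                        activation_type = "visual_recipient",
                        baseline_rate = 10,
                        epoch_gains = list(
                          fixation = c(In = 1, Out = 1),
                          visual = c(In = 3, Out = 1.2),
                          delay = c(In = 1.5, Out = 0.9),
                          presaccadic = c(In = 2.5, Out = 1.2)),
                        evoked_prob = c(In = 0.22, Out = 0.18),
                        evoked_latency_mean = NULL,
                        evoked_latency_sd = NULL,
                        refractory_ms = 1,
                        collision_window_ms = 4) {
  types <- c("visual_recipient", "slow_input", "non_activated", "antidromic")
  activation_type <- match.arg(activation_type, types)
  if (is.null(evoked_latency_mean)) {
    evoked_latency_mean <- switch(activation_type,
      slow_input = c(In = 12.65, Out = 12.81),
      c(In = 6.45, Out = 6.61))
  }
  if (is.null(evoked_latency_sd)) {
    evoked_latency_sd <- switch(activation_type,
      slow_input = c(In = 1.40, Out = 1.40),
      c(In = 0.67, Out = 0.67))
  }
  evoked_prob <- .cond_vec(evoked_prob)
  evoked_latency_mean <- .cond_vec(evoked_latency_mean)
  evoked_latency_sd <- .cond_vec(evoked_latency_sd)
  if (activation_type == "non_activated") evoked_prob[] <- 0
  stopifnot(baseline_rate >= 0,
            all(evoked_prob >= 0 & evoked_prob <= 1),
            refractory_ms >= 1, collision_window_ms > 0)
  if (activation_type == "visual_recipient" && any(evoked_latency_mean >= 10))
    stop("visual_recipient latency means must be < 10 ms")
  if (activation_type == "slow_input" && any(evoked_latency_mean < 10))
    stop("slow_input latency means must be >= 10 ms")
  structure(list(unit_id = as.character(unit_id),
                 activation_type = activation_type,
                 baseline_rate = baseline_rate,
                 epoch_gains = lapply(epoch_gains, .cond_vec),
                 evoked_prob = evoked_prob,
                 evoked_latency_mean = evoked_latency_mean,
                 evoked_latency_sd = evoked_latency_sd,
                 refractory_ms = refractory_ms,
                 collision_window_ms = collision_window_ms),
            class = "wm_unit_config")
}

.cond_vec <- function(x) {
  if (length(x) == 1) x <- c(In = unname(x), Out = unname(x))
  if (is.null(names(x))) names(x) <- c("In", "Out")
  x[c("In", "Out")]
}

#' Configure evoked-spike coupling of a unit pair
#'
#' `kappa` is the per-pulse probability that a stimulation pulse evokes a
#' coincident spike (one shared latency draw) in both units; it may not
#' exceed either unit's evoked probability. It is a generative convenience
#' standing in for the unknown true coupling of simultaneously recorded
#' neurons.
#'
#' @param unit_a,unit_b unit identifiers.
#' @param kappa `c(In =, Out =)` joint evoked-spike probability.
#' @return list of class `wm_pair_coupling`.
#' @export
pair_coupling <- function(unit_a, unit_b, kappa = c(In = 0.103, Out = 0.065)) {
  kappa <- .cond_vec(kappa)
  stopifnot(all(kappa >= 0 & kappa <= 1))
  structure(list(unit_a = as.character(unit_a), unit_b = as.character(unit_b),
                 kappa = kappa),
            class = "wm_pair_coupling")
}

#' Configure a simulated session
#'
#' Task timing defaults to the memory-guided saccade schedule: 1 s fixation,
#' 1 s cue presentation, 1 s delay; the saccade follows the go cue after a
#' reaction time drawn from N(200, 20) ms. Half of the configuration's
#' trials are stimulated (a single pulse per trial at the epoch's nominal
#' offset); `n_trials` gives the number of trials per condition x
#' stimulation cell.
#'
#' @param units list of [unit_config()] objects.
#' @param couplings list of [pair_coupling()] objects (each unit may appear
#'   in at most one coupling).
#' @param n_trials trials per (condition, stimulated) cell; scalar or named
#'   vector `c(In_stim =, In_nonstim =, Out_stim =, Out_nonstim =)`.
#' @param fix_ms,cue_ms,delay_ms task interval durations (ms).
#' @param stim_epochs character vector of epochs receiving stimulation;
#'   stimulated trials are allocated to epochs by `stim_epoch_weights`.
#' @param stim_epoch_weights allocation weights (default uniform).
#' @param saccade_rt_mean,saccade_rt_sd reaction-time distribution (ms).
#' @param artifact_end artifact blank length (ms); evoked latencies are
#'   truncated to `[artifact_end, 20]` ms.
#' @param extra_pairs optional data.frame (`unit_a`, `unit_b`) of additional,
#'   uncoupled pairs to list in the session.
#' @param seed master seed; every random stream of the simulation derives
#'   from it.
#' @return list of class `wm_simulation_config`.
#' @export
simulation_config <- function(units, couplings = list(), n_trials = 60,
                              fix_ms = 1000, cue_ms = 1000, delay_ms = 1000,
                              stim_epochs = "delay",
                              stim_epoch_weights = NULL,
                              saccade_rt_mean = 200, saccade_rt_sd = 20,
                              artifact_end = 3, extra_pairs = NULL,
                              seed = 1) {
  if (inherits(units, "wm_unit_config")) units <- list(units)
  if (inherits(couplings, "wm_pair_coupling")) couplings <- list(couplings)
  if (length(n_trials) == 1) {
    n_trials <- c(In_stim = n_trials, In_nonstim = n_trials,
                  Out_stim = n_trials, Out_nonstim = n_trials)
  }
  cells <- c("In_stim", "In_nonstim", "Out_stim", "Out_nonstim")
  stopifnot(all(cells %in% names(n_trials)), all(n_trials[cells] >= 1))
  stopifnot(all(stim_epochs %in% names(.epoch_stim_offsets)))
  if (is.null(stim_epoch_weights))
    stim_epoch_weights <- rep(1, length(stim_epochs))
  ids <- vapply(units, function(u) u$unit_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate unit ids")
  coupled <- unlist(lapply(couplings, function(cp) c(cp$unit_a, cp$unit_b)))
  if (anyDuplicated(coupled))
    stop("a unit may appear in at most one coupling")
  for (cp in couplings) {
    for (u in c(cp$unit_a, cp$unit_b))
      if (!u %in% ids) stop("coupling references unknown unit: ", u)
    pa <- units[[match(cp$unit_a, ids)]]$evoked_prob
    pb <- units[[match(cp$unit_b, ids)]]$evoked_prob
    if (any(cp$kappa > pmin(pa, pb) + 1e-12))
      stop("kappa exceeds a member unit's evoked probability for pair ",
           cp$unit_a, "-", cp$unit_b)
  }
  structure(list(units = units, couplings = couplings,
                 n_trials = n_trials[cells],
                 fix_ms = fix_ms, cue_ms = cue_ms, delay_ms = delay_ms,
                 stim_epochs = stim_epochs,
                 stim_epoch_weights = stim_epoch_weights,
                 saccade_rt_mean = saccade_rt_mean,
                 saccade_rt_sd = saccade_rt_sd,
                 artifact_end = artifact_end,
                 extra_pairs = extra_pairs, seed = seed),
            class = "wm_simulation_config")
}

.substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * (k + 1)) %% 2147483647)
}

# truncated-normal draws via inverse CDF (exact, vectorised)
.rtnorm <- function(n, mean, sd, lo, hi) {
  a <- pnorm(lo, mean, sd); b <- pnorm(hi, mean, sd)
  qnorm(runif(n, a, b), mean, sd)
}

# Background spikes for one unit on a set of trials: exact sampling of the
# per-1-ms-bin Bernoulli process with piecewise-constant rate (bin occupancy
# ~ Binomial(n_bins, rate * dt), occupied bins uniform without replacement,
# sub-ms placement uniform within the bin).
.background_spikes <- function(ucfg, trials, trial_end) {
  out_t <- rep(list(numeric(0)), nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    g <- ucfg$epoch_gains
    cnd <- tr$condition
    segs <- rbind(
      c(tr$fix_on, tr$cue_on, g$fixation[[cnd]]),
      c(tr$cue_on, tr$cue_off, g$visual[[cnd]]),
      c(tr$cue_off, tr$go_cue, g$delay[[cnd]]),
      c(tr$go_cue, trial_end[i], g$presaccadic[[cnd]]))
    times <- NULL
    for (s in seq_len(nrow(segs))) {
      nb <- floor(segs[s, 2] - segs[s, 1])
      if (nb <= 0) next
      p <- min(1, ucfg$baseline_rate * segs[s, 3] / 1000)
      if (p <= 0) next
      k <- rbinom(1, nb, p)
      if (k > 0) {
        bins <- sample.int(nb, k)
        times <- c(times, segs[s, 1] + (bins - 1) + runif(k))
      }
    }
    if (length(times)) out_t[[i]] <- sort(times)
  }
  out_t
}

#' Simulate a session
#'
#' Generates a [wm_session()] from a [simulation_config()]. Background
#' spikes are an exact per-1-ms-bin Bernoulli process with
#' piecewise-constant, condition- and epoch-dependent rate, thinned to
#' enforce the refractory period. On stimulated trials an evoked spike is
#' inserted with the unit's per-condition probability at `stim_time +
#' latency`, the latency drawn from a Normal truncated to
#' `[artifact_end, 20]` ms; coupled pairs share a single latency draw with
#' probability `kappa` (marginal evoked probabilities are preserved).
#' Antidromic units obey the collision rule: the evoked spike is suppressed
#' whenever a background spike occurred within the collision window before
#' the pulse. Evoked spikes win refractory conflicts with background spikes.
#'
#' Each unit consumes its own random substream derived from the master
#' seed, so adding a unit never perturbs the others; identical
#' configurations and seeds give identical sessions.
#'
#' @param config a [simulation_config()].
#' @return a [wm_session()] whose `pairs` table lists the coupled pairs
#'   (plus any `extra_pairs`).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "wm_simulation_config"))
  trials <- .simulate_trials(config)
  trial_end <- trials$saccade_onset + 200
  ids <- vapply(config$units, function(u) u$unit_id, character(1))

  # per-unit spikes
  spk <- vector("list", length(config$units))
  for (k in seq_along(config$units)) {
    spk[[k]] <- .simulate_unit_spikes(config$units[[k]], trials, trial_end,
                                      config$artifact_end,
                                      .substream_seed(config$seed, k))
  }
  names(spk) <- ids

  # couplings override the evoked component of both member units
  for (j in seq_along(config$couplings)) {
    cp <- config$couplings[[j]]
    ka <- match(cp$unit_a, ids); kb <- match(cp$unit_b, ids)
    spk_ab <- .apply_coupling(cp, config$units[[ka]], config$units[[kb]],
                              spk[[ka]], spk[[kb]], trials,
                              config$artifact_end,
                              .substream_seed(config$seed, 100000 + j))
    spk[[ka]] <- spk_ab[[1]]; spk[[kb]] <- spk_ab[[2]]
  }

  # refractory thinning, evoked spikes win conflicts
  rows <- vector("list", length(spk))
  for (k in seq_along(spk)) {
    u <- config$units[[k]]
    per_trial <- spk[[k]]
    lst <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tt <- per_trial$times[[i]]
      if (!length(tt)) next
      ord <- order(tt)
      kept <- .thin_refractory_cpp(tt[ord], per_trial$evoked[[i]][ord],
                                   u$refractory_ms)
      if (length(kept))
        lst[[i]] <- data.frame(unit_id = u$unit_id,
                               trial_id = trials$trial_id[i], time_ms = kept)
    }
    rows[[k]] <- do.call(rbind, lst[!vapply(lst, is.null, logical(1))])
  }
  spikes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), trial_id = numeric(0),
                         time_ms = numeric(0))
  pairs <- NULL
  if (length(config$couplings))
    pairs <- do.call(rbind, lapply(config$couplings, function(cp)
      data.frame(unit_a = cp$unit_a, unit_b = cp$unit_b)))
  if (!is.null(config$extra_pairs))
    pairs <- rbind(pairs, config$extra_pairs[, c("unit_a", "unit_b")])
  wm_session(trials, spikes, pairs)
}

.simulate_trials <- function(config) {
  n <- config$n_trials
  cond <- rep(c("In", "In", "Out", "Out"), times = n)
  stim <- rep(c(TRUE, FALSE, TRUE, FALSE), times = n)
  nt <- length(cond)
  set.seed(.substream_seed(config$seed, 0))
  rt <- pmax(120, rnorm(nt, config$saccade_rt_mean, config$saccade_rt_sd))
  epochs <- rep(NA_character_, nt)
  nstim <- sum(stim)
  if (length(config$stim_epochs) == 1) {
    epochs[stim] <- config$stim_epochs
  } else {
    epochs[stim] <- sample(config$stim_epochs, nstim, replace = TRUE,
                           prob = config$stim_epoch_weights)
  }
  fix_on <- rep(0, nt)
  cue_on <- fix_on + config$fix_ms
  cue_off <- cue_on + config$cue_ms
  go_cue <- cue_off + config$delay_ms
  saccade_onset <- go_cue + rt
  trials <- data.frame(
    trial_id = seq_len(nt), condition = cond, stimulated = stim,
    stim_epoch = ifelse(stim, epochs, "none"),
    fix_on = fix_on, cue_on = cue_on, cue_off = cue_off, go_cue = go_cue,
    saccade_onset = saccade_onset, stim_time = NA_real_)
  for (e in unique(epochs[stim])) {
    sel <- stim & epochs == e
    trials$stim_time[sel] <- virtual_stim_time(trials[sel, , drop = FALSE], e)
  }
  trials
}

# Returns list(times = list per trial, evoked = list per trial of logicals).
.simulate_unit_spikes <- function(ucfg, trials, trial_end, artifact_end, seed) {
  set.seed(seed)
  bg <- .background_spikes(ucfg, trials, trial_end)
  nt <- nrow(trials)
  # evoked component: decision + latency per stimulated trial (always drawn,
  # whether used or not, to keep streams aligned across activation types)
  u_fire <- runif(nt)
  lat <- numeric(nt)
  for (cnd in .conditions) {
    sel <- trials$condition == cnd
    lat[sel] <- .rtnorm(sum(sel), ucfg$evoked_latency_mean[[cnd]],
                        ucfg$evoked_latency_sd[[cnd]], artifact_end, 20)
  }
  times <- vector("list", nt); evoked <- vector("list", nt)
  p <- ucfg$evoked_prob
  for (i in seq_len(nt)) {
    tt <- bg[[i]]; ev <- rep(FALSE, length(tt))
    tr <- trials[i, ]
    if (isTRUE(tr$stimulated) && u_fire[i] < p[[tr$condition]]) {
      suppress <- FALSE
      if (ucfg$activation_type == "antidromic") {
        suppress <- any(tt >= tr$stim_time - ucfg$collision_window_ms &
                        tt < tr$stim_time)
      }
      if (!suppress) {
        tt <- c(tt, tr$stim_time + lat[i])
        ev <- c(ev, TRUE)
      }
    }
    times[[i]] <- tt; evoked[[i]] <- ev
  }
  list(times = times, evoked = evoked, u_fire = u_fire, lat = lat)
}

# Rebuild both members' evoked spikes under coupling: with probability kappa
# the pulse evokes a coincident spike in both units (one shared latency);
# otherwise each unit fires independently with the residual probability
# (p - kappa)/(1 - kappa), preserving marginals. Shared latencies are drawn
# from the average of the two units' latency parameters.
.apply_coupling <- function(cp, ua, ub, sa, sb, trials, artifact_end, seed) {
  set.seed(seed)
  nt <- nrow(trials)
  u_joint <- runif(nt)
  mean_ab <- (ua$evoked_latency_mean + ub$evoked_latency_mean) / 2
  sd_ab <- (ua$evoked_latency_sd + ub$evoked_latency_sd) / 2
  lat_j <- numeric(nt)
  for (cnd in .conditions) {
    sel <- trials$condition == cnd
    lat_j[sel] <- .rtnorm(sum(sel), mean_ab[[cnd]], sd_ab[[cnd]],
                          artifact_end, 20)
  }
  rebuild <- function(s, ucfg, joint) {
    for (i in seq_len(nt)) {
      tr <- trials[i, ]
      if (!isTRUE(tr$stimulated)) next
      cnd <- tr$condition
      kap <- cp$kappa[[cnd]]
      pu <- ucfg$evoked_prob[[cnd]]
      # strip this unit's previous evoked spike
      keep <- !s$evoked[[i]]
      tt <- s$times[[i]][keep]; ev <- rep(FALSE, sum(keep))
      fire <- FALSE; latency <- NA_real_
      if (joint[i]) {
        fire <- TRUE; latency <- lat_j[i]
      } else if (kap < 1 && s$u_fire[i] < (pu - kap) / (1 - kap)) {
        fire <- TRUE; latency <- s$lat[i]
      }
      if (fire && ucfg$activation_type == "antidromic") {
        if (any(tt >= tr$stim_time - ucfg$collision_window_ms &
                tt < tr$stim_time)) fire <- FALSE
      }
      if (fire) { tt <- c(tt, tr$stim_time + latency); ev <- c(ev, TRUE) }
      s$times[[i]] <- tt; s$evoked[[i]] <- ev
    }
    s
  }
  joint <- logical(nt)
  for (cnd in .conditions) {
    sel <- trials$condition == cnd & trials$stimulated
    joint[sel] <- u_joint[sel] < cp$kappa[[cnd]]
  }
  list(rebuild(sa, ua, joint), rebuild(sb, ub, joint))
}

#' Simulate a single antidromically activated unit
#'
#' Convenience wrapper exposing the collision rule in isolation: spikes of
#' one antidromic unit are generated against a given trial table. The evoked
#' spike is suppressed whenever a background spike occurred within the
#' collision window `[stim_time - collision_window_ms, stim_time)`;
#' otherwise it is evoked exactly as for orthodromic units.
#'
#' @param ucfg a [unit_config()] with `activation_type = "antidromic"`.
#' @param trials a trial table (e.g. from a simulated session).
#' @param seed integer seed.
#' @param artifact_end artifact blank (ms).
#' @return data.frame `unit_id`, `trial_id`, `time_ms`.
#' @export
simulate_antidromic_unit <- function(ucfg, trials, seed, artifact_end = 3) {
  stopifnot(inherits(ucfg, "wm_unit_config"))
  if (ucfg$activation_type != "antidromic")
    stop("unit's activation_type must be 'antidromic'")
  trial_end <- trials$saccade_onset + 200
  s <- .simulate_unit_spikes(ucfg, trials, trial_end, artifact_end, seed)
  lst <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tt <- s$times[[i]]
    if (!length(tt)) next
    ord <- order(tt)
    kept <- .thin_refractory_cpp(tt[ord], s$evoked[[i]][ord], ucfg$refractory_ms)
    if (length(kept))
      lst[[i]] <- data.frame(unit_id = ucfg$unit_id,
                             trial_id = trials$trial_id[i], time_ms = kept)
  }
  out <- do.call(rbind, lst[!vapply(lst, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(unit_id = character(0), trial_id = numeric(0),
                      time_ms = numeric(0))
  rownames(out) <- NULL
  out
}
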