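#' Read a session from CSV tables
#'
#' Reads the canonical plain-text interchange format: `trials.csv` (one row
#' per trial), `spikes.csv` (one row per spike: `unit_id`, `trial_id`,
#' `time_ms`) and an optional `pairs.csv` (`unit_a`, `unit_b`). Times are in
#' ms; a header row is required. Missing required columns raise a fatal
#' error naming the column; non-numeric times are reported with their line
#' numbers.
#'
#' @param trials_path,spikes_path,pairs_path file paths (`pairs_path` may be
#'   NULL).
#' @param validate run [validate_session()] and stop on structural
#'   violations.
#' @return a [wm_session()].
#' @export
read_session <- function(trials_path, spikes_path, pairs_path = NULL,
                         validate = TRUE) {
  for (p in c(trials_path, spikes_path, pairs_path))
    if (!file.exists(p)) stop("file not found: ", p)
  trials <- read.csv(trials_path, stringsAsFactors = FALSE)
  req_tr <- c("trial_id", "condition", "stimulated", "stim_epoch", "fix_on",
              "cue_on", "cue_off", "go_cue", "saccade_onset", "stim_time")
  miss <- setdiff(req_tr, names(trials))
  if (length(miss))
    stop(trials_path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  spikes <- read.csv(spikes_path, stringsAsFactors = FALSE)
  req_sp <- c("unit_id", "trial_id", "time_ms")
  miss <- setdiff(req_sp, names(spikes))
  if (length(miss))
    stop(spikes_path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(spikes$time_ms)) {
    bad <- which(is.na(suppressWarnings(as.numeric(spikes$time_ms))))
    stop(spikes_path, ": non-numeric time_ms on data line(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  for (col in c("fix_on", "cue_on", "cue_off", "go_cue", "saccade_onset",
                "stim_time")) {
    if (!is.numeric(trials[[col]]) && !all(is.na(trials[[col]]))) {
      v <- suppressWarnings(as.numeric(trials[[col]]))
      bad <- which(is.na(v) & !(trials[[col]] %in% c("", "NA")))
      if (length(bad))
        stop(trials_path, ": non-numeric ", col, " on data line(s) ",
             paste(utils::head(bad, 10), collapse = ", "))
      trials[[col]] <- v
    }
    if (all(is.na(trials[[col]]))) trials[[col]] <- as.numeric(trials[[col]])
  }
  trials$stimulated <- as.logical(trials$stimulated)
  pairs <- NULL
  if (!is.null(pairs_path)) {
    pairs <- read.csv(pairs_path, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (!all(c("unit_a", "unit_b") %in% names(pairs)))
      stop(pairs_path, " is missing required column(s): unit_a, unit_b")
  }
  unknown <- setdiff(unique(spikes$trial_id), trials$trial_id)
  if (length(unknown))
    stop(spikes_path, " references unknown trial_id(s): ",
         paste(utils::head(unknown, 10), collapse = ", "))
  s <- wm_session(trials, spikes, pairs)
  if (validate) {
    v <- validate_session(s)
    if (!v$ok)
      stop("session fails validation; first issue: ",
           v$issues$scope[1], " ", v$issues$id[1], ": ", v$issues$issue[1])
  }
  s
}

#' Write a session to CSV tables
#'
#' Inverse of [read_session()]: writes `trials.csv`, `spikes.csv` and
#' `pairs.csv` into `dir`.
#'
#' @param session a [wm_session()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "wm_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "spikes.csv", "pairs.csv"))
  write.csv(session$trials, paths[1], row.names = FALSE)
  write.csv(session$spikes, paths[2], row.names = FALSE)
  write.csv(session$pairs, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write result tables with a reproducibility manifest
#'
#' Writes one CSV per named table plus `manifest.json` recording file
#' names, row counts, the seed, and an MD5 hash of the serialized
#' configuration.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param seed seed used to produce the tables (recorded in the manifest).
#' @param config configuration object to hash into the manifest.
#' @param partial named logical vector flagging tables from stages that
#'   failed (recorded in the manifest).
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, seed = NULL, config = NULL,
                          partial = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- list()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], path, row.names = FALSE)
    entries[[nm]] <- list(file = paste0(nm, ".csv"),
                          rows = nrow(tables[[nm]]),
                          partial = isTRUE(partial[[nm]]))
  }
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = seed,
                   config_md5 = .config_md5(config),
                   tables = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

.config_md5 <- function(config) {
  if (is.null(config)) return(NULL)
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(.strip_env(config), file = tf)
  unname(tools::md5sum(tf))
}

.strip_env <- function(x) {
  if (is.list(x)) {
    attrs <- attributes(x)
    x <- lapply(x, .strip_env)
    attributes(x) <- attrs
  }
  x
}
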