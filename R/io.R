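#' Write session recordings as tabular spike-time files
#'
#' The on-disk format is two long tables plus a JSON manifest:
#' `<prefix>_spikes.csv` with columns `subject, session, trial, site,
#' spike_time_s` (one row per spike) and `<prefix>_trials.csv` with
#' columns `subject, session, trial, stimulus_id, context`. The manifest
#' `<prefix>_manifest.json` echoes the recording window and session list.
#' Tab-separated files are produced when `sep = "\t"`.
#'
#' @param sessions a [SessionRecording-class] or list of them.
#' @param prefix output path prefix.
#' @param sep field separator: `","` (default) or `"\t"` (then the
#'   extension becomes `.tsv`).
#' @return invisible character vector of the files written.
#' @export
writeSpikeTable <- function(sessions, prefix, sep = ",") {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  ext <- if (sep == "\t") ".tsv" else ".csv"
  spikeRows <- list(); trialRows <- list()
  for (sess in sessions) {
    meta <- sess@trialMeta
    trialRows[[length(trialRows) + 1L]] <- data.frame(
      subject = sess@subject, session = sess@session, trial = meta$trial,
      stimulus_id = meta$stimulusId, context = meta$context,
      stringsAsFactors = FALSE)
    for (tr in seq_along(sess@trials))
      for (s in seq_along(sess@sites)) {
        t <- sess@trials[[tr]][[s]]
        if (!length(t)) next
        spikeRows[[length(spikeRows) + 1L]] <- data.frame(
          subject = sess@subject, session = sess@session,
          trial = meta$trial[tr], site = sess@sites[s], spike_time_s = t,
          stringsAsFactors = FALSE)
      }
  }
  spikesFile <- paste0(prefix, "_spikes", ext)
  trialsFile <- paste0(prefix, "_trials", ext)
  manifestFile <- paste0(prefix, "_manifest.json")
  utils::write.table(do.call(rbind, spikeRows), spikesFile, sep = sep,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, trialRows), trialsFile, sep = sep,
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(window = sessions[[1]]@window,
         sessions = vapply(sessions, function(s) s@session, character(1)),
         sites = lapply(sessions, function(s) s@sites)),
    manifestFile, auto_unbox = TRUE, digits = NA)
  invisible(c(spikesFile, trialsFile, manifestFile))
}

#' Read session recordings from tabular spike-time files
#'
#' Inverse of [writeSpikeTable()]. Trials listed in the trial table but
#' absent from the spike table are kept as empty trials. Duplicate spike
#' times within one (trial, site) are rejected at parse time.
#'
#' @param spikesFile long spike table (`subject, session, trial, site,
#'   spike_time_s`), comma- or tab-separated by extension.
#' @param trialsFile trial metadata table (`subject, session, trial,
#'   stimulus_id, context`).
#' @param window numeric(2) recording window; taken from the manifest
#'   sitting next to `spikesFile` when `NULL`.
#' @return list of [SessionRecording-class] objects.
#' @export
readSpikeTable <- function(spikesFile, trialsFile, window = NULL) {
  sep <- if (grepl("\\.tsv$", spikesFile)) "\t" else ","
  spikes <- utils::read.table(spikesFile, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  trials <- utils::read.table(trialsFile, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  need <- c("subject", "session", "trial", "site", "spike_time_s")
  if (!all(need %in% names(spikes)))
    stop("spike table needs columns ", paste(need, collapse = ", "))
  if (is.null(window)) {
    manifestFile <- sub("_spikes\\.(csv|tsv)$", "_manifest.json", spikesFile)
    if (file.exists(manifestFile))
      window <- as.numeric(jsonlite::read_json(manifestFile,
                                               simplifyVector = TRUE)$window)
    else
      window <- range(spikes$spike_time_s)
  }
  out <- list()
  for (sessId in unique(trials$session)) {
    tm <- trials[trials$session == sessId, ]
    tm <- tm[order(tm$trial), ]
    sp <- spikes[spikes$session == sessId, ]
    sites <- sort(unique(sp$site))
    if (!length(sites)) sites <- "site01"
    trialList <- lapply(tm$trial, function(tr) {
      lapply(sites, function(st) {
        t <- sort(sp$spike_time_s[sp$trial == tr & sp$site == st])
        if (anyDuplicated(t))
          stop("duplicate spike times in session ", sessId, ", trial ", tr,
               ", site ", st)
        t
      })
    })
    out[[length(out) + 1L]] <- new("SessionRecording",
      subject = tm$subject[1], session = sessId, sites = sites,
      window = window, trials = trialList,
      trialMeta = data.frame(trial = tm$trial, stimulusId = tm$stimulus_id,
                             context = tm$context, stringsAsFactors = FALSE))
  }
  out
}

#' Materialise one trial of a session as a TrialSiteMatrix
#'
#' @param session a [SessionRecording-class].
#' @param trial trial number (matching `trialMeta$trial`).
#' @return a [TrialSiteMatrix-class].
#' @export
trialTrains <- function(session, trial) {
  idx <- match(trial, session@trialMeta$trial)
  if (is.na(idx)) stop("no such trial: ", trial)
  trains <- lapply(session@trials[[idx]], spikeTrain,
                   window = session@window)
  trialSiteMatrix(trains, sites = session@sites)
}

setMethod("show", "SessionRecording", function(object) {
  cat(sprintf("SessionRecording %s (subject %s): %d trials, %d sites, window [%g, %g] s\n",
              object@session, object@subject, length(object@trials),
              length(object@sites), object@window[1], object@window[2]))
})
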