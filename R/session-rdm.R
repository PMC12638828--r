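# Cross-trial pair sampling and session-level RDM construction.

# canonical list of the 120 unordered stimulus pairs, in upper-triangle
# order of the 16 analysed ids
stimulusPairs <- function(ids) {
  n <- length(ids)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) seq(k + 1L, n)))
  # upper.tri order is column-major: regenerate accordingly
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = idx[, "row"], j = idx[, "col"])
}

# Mean multi-site distance per stimulus pair for one session restricted to
# a trial subset. Returns a vector over the 120 pairs (NA where a stimulus
# has no usable trial). All cross-trial pairs are used up to `cap`; beyond
# that a seeded subsample keyed to the session id is drawn. Sampling is
# based on trial ids, not list positions, so the result is invariant to
# trial-order permutations.
sessionPairMeans <- function(session, trialRows, measure, window, ids,
                             cap = 200L, seed = 0L, rateSites = 30L) {
  meta <- session@trialMeta[trialRows, , drop = FALSE]
  ord <- order(meta$trial)
  trialRows <- trialRows[ord]
  meta <- meta[ord, , drop = FALSE]
  byStim <- split(trialRows, factor(meta$stimulusId, levels = ids))
  pairs <- stimulusPairs(ids)
  seedBase <- mixSeed(seed, session@session)
  ti <- integer(0); tj <- integer(0); pid <- integer(0)
  for (p in seq_len(nrow(pairs))) {
    a <- byStim[[pairs$i[p]]]; b <- byStim[[pairs$j[p]]]
    if (!length(a) || !length(b)) next
    eg <- expand.grid(a = a, b = b)
    if (nrow(eg) > cap) {
      keep <- withSeed(mixSeed(seedBase, p), sample.int(nrow(eg), cap))
      eg <- eg[keep, , drop = FALSE]
    }
    ti <- c(ti, eg$a); tj <- c(tj, eg$b)
    pid <- c(pid, rep.int(p, nrow(eg)))
  }
  out <- rep(NA_real_, nrow(pairs))
  if (!length(pid)) return(out)
  if (measure %in% c("ISI", "SPIKE")) {
    used <- sort(unique(c(ti, tj)))
    remap <- match(ti, used); remapJ <- match(tj, used)
    kind <- if (measure == "ISI") 0L else 1L
    out <- .cppPairGroupMeans(session@trials[used], remap, remapJ, pid,
                              nrow(pairs), window[1], window[2], kind)
    out[is.nan(out)] <- NA_real_
    return(out)
  }
  # rate coding on per-site counts within the window, using a fixed seeded
  # site subset when the session has more than `rateSites` sites
  counts <- t(vapply(session@trials, function(tr)
    vapply(tr, countInWindow, numeric(1), window = window),
    numeric(length(session@sites))))
  nS <- ncol(counts)
  if (nS > rateSites) {
    sub <- withSeed(mixSeed(seedBase, "rate-sites"),
                    sort(sample.int(nS, rateSites)))
    counts <- counts[, sub, drop = FALSE]
  }
  ca <- counts[ti, , drop = FALSE]; cb <- counts[tj, , drop = FALSE]
  d <- switch(measure,
    euclidean = sqrt(rowSums((ca - cb)^2)),
    cosine = {
      na <- sqrt(rowSums(ca^2)); nb <- sqrt(rowSums(cb^2))
      ifelse(na == 0 | nb == 0, NA_real_, 1 - rowSums(ca * cb) / (na * nb))
    },
    pearson = {
      sda <- apply(ca, 1L, stats::sd); sdb <- apply(cb, 1L, stats::sd)
      r <- rep(NA_real_, nrow(ca))
      ok <- sda > 0 & sdb > 0
      if (any(ok)) {
        cam <- ca[ok, , drop = FALSE] - rowMeans(ca[ok, , drop = FALSE])
        cbm <- cb[ok, , drop = FALSE] - rowMeans(cb[ok, , drop = FALSE])
        r[ok] <- 1 - rowSums(cam * cbm) /
          sqrt(rowSums(cam^2) * rowSums(cbm^2))
      }
      r
    },
    stop("unknown measure: ", measure))
  means <- tapply(d, factor(pid, levels = seq_len(nrow(pairs))),
                  mean, na.rm = TRUE)
  out <- as.numeric(means)
  out[is.nan(out)] <- NA_real_
  out
}

pairVectorToMatrix <- function(v, ids) {
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

#' Build a session-level RDM
#'
#' Entry (i, j) is the mean multi-site dissimilarity over sampled
#' cross-trial pairs (one trial showing stimulus i, one showing j) within
#' the session and task context. All cross-trial pairs are used up to
#' `cap` pairs per cell; beyond that a subsample seeded by the session id
#' is drawn, making the result reproducible and invariant to trial order.
#' For rate measures a fixed seeded subset of `rateSites` sites is used.
#' A stimulus with no trial yields missing (`NA`) entries, never zeros.
#'
#' @param session a [SessionRecording-class].
#' @param measure one of `"ISI"`, `"SPIKE"`, `"euclidean"`, `"cosine"`,
#'   `"pearson"`.
#' @param window numeric(2) analysis window (s from stimulus onset);
#'   default the 0-0.25 s whole period.
#' @param context restrict to trials of this task context (`NULL`: all).
#' @param stimset the [StimulusSet-class] fixing the 16-stimulus ordering.
#' @param cap maximum cross-trial pairs per cell (default 200).
#' @param seed seed entering the pair-subsampling and site-subset draws
#'   (combined with the session id).
#' @param rateSites number of sites used by rate measures (default 30).
#' @return an [RDM-class].
#' @export
buildSessionRDM <- function(session, measure = validMeasures,
                            window = c(0, 0.25), context = NULL,
                            stimset = makeStimulusSet(), cap = 200L,
                            seed = 0L, rateSites = 30L) {
  measure <- match.arg(measure)
  ids <- analyzedStimuli(stimset)
  rows <- seq_len(nrow(session@trialMeta))
  if (!is.null(context))
    rows <- rows[session@trialMeta$context == context]
  rows <- rows[session@trialMeta$stimulusId[rows] %in% ids]
  v <- sessionPairMeans(session, rows, measure, window, ids, cap = cap,
                        seed = seed, rateSites = rateSites)
  rdm(pairVectorToMatrix(v, ids), ids = ids, measure = measure,
      window = window,
      context = if (is.null(context)) "all" else context,
      source = session@session)
}

#' Build an RDM from pooled trial subsets across sessions
#'
#' Used by the cross-validation machinery: dissimilarities are computed
#' within each session (site sets differ across sessions) from the listed
#' trial rows only, then averaged across sessions per cell.
#'
#' @param sessions list of [SessionRecording-class] objects.
#' @param trialRows list (parallel to `sessions`) of integer trial-row
#'   vectors to use in each session.
#' @inheritParams buildSessionRDM
#' @return an [RDM-class].
#' @export
buildPooledRDM <- function(sessions, trialRows, measure = validMeasures,
                           window = c(0, 0.25), stimset = makeStimulusSet(),
                           cap = 200L, seed = 0L, rateSites = 30L) {
  measure <- match.arg(measure)
  ids <- analyzedStimuli(stimset)
  acc <- matrix(NA_real_, length(sessions), length(ids) * (length(ids) - 1L) / 2L)
  for (k in seq_along(sessions)) {
    rows <- trialRows[[k]]
    rows <- rows[sessions[[k]]@trialMeta$stimulusId[rows] %in% ids]
    if (!length(rows)) next
    acc[k, ] <- sessionPairMeans(sessions[[k]], rows, measure, window, ids,
                                 cap = cap, seed = seed,
                                 rateSites = rateSites)
  }
  v <- colMeans(acc, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  rdm(pairVectorToMatrix(v, ids), ids = ids, measure = measure,
      window = window, context = "pooled", source = "pooled-trials")
}
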