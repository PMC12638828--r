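# Independent dense-time oracles for the spike dissimilarity profiles,
# written directly from the pointwise definitions (no shared code with the
# package's segment-based implementation), plus small fixture builders.

oracleAugment <- function(times, w) {
  t <- times[times >= w[1] & times <= w[2]]
  unique(c(w[1], t, w[2]))
}

# interval length of the augmented train containing time t (pointwise)
oracleIsiAt <- function(aug, t) {
  p <- max(aug[aug <= t]); f <- min(aug[aug >= t])
  if (p == f) { # t is exactly a spike: use the following interval
    i <- which(aug == p)
    if (i < length(aug)) return(aug[i + 1] - aug[i])
    return(aug[i] - aug[i - 1])
  }
  f - p
}

oracleIsiValue <- function(xa, ya, t) {
  xi <- oracleIsiAt(xa, t); yi <- oracleIsiAt(ya, t)
  abs(xi - yi) / max(xi, yi)
}

oracleSpikeValue <- function(xa, ya, t) {
  sFor <- function(aa, bb) {
    p <- max(aa[aa <= t]); f <- min(aa[aa > t])
    if (!is.finite(f)) { f <- p; p <- max(aa[aa < t]) }
    dp <- min(abs(bb - p)); df <- min(abs(bb - f))
    isi <- f - p
    list(S = (dp * (f - t) + df * (t - p)) / isi, isi = isi)
  }
  x <- sFor(xa, ya); y <- sFor(ya, xa)
  m <- (x$isi + y$isi) / 2
  (x$S * y$isi + y$S * x$isi) / (2 * m * m)
}

# evaluation times inside the window, away from all breakpoints
oracleSampleTimes <- function(xa, ya, n = 200, margin = 1e-6) {
  w <- range(c(xa, ya))
  t <- seq(w[1] + margin, w[2] - margin, length.out = n)
  bp <- sort(unique(c(xa, ya)))
  ok <- vapply(t, function(ti) min(abs(bp - ti)) > margin, logical(1))
  t[ok]
}

randomTrain <- function(maxSpikes = 12, window = c(0, 1)) {
  n <- sample(0:maxSpikes, 1)
  spikeTrain(sort(stats::runif(n, window[1], window[2])), window)
}

# tiny single-context session with hand-chosen per-stimulus trains
manualSession <- function(trainsByStimulus, sites, window, context = "motion",
                          subject = "m1", session = "manual01") {
  ids <- rep(names(trainsByStimulus),
             vapply(trainsByStimulus, length, integer(1)))
  trials <- unlist(trainsByStimulus, recursive = FALSE, use.names = FALSE)
  new("SessionRecording", subject = subject, session = session,
      sites = sites, window = window, trials = trials,
      trialMeta = data.frame(trial = seq_along(ids), stimulusId = ids,
                             context = context, stringsAsFactors = FALSE))
}

# nested unit -> context -> RDM list from a small simulated cohort
cohortContextRDMs <- function(cfg, measure = "ISI",
                              stimset = makeStimulusSet()) {
  rdms <- list()
  for (subj in seq_len(cfg$subjects)) {
    byCtx <- list()
    for (cx in cfg$contexts) {
      per <- lapply(seq_len(cfg$sessionsPerContext), function(k)
        rdmMatrix(buildSessionRDM(simulateSession(cfg, subj, cx, k, stimset),
                                  measure, context = cx, stimset = stimset)))
      byCtx[[cx]] <- rdm(Reduce(`+`, per) / length(per),
                         ids = analyzedStimuli(stimset), measure = measure,
                         context = cx)
    }
    rdms[[sprintf("m%d", subj)]] <- byCtx
  }
  rdms
}

# attention geometry with seeded symmetric Gaussian noise on the cells
seededNoisyAE <- function(w, seed, sd = 0.01,
                          stimset = makeStimulusSet()) {
  set.seed(seed)
  m <- rdmMatrix(attentionRDM(stimset, w))
  n <- matrix(0, 16, 16)
  n[upper.tri(n)] <- stats::rnorm(120, sd = sd)
  m <- pmax(m + n + t(n), 0)
  diag(m) <- 0
  rdm(m, ids = analyzedStimuli(stimset))
}

# one seeded replicate of the full generator -> session RDMs -> model-free
# stretching test pipeline; returns the interaction p and contrast sign
stretchReplicate <- function(rep, preset, stimset = makeStimulusSet()) {
  cfg <- cohortConfig(preset, sessionsPerContext = 1, sites = 8,
                      trialsPerStimulus = 4, noise = 0.2,
                      seed = 1000 + rep)
  rdms <- list()
  for (subj in 1:2) {
    byCtx <- list()
    for (cx in c("color", "motion"))
      byCtx[[cx]] <- buildSessionRDM(simulateSession(cfg, subj, cx, 1,
                                                     stimset),
                                     "ISI", context = cx, stimset = stimset)
    rdms[[paste0("m", subj)]] <- byCtx
  }
  st <- stretchingTest(stretchingTable(rdms, stimset))
  c(p = st$interaction$p, dir = as.numeric(mean(st$contrasts$meanDiff) > 0))
}
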