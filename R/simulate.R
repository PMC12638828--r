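#' Cohort configuration for the synthetic-recording generator
#'
#' Describes a simulated multi-session recording cohort whose
#' representational geometry is planted at the level of expected pairwise
#' distances: in each task context the target dissimilarity between two
#' stimuli is the attention-weighted geometry [attentionRDM()] evaluated at
#' that context's true attention weight (weight on the motion dimension,
#' `c = 1`).
#'
#' In `"timing"` mode every site fires exactly the same number of spikes
#' for every stimulus (rate measures carry no signal by construction); the
#' stimulus is encoded by modulating the interspike-interval pattern of a
#' shared template train in proportion to the projection of the weighted
#' stimulus coordinates onto a site-specific random direction. In `"rate"`
#' mode per-site mean counts are linear in the same weighted projection
#' with additive noise, and spike times within the window are uniform.
#'
#' @param preset one of `"modulated"` (attention tracks context:
#'   motion-weight 0.8 in the motion context, 0.2 in the color context),
#'   `"null"` (0.5 in both contexts: no stretching), `"mt-like"`
#'   (motion-bound: 0.9 in both contexts), `"v4-like"` (color-bound: 0.1 in
#'   both), `"pfc-like"` (alias of `"modulated"`).
#' @param subjects number of subjects (default 2).
#' @param sessionsPerContext sessions per subject and context (default 5;
#'   `paperScale = TRUE` raises the cohort to 53 sessions per subject).
#' @param sites recording sites per session (default 30).
#' @param trialsPerStimulus trials per stimulus per session (default 10;
#'   at least 2 are required for cross-trial pairs).
#' @param window recording window around stimulus onset in seconds.
#' @param wTrue named numeric: true attention weight on the motion
#'   dimension per context; overrides the preset.
#' @param coding `"timing"` or `"rate"`.
#' @param noise nonnegative noise scale: spike-time jitter as a fraction of
#'   the template interspike interval (timing) or count noise as a fraction
#'   of the base count (rate). Default 0.2.
#' @param includeAmbiguous also simulate trials of the 5 ambiguous stimuli
#'   (excluded from all analyses). Default `FALSE`.
#' @param seed master seed; all draws are keyed by
#'   (seed, subject, context, session, trial, site) so any single trial is
#'   reproducible in isolation.
#' @param paperScale if `TRUE`, use 53 sessions split across the two
#'   contexts per subject.
#' @return a list of class `cohortConfig`.
#' @export
cohortConfig <- function(preset = c("modulated", "null", "mt-like",
                                    "v4-like", "pfc-like"),
                         subjects = 2L, sessionsPerContext = 5L,
                         sites = 30L, trialsPerStimulus = 10L,
                         window = c(-0.1, 0.5), wTrue = NULL,
                         coding = c("timing", "rate"), noise = 0.2,
                         includeAmbiguous = FALSE, seed = 1L,
                         paperScale = FALSE) {
  preset <- match.arg(preset)
  coding <- match.arg(coding)
  if (is.null(wTrue))
    wTrue <- switch(preset,
                    "modulated" = , "pfc-like" = c(color = 0.2, motion = 0.8),
                    "null" = c(color = 0.5, motion = 0.5),
                    "mt-like" = c(color = 0.9, motion = 0.9),
                    "v4-like" = c(color = 0.1, motion = 0.1))
  if (paperScale) sessionsPerContext <- 27L  # ~53 sessions per subject
  stopifnot(trialsPerStimulus >= 2L, sites >= 1L, noise >= 0,
            window[1] < window[2],
            all(c("color", "motion") %in% names(wTrue)))
  structure(list(preset = preset, subjects = as.integer(subjects),
                 contexts = c("color", "motion"),
                 sessionsPerContext = as.integer(sessionsPerContext),
                 sites = as.integer(sites),
                 trialsPerStimulus = as.integer(trialsPerStimulus),
                 window = as.numeric(window), wTrue = wTrue,
                 coding = coding, noise = noise,
                 includeAmbiguous = isTRUE(includeAmbiguous),
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

# centered stimulus coordinates in [-1, 1] on (color, motion); analysed
# stimuli use their grid coordinates, ambiguous stimuli their boundary
# steps on the 7-step physical axes
centeredCoords <- function(stimset) {
  s <- stimulusCoords(stimset)
  cc <- ifelse(s$ambiguous, (s$colorStep - 4) / 3, (s$colorCoord - 2.5) / 1.5)
  mc <- ifelse(s$ambiguous, (s$motionStep - 4) / 3, (s$motionCoord - 2.5) / 1.5)
  m <- cbind(color = cc, motion = mc)
  rownames(m) <- s$stimulusId
  m
}

# interval-modulation depth of the timing code (fraction of the template
# interspike interval) and rate-code count parameters
.timingAlpha <- 0.4
.rateBase <- 10
.rateGain <- 6

#' Simulate one recording session
#'
#' Generates a single-context [SessionRecording-class] whose expected
#' pairwise representational distances follow the planted
#' attention-weighted geometry of `config` (see [cohortConfig()]).
#'
#' @param config a [cohortConfig()].
#' @param subject subject index (1-based) or id string `"m<k>"`.
#' @param context `"color"` or `"motion"`.
#' @param sessionIndex session index within subject and context.
#' @param stimset the [StimulusSet-class]; defaults to [makeStimulusSet()].
#' @return a [SessionRecording-class].
#' @export
simulateSession <- function(config, subject, context, sessionIndex,
                            stimset = makeStimulusSet()) {
  stopifnot(inherits(config, "cohortConfig"))
  context <- match.arg(context, c("color", "motion"))
  subjIdx <- if (is.character(subject)) as.integer(sub("^m", "", subject)) else as.integer(subject)
  subject <- sprintf("m%d", subjIdx)
  ctxIdx <- match(context, c("color", "motion"))
  w <- config$wTrue[[context]]
  coords <- centeredCoords(stimset)
  s <- stimulusCoords(stimset)
  useIds <- if (config$includeAmbiguous) s$stimulusId else s$stimulusId[!s$ambiguous]
  # weighted coordinates: weight w on motion, 1 - w on color
  wc <- cbind(sqrt(1 - w) * coords[useIds, "color"],
              sqrt(w) * coords[useIds, "motion"])
  nSites <- config$sites
  # site-specific random unit directions in the (color, motion) plane,
  # independent across sites and sessions: the site-pooled |projection|
  # approximates the planted weighted norm with O(1/sqrt(sites)) angular
  # sampling error, and sessions are exchangeable draws of a site
  # population rather than copies of one direction set
  ang <- vapply(seq_len(nSites), function(sIdx)
    withSeed(mixSeed(config$seed, subjIdx, ctxIdx, sessionIndex, sIdx,
                     "direction"),
             stats::runif(1, 0, 2 * pi)), numeric(1))
  u <- cbind(cos(ang), sin(ang))
  z <- wc %*% t(u)  # stimuli x sites projections in [-sqrt(2), sqrt(2)]
  z <- z / sqrt(2)
  # heterogeneous tuning: a session-fixed per-(site, stimulus) distortion
  # of the encoded projection, scaled by the noise level; keeps the
  # session-to-session geometric error high-dimensional across stimulus
  # pairs rather than one shared direction-set effect
  if (config$noise > 0) {
    tune <- withSeed(mixSeed(config$seed, subjIdx, ctxIdx, sessionIndex,
                             "tuning"),
                     matrix(stats::rnorm(length(z), sd = 0.3 * config$noise),
                            nrow(z), ncol(z)))
    z <- z + tune
  }
  nTrial <- config$trialsPerStimulus
  stimSeq <- rep(useIds, each = nTrial)
  trials <- vector("list", length(stimSeq))
  w0 <- config$window
  for (tr in seq_along(stimSeq)) {
    stim <- stimSeq[tr]
    trialTrains <- vector("list", nSites)
    for (sIdx in seq_len(nSites)) {
      sd_ <- mixSeed(config$seed, subjIdx, ctxIdx, sessionIndex, tr, sIdx)
      zz <- unname(z[stim, sIdx])
      trialTrains[[sIdx]] <- withSeed(sd_, {
        if (config$coding == "timing") timingTrain(zz, w0, config$noise)
        else rateTrain(zz, w0, config$noise)
      })
    }
    trials[[tr]] <- trialTrains
  }
  meta <- data.frame(trial = seq_along(stimSeq), stimulusId = stimSeq,
                     context = context, stringsAsFactors = FALSE)
  new("SessionRecording", subject = subject,
      session = sprintf("%s_%s_s%02d", subject, context, sessionIndex),
      sites = sprintf("site%02d", seq_len(nSites)), window = w0,
      trials = trials, trialMeta = meta)
}

# timing-coded train: intervals alternate T0 * (1 +/- alpha * z) around the
# template interval, plus per-spike jitter. The spike count is 24 at zero
# noise and jitters stimulus-independently with noise, so rate measures
# carry no stimulus signal in expectation (and none at all at zero noise).
timingTrain <- function(z, window, noise) {
  K <- 24L
  if (noise > 0)
    K <- max(8L, min(48L, K + as.integer(round(stats::rnorm(1, sd = 3 * noise)))))
  T0 <- (window[2] - window[1]) / K
  dev <- .timingAlpha * z * T0
  ivals <- rep(c(T0 + dev, T0 - dev), length.out = K - 1L)
  t <- window[1] + 0.5 * T0 + cumsum(c(0, ivals))
  if (noise > 0) t <- sort(t + stats::rnorm(K, sd = noise * T0))
  t <- pmin(pmax(t, window[1] + 1e-6), window[2] - 1e-6)
  enforceIncreasing(t)
}

# rate-coded train: count linear in the weighted projection with additive
# noise; homogeneous (uniform) spike timing
rateTrain <- function(z, window, noise) {
  n <- max(0L, as.integer(round(.rateBase + .rateGain * z +
                                stats::rnorm(1, sd = noise * .rateBase))))
  if (n == 0L) return(numeric(0))
  enforceIncreasing(sort(stats::runif(n, window[1], window[2])))
}

enforceIncreasing <- function(t) {
  if (length(t) > 1L) {
    d <- diff(t)
    if (any(d <= 0)) t <- cumsum(c(t[1], pmax(d, 1e-9)))
  }
  t
}

#' Simulate a full cohort
#'
#' Generates the full subject x context x session grid of
#' [simulateSession()] recordings.
#'
#' @inheritParams simulateSession
#' @return list of [SessionRecording-class] objects.
#' @examples
#' cfg <- cohortConfig("null", sessionsPerContext = 1, sites = 4,
#'                     trialsPerStimulus = 2)
#' length(simulateCohort(cfg))  # 2 subjects x 2 contexts x 1 session
#' @export
simulateCohort <- function(config, stimset = makeStimulusSet()) {
  out <- list()
  for (subj in seq_len(config$subjects))
    for (ctx in config$contexts)
      for (sess in seq_len(config$sessionsPerContext))
        out[[length(out) + 1L]] <-
          simulateSession(config, subj, ctx, sess, stimset)
  out
}
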