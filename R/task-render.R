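#' Configuration of the rendered visuomotor task and recurrent model
#'
#' The `"scaled"` preset keeps the trial structure (fixation, cue, moving
#' colored dots; labels L/R/N; trial-by-trial learning with batch size 1)
#' at a size a single CPU can train: 32x32 frames, 30 frames per trial
#' (3 fixation + 7 cue + 20 stimulus, preserving the 0.5 s / 1 s / 3 s
#' phase proportions), a fixed average-pooling feature extractor, and a
#' 3-layer stacked LSTM with 64 cells. The `"full"` preset carries the
#' full-scale constants (270 frames at 60 frames/s, 6 layers x 1000
#' cells, 256-unit readout, learning rate 1e-5) for parity.
#'
#' @param preset `"scaled"` or `"full"`.
#' @param ... named overrides of any config entry.
#' @return list of class `taskConfig`. Entries: `imageSize`, `framesFix`,
#'   `framesCue`, `framesStim`, `frameRate` (frames/s used by the
#'   LSTM-time mapping), `nDots`, `dotRadius`, `speed` (pixels/frame),
#'   `extractor` (`"pool"`: average-pool to `poolTo` x `poolTo` per
#'   channel; `"pool+diff"` (default): append the per-frame temporal
#'   difference of the pooled image as a motion-energy channel; `"proj"`:
#'   a fixed seeded random projection to `projDim`), `layers`, `hidden`,
#'   `ht`, `classes`, `lr`, `lrDecayEpochs`/`lrDecayFactor` (stepped
#'   learning-rate decay at the listed epochs), `lossMode`
#'   (`"final"`: cross-entropy on the trial-final output; `"all"`: mean
#'   over frames), `clip` (gradient-norm clip).
#' @export
taskConfig <- function(preset = c("scaled", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(imageSize = 32L, framesFix = 3L, framesCue = 7L,
              framesStim = 20L, frameRate = 30 / 4.5, nDots = 14L,
              dotRadius = 2L, speed = 3, extractor = "pool+diff", poolTo = 8L,
              projDim = 64L, projSeed = 20260101L, layers = 3L,
              hidden = 64L, ht = 32L, classes = 3L, lr = 1e-3,
              lrDecayEpochs = c(16L, 24L), lrDecayFactor = 0.3,
              lossMode = "final", clip = 5)
  if (preset == "full")
    cfg[c("framesFix", "framesCue", "framesStim", "frameRate", "layers",
          "hidden", "ht", "lr")] <-
      list(30L, 60L, 180L, 60, 6L, 1000L, 256L, 1e-5)
  over <- list(...)
  cfg[names(over)] <- over
  cfg$framesPerTrial <- cfg$framesFix + cfg$framesCue + cfg$framesStim
  structure(cfg, class = "taskConfig")
}

# 7-step color axis interpolating green -> red (step 4 = boundary) and
# 7-step motion axis spanning up -> down through horizontal
stepColor <- function(step) {
  r <- (step - 1) / 6
  c(r = r, g = 1 - r, b = 0.15)
}
stepAngle <- function(step) (90 - (step - 1) * 30) * pi / 180  # radians

drawSquare <- function(img, cx, cy, r, col) {
  n <- dim(img)[1]
  xs <- max(1, round(cx - r)):min(n, round(cx + r))
  ys <- max(1, round(cy - r)):min(n, round(cy + r))
  for (ch in 1:3) img[ys, xs, ch] <- col[ch]
  img
}

drawDisc <- function(img, cx, cy, r, col) {
  n <- dim(img)[1]
  xs <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  for (x in xs) for (y in ys)
    if ((x - cx)^2 + (y - cy)^2 <= r^2)
      img[y, x, ] <- col
  img
}

# cue shapes: cross/quatrefoil signal the motion task, circle/triangle the
# color task
drawCue <- function(img, shape) {
  n <- dim(img)[1]; c0 <- (n + 1) / 2
  white <- c(1, 1, 1)
  switch(shape,
    cross = {
      img <- drawSquare(img, c0, c0, 1, white)
      for (d in c(-6, -3, 3, 6)) {
        img <- drawSquare(img, c0 + d, c0, 1, white)
        img <- drawSquare(img, c0, c0 + d, 1, white)
      }
      img
    },
    quatrefoil = {
      for (d in list(c(-5, 0), c(5, 0), c(0, -5), c(0, 5)))
        img <- drawDisc(img, c0 + d[1], c0 + d[2], 3, white)
      img
    },
    circle = drawDisc(img, c0, c0, 7, white),
    triangle = {
      for (row in 0:7) {
        y <- round(c0 - 4 + row)
        xs <- max(1, round(c0 - row / 2)):min(n, round(c0 + row / 2))
        img[y, xs, 1] <- 1; img[y, xs, 2] <- 1; img[y, xs, 3] <- 1
      }
      img
    })
}

#' Render one trial of the cued color/motion task
#'
#' Frames show a central fixation point, then a cue whose shape encodes
#' the task context (cross/quatrefoil: motion; circle/triangle: color),
#' then a field of dots sharing one color and drifting with 100%
#' coherence in one direction. Dot starting positions are re-randomised
#' per trial (seeded); the per-frame displacement of every dot equals the
#' direction vector times the speed. Ambiguous stimuli are labelled `N`
#' regardless of the cue.
#'
#' @param stimulusId stimulus id from the [StimulusSet-class].
#' @param context `"color"` or `"motion"`.
#' @param config a [taskConfig()].
#' @param seed integer seed for dot placement and cue-shape choice.
#' @param stimset the stimulus set.
#' @return a [TrialImages-class]. `dotTracks` holds the unwrapped dot
#'   coordinates (pixels, frame x dot x (x, y)); rasterisation wraps them
#'   into the image torus.
#' @export
renderTrial <- function(stimulusId, context = c("color", "motion"),
                        config = taskConfig(), seed = 1L,
                        stimset = makeStimulusSet()) {
  context <- match.arg(context)
  s <- stimulusCoords(stimset)
  row <- s[s$stimulusId == stimulusId, ]
  if (nrow(row) != 1L) stop("unknown stimulus: ", stimulusId)
  label <- if (context == "color") row$labelColor else row$labelMotion
  n <- config$imageSize
  nF <- config$framesPerTrial
  col <- stepColor(row$colorStep)
  ang <- stepAngle(row$motionStep)
  v <- config$speed * c(cos(ang), sin(ang))
  frames <- array(0, dim = c(n, n, 3L, nF))
  c0 <- (n + 1) / 2
  rnd <- withSeed(mixSeed(seed, stimulusId, context), {
    list(pos = cbind(stats::runif(config$nDots, 1, n),
                     stats::runif(config$nDots, 1, n)),
         shapePick = stats::runif(1))
  })
  shape <- if (context == "motion") {
    if (rnd$shapePick < 0.5) "cross" else "quatrefoil"
  } else {
    if (rnd$shapePick < 0.5) "circle" else "triangle"
  }
  phase <- rep(c("fixation", "cue", "stimulus"),
               c(config$framesFix, config$framesCue, config$framesStim))
  tracks <- array(NA_real_, dim = c(config$framesStim, config$nDots, 2L))
  for (f in seq_len(nF)) {
    img <- array(0, dim = c(n, n, 3L))
    if (phase[f] == "fixation") {
      img <- drawSquare(img, c0, c0, 1, c(1, 1, 1))
    } else if (phase[f] == "cue") {
      img <- drawCue(img, shape)
    } else {
      k <- f - config$framesFix - config$framesCue
      pos <- rnd$pos + (k - 1) * matrix(v, config$nDots, 2L, byrow = TRUE)
      tracks[k, , ] <- pos
      wrapped <- ((pos - 1) %% n) + 1
      for (dIdx in seq_len(config$nDots))
        img <- drawSquare(img, wrapped[dIdx, 1],
                          # image rows grow downward; y grows upward
                          n + 1 - wrapped[dIdx, 2], config$dotRadius, col)
    }
    frames[, , , f] <- img
  }
  new("TrialImages", frames = frames, phase = phase,
      stimulusId = stimulusId, context = context, label = label,
      dotTracks = tracks, seed = as.integer(seed))
}

#' @describeIn renderTrial per-trial target label accessor
#' @param x a `TrialImages`.
#' @export
trialLabel <- function(x) x@label

setMethod("show", "TrialImages", function(object) {
  cat(sprintf("TrialImages: %s (%s context, label %s), %d frames\n",
              object@stimulusId, object@context, object@label,
              length(object@phase)))
})

# global gradient-based flow estimate between two luminance frames
# (least-squares solution of the brightness-constancy equation), the
# classic motion-energy front-end
globalFlow <- function(prev, cur) {
  n <- nrow(prev)
  Ix <- (cbind(prev[, -1], prev[, n]) - cbind(prev[, 1], prev[, -n])) / 2
  Iy <- (rbind(prev[-1, ], prev[n, ]) - rbind(prev[1, ], prev[-n, ])) / 2
  It <- cur - prev
  a <- sum(Ix * Ix); b <- sum(Ix * Iy); d <- sum(Iy * Iy)
  det <- a * d - b * b
  if (det < 1e-8) return(c(0, 0))
  vx <- (-d * sum(Ix * It) + b * sum(Iy * It)) / det
  vy <- (b * sum(Ix * It) - a * sum(Iy * It)) / det
  # image rows grow downward; report y as upward velocity
  c(vx, -vy)
}

# average-pool each frame to poolTo x poolTo per channel and flatten; the
# default extractor appends the pooled temporal difference and a global
# optical-flow estimate as motion-energy channels; "proj" applies a fixed
# seeded random projection instead
extractFeatures <- function(frames, config) {
  n <- dim(frames)[1]; nF <- dim(frames)[4]
  p <- config$poolTo
  P <- matrix(0, p, n)
  blk <- n / p
  for (i in seq_len(p)) P[i, ((i - 1) * blk + 1):(i * blk)] <- 1 / blk
  feat <- matrix(0, nF, p * p * 3L)
  lum <- vector("list", nF)
  for (f in seq_len(nF)) {
    v <- numeric(0)
    for (ch in 1:3) v <- c(v, as.vector(P %*% frames[, , ch, f] %*% t(P)))
    feat[f, ] <- v
    lum[[f]] <- (frames[, , 1, f] + frames[, , 2, f] + frames[, , 3, f]) / 3
  }
  if (identical(config$extractor, "pool+diff")) {
    flow <- t(vapply(seq_len(nF), function(f) {
      if (f == 1L) c(0, 0) else globalFlow(lum[[f - 1L]], lum[[f]])
    }, numeric(2)))
    feat <- cbind(feat, rbind(0, diff(feat)), flow / max(1, config$speed))
  } else if (identical(config$extractor, "proj")) {
    R <- withSeed(config$projSeed,
                  matrix(stats::rnorm(config$projDim * ncol(feat)),
                         ncol(feat), config$projDim) / sqrt(ncol(feat)))
    feat <- feat %*% R
  }
  feat
}

#' Render a trial set and extract model-ready features
#'
#' Renders each requested trial, extracts its per-frame feature matrix
#' and discards the raw frames (memory stays bounded for large sets).
#'
#' @param specs data.frame with columns `stimulusId`, `context` and
#'   `trialSeed` (see [makeTrialSpecs()]).
#' @param config a [taskConfig()].
#' @return list with `features` (list of frames x d matrices), `meta`
#'   (the specs with a `label` column).
#' @export
prepareTrialData <- function(specs, config = taskConfig()) {
  stimset <- makeStimulusSet()
  feats <- vector("list", nrow(specs))
  labels <- character(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    tr <- renderTrial(specs$stimulusId[i], specs$context[i], config,
                      seed = specs$trialSeed[i], stimset = stimset)
    feats[[i]] <- extractFeatures(tr@frames, config)
    labels[i] <- tr@label
  }
  meta <- specs
  meta$label <- labels
  list(features = feats, meta = meta)
}

#' Enumerate trial specifications for a balanced trial set
#'
#' @param nPerStim trials per stimulus per context.
#' @param contexts task contexts to include.
#' @param seed base seed; every trial gets its own derived seed.
#' @param stimset the stimulus set.
#' @return data.frame with `stimulusId`, `context`, `trialSeed`.
#' @export
makeTrialSpecs <- function(nPerStim, contexts = c("color", "motion"),
                           seed = 1L, stimset = makeStimulusSet()) {
  s <- stimulusCoords(stimset)
  g <- expand.grid(stimulusId = s$stimulusId, context = contexts,
                   rep = seq_len(nPerStim), stringsAsFactors = FALSE)
  g$trialSeed <- vapply(seq_len(nrow(g)), function(i)
    mixSeed(seed, g$stimulusId[i], g$context[i], g$rep[i]), integer(1))
  g[c("stimulusId", "context", "trialSeed")]
}

#' LSTM-time frame accounting
#'
#' Number of input images covered by a time bin at a given frame rate:
#' at 60 frames/s a 0.05 s bin covers 3 input images and the 0.25 s whole
#' period covers 15.
#'
#' @param width bin width in seconds.
#' @param frameRate frames per second.
#' @return integer frame count (at least 1).
#' @examples
#' lstmFrameCount(0.05, 60)  # 3
#' lstmFrameCount(0.25, 60)  # 15
#' @export
lstmFrameCount <- function(width, frameRate)
  max(1L, as.integer(round(width * frameRate)))
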