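#' @import methods
NULL

#' SpikeTrain: spike times of one unit within a bounded observation window
#'
#' Atomic input to all timing measures. Spike times are strictly increasing
#' and lie inside the closed window `[t0, t1]`.
#'
#' @slot times numeric, strictly increasing spike times in seconds.
#' @slot window numeric(2), closed observation interval `c(t0, t1)` with
#'   `t0 < t1`.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
         representation(times = "numeric", window = "numeric"))

setValidity("SpikeTrain", function(object) {
  w <- object@window
  t <- object@times
  if (length(w) != 2L || anyNA(w)) return("window must be numeric(2)")
  if (!(w[1] < w[2])) return("window must satisfy t0 < t1")
  if (anyNA(t)) return("spike times must not contain NA")
  if (length(t) && (any(t < w[1]) || any(t > w[2])))
    return("all spike times must lie in the window")
  if (length(t) > 1L && any(diff(t) <= 0))
    return("spike times must be strictly increasing (duplicates rejected)")
  TRUE
})

#' DissimilarityProfile: time-resolved bivariate dissimilarity
#'
#' The ISI profile is piecewise constant; the SPIKE profile is piecewise
#' linear. Values are stored per segment between consecutive breakpoints:
#' one value per segment for ISI, a start/end value pair per segment for
#' SPIKE.
#'
#' @slot breakpoints increasing numeric vector spanning the window.
#' @slot values numeric matrix with one row per segment; 1 column (ISI) or
#'   2 columns (SPIKE: value at segment start and end).
#' @slot kind `"ISI"` or `"SPIKE"`.
#' @slot window numeric(2) observation window.
#' @exportClass DissimilarityProfile
setClass("DissimilarityProfile",
         representation(breakpoints = "numeric", values = "matrix",
                        kind = "character", window = "numeric"))

setValidity("DissimilarityProfile", function(object) {
  b <- object@breakpoints
  v <- object@values
  if (!object@kind %in% c("ISI", "SPIKE")) return("kind must be ISI or SPIKE")
  if (length(b) < 2L || any(diff(b) <= 0)) return("breakpoints must increase")
  if (nrow(v) != length(b) - 1L) return("one value row per segment required")
  if (ncol(v) != (if (object@kind == "ISI") 1L else 2L))
    return("ISI profiles carry 1 value per segment, SPIKE profiles 2")
  if (any(v < -1e-12)) return("profile values must be nonnegative")
  if (object@kind == "ISI" && any(v >= 1)) return("ISI values must be < 1")
  TRUE
})

#' TrialSiteMatrix: the spike trains of one trial across recording sites
#'
#' @slot trains named list of [SpikeTrain-class] objects, one per site;
#'   all trains share one window.
#' @slot sites character vector of site identifiers.
#' @exportClass TrialSiteMatrix
setClass("TrialSiteMatrix",
         representation(trains = "list", sites = "character"))

setValidity("TrialSiteMatrix", function(object) {
  if (length(object@trains) != length(object@sites))
    return("one train per site required")
  if (!length(object@trains)) return("at least one site required")
  if (!all(vapply(object@trains, is, logical(1), "SpikeTrain")))
    return("trains must be SpikeTrain objects")
  w <- vapply(object@trains, function(x) x@window, numeric(2))
  if (any(abs(w - w[, 1]) > 1e-12)) return("all trains must share one window")
  TRUE
})

#' SessionRecording: one recording session
#'
#' Trials are stored compactly as lists of per-site numeric spike-time
#' vectors; [trialTrains()] materialises a [TrialSiteMatrix-class] on demand.
#'
#' @slot subject character scalar subject id.
#' @slot session character scalar session id.
#' @slot sites character vector of site ids (consistent across trials).
#' @slot window numeric(2) recording window around stimulus onset (s).
#' @slot trials list (one element per trial) of lists of per-site numeric
#'   spike-time vectors, in site order.
#' @slot trialMeta data.frame with columns `trial`, `stimulusId`, `context`.
#' @exportClass SessionRecording
setClass("SessionRecording",
         representation(subject = "character", session = "character",
                        sites = "character", window = "numeric",
                        trials = "list", trialMeta = "data.frame"))

setValidity("SessionRecording", function(object) {
  if (length(object@trials) != nrow(object@trialMeta))
    return("trialMeta must have one row per trial")
  need <- c("trial", "stimulusId", "context")
  if (!all(need %in% names(object@trialMeta)))
    return("trialMeta needs columns trial, stimulusId, context")
  if (!(object@window[1] < object@window[2])) return("invalid window")
  ns <- lengths(object@trials)
  if (length(ns) && any(ns != length(object@sites)))
    return("every trial must carry one spike vector per site")
  TRUE
})

#' StimulusSet: the cued color/motion stimulus grid
#'
#' 16 analysed stimuli tile the 4x4 (color, motion) grid; 5 ambiguous
#' stimuli sit at or near the category boundary and are labelled `N` in both
#' contexts. `colorStep`/`motionStep` give positions on the underlying
#' 7-step physical axes used by the stimulus renderer.
#'
#' @slot stimuli data.frame with columns `stimulusId`, `colorCoord`,
#'   `motionCoord` (grid 1..4, NA for ambiguous), `colorStep`, `motionStep`
#'   (physical axes 1..7), `ambiguous`, `labelColor`, `labelMotion`.
#' @exportClass StimulusSet
setClass("StimulusSet", representation(stimuli = "data.frame"))

setValidity("StimulusSet", function(object) {
  s <- object@stimuli
  need <- c("stimulusId", "colorCoord", "motionCoord", "colorStep",
            "motionStep", "ambiguous", "labelColor", "labelMotion")
  if (!all(need %in% names(s))) return("missing stimulus columns")
  if (anyDuplicated(s$stimulusId)) return("duplicate stimulus ids")
  grid <- s[!s$ambiguous, c("colorCoord", "motionCoord")]
  if (nrow(grid) &&
      (nrow(unique(grid)) != nrow(grid) ||
       !all(sort(unique(grid$colorCoord)) %in% 1:4)))
    return("non-ambiguous stimuli must have unique grid coordinates in 1..4")
  amb <- s[s$ambiguous, ]
  if (nrow(amb) && !all(amb$labelColor == "N" & amb$labelMotion == "N"))
    return("ambiguous stimuli must be labelled N in both contexts")
  TRUE
})

#' RDM: representational dissimilarity matrix over the analysed stimuli
#'
#' @slot mat symmetric nonnegative matrix with zero diagonal; `NA` marks
#'   entries that could not be estimated.
#' @slot ids character stimulus ordering (row/col names of `mat`).
#' @slot measure character provenance: which dissimilarity measure.
#' @slot window numeric(2) analysis window (s), or `NA` where inapplicable.
#' @slot context character task context provenance (`"color"`, `"motion"`,
#'   `"none"`, ...).
#' @slot source character free-form provenance tag.
#' @exportClass RDM
setClass("RDM",
         representation(mat = "matrix", ids = "character",
                        measure = "character", window = "numeric",
                        context = "character", source = "character"))

setValidity("RDM", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (nrow(m) != length(object@ids)) return("ids must match matrix dimension")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)) ||
      !all(is.na(m) == t(is.na(m))))
    return("matrix must be symmetric (including missingness pattern)")
  d <- diag(m)
  if (any(!is.na(d) & abs(d) > 1e-10)) return("diagonal must be zero")
  if (any(!is.na(m) & m < -1e-10)) return("entries must be nonnegative")
  TRUE
})

#' RSAResult: one RDM-to-RDM Spearman comparison
#'
#' @slot rho Spearman rank correlation over comparable upper-triangle cells.
#' @slot nCells number of compared (non-missing) cells.
#' @slot window numeric(2) analysis window or NA.
#' @slot measure character measure provenance.
#' @exportClass RSAResult
setClass("RSAResult",
         representation(rho = "numeric", nCells = "integer",
                        window = "numeric", measure = "character"))

setValidity("RSAResult", function(object) {
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
    return("rho must lie in [-1, 1]")
  TRUE
})

#' AttentionFit: grid-search fit of the attention weight
#'
#' @slot w fitted attention weight on the relevant dimension, in `[0, 1]`.
#' @slot rho training Spearman correlation at the fitted weight.
#' @slot tie logical, whether the argmax was a tied run (then `w` is the
#'   midpoint of the longest tied run).
#' @slot grid numeric candidate grid searched.
#' @slot relevantDimension `"color"` or `"motion"`.
#' @exportClass AttentionFit
setClass("AttentionFit",
         representation(w = "numeric", rho = "numeric", tie = "logical",
                        grid = "numeric", relevantDimension = "character"))

#' CVResult: cross-validated attention-model evaluations
#'
#' @slot folds data.frame with one row per held-out evaluation: `subject`,
#'   `context`, `fold`, `model`, `wFit`, `rhoTrain`, `rhoHeldout`.
#' @slot k number of folds.
#' @slot assignment list recording the seeded fold assignment of trials.
#' @exportClass CVResult
setClass("CVResult",
         representation(folds = "data.frame", k = "integer",
                        assignment = "list"))

#' TrialImages: one rendered trial of the cued color/motion task
#'
#' @slot frames numeric array height x width x 3 x nFrames in `[0, 1]`, or a
#'   0-length array when frames were dropped after feature extraction.
#' @slot phase character per-frame phase label (`fixation`, `cue`,
#'   `stimulus`).
#' @slot stimulusId character stimulus id.
#' @slot context `"color"` or `"motion"`.
#' @slot label target response, one of `"L"`, `"R"`, `"N"`.
#' @slot dotTracks numeric array nStimulusFrames x nDots x 2 of dot
#'   coordinates (pixels) before rasterisation.
#' @slot seed integer seed used for dot placement.
#' @exportClass TrialImages
setClass("TrialImages",
         representation(frames = "array", phase = "character",
                        stimulusId = "character", context = "character",
                        label = "character", dotTracks = "array",
                        seed = "integer"))

setValidity("TrialImages", function(object) {
  if (!object@label %in% c("L", "R", "N")) return("label must be L, R or N")
  if (!object@context %in% c("color", "motion"))
    return("context must be color or motion")
  TRUE
})

#' TaskModel: a trained stacked recurrent (LSTM) task classifier
#'
#' @slot params list of layer weight matrices and readout weights.
#' @slot config list, the model/rendering configuration used.
#' @slot lossTrace numeric per-step training loss.
#' @slot checkpoints data.frame of evaluation checkpoints (`step`, `f1`).
#' @exportClass TaskModel
setClass("TaskModel",
         representation(params = "list", config = "list",
                        lossTrace = "numeric", checkpoints = "data.frame"))
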