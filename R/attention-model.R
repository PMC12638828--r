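#' Attention model specification
#'
#' @param gridStep spacing of the candidate weight grid on `[0, 1]`
#'   (default 0.01, matching the reported weight precision). The grid
#'   always covers 0 and 1.
#' @param c positive scale constant of the attention geometry. Fixed and
#'   excluded from the search: Spearman comparison is provably invariant
#'   to it.
#' @return list with `wGrid` and `c`.
#' @export
attentionModelSpec <- function(gridStep = 0.01, c = 1) {
  stopifnot(gridStep > 0, gridStep <= 0.5, c > 0)
  wGrid <- seq(0, 1, by = gridStep)
  if (wGrid[length(wGrid)] < 1) wGrid <- c(wGrid, 1)
  list(wGrid = wGrid, c = c)
}

# Precompute the rank vectors of the attention geometry's upper-triangle
# cells for every grid weight (optionally restricted to non-missing cells).
attentionGridRanks <- function(stimset, spec, relevantDimension,
                               keep = NULL) {
  sapply(spec$wGrid, function(w) {
    v <- upperCells(attentionRDM(stimset, w, c = spec$c,
                                 relevantDimension = relevantDimension)@mat)
    if (!is.null(keep)) v <- v[keep]
    rank(v)
  })
}

#' Fit the attention weight to an RDM by grid search
#'
#' Evaluates the Spearman correlation between [attentionRDM()] at every
#' grid weight and the data RDM, and returns the maximising weight. A tied
#' argmax run returns the midpoint of the longest tied run (recorded in
#' the fit). The scale constant `c` never affects the result.
#'
#' @param x data [RDM-class] (>= 3 non-missing comparable cells).
#' @param stimset the [StimulusSet-class].
#' @param spec an [attentionModelSpec()].
#' @param relevantDimension dimension carrying the weight `w` (the
#'   complement `1 - w` falls on the other dimension). Default `"motion"`,
#'   so fitted weights read as motion-attention in both contexts.
#' @param gridRanks optional precomputed matrix of per-weight rank vectors
#'   (as built internally) for repeated fitting against complete RDMs.
#' @return an [AttentionFit-class].
#' @examples
#' ss <- makeStimulusSet()
#' f <- fitAttention(attentionRDM(ss, 0.8), ss)
#' attentionWeight(f)  # ~0.8 (midpoint of the tied rho = 1 run)
#' @export
fitAttention <- function(x, stimset = makeStimulusSet(),
                         spec = attentionModelSpec(),
                         relevantDimension = c("motion", "color"),
                         gridRanks = NULL) {
  relevantDimension <- match.arg(relevantDimension)
  v <- upperCells(x@mat)
  keep <- !is.na(v)
  if (sum(keep) < 3L) stop("insufficient data: need >= 3 comparable cells")
  rv <- rank(v[keep])
  if (stats::sd(rv) == 0)
    stop("all-constant RDM: attention weight is unidentified")
  if (is.null(gridRanks))
    gridRanks <- attentionGridRanks(stimset, spec, relevantDimension,
                                    keep = if (all(keep)) NULL else keep)
  rhos <- suppressWarnings(stats::cor(gridRanks, rv))
  rhos[is.na(rhos)] <- -Inf
  best <- max(rhos)
  tied <- which(rhos >= best - 1e-10)
  tie <- length(tied) > 1L
  if (tie) {
    runs <- split(tied, cumsum(c(1L, diff(tied) != 1L)))
    run <- runs[[which.max(lengths(runs))]]
    w <- mean(spec$wGrid[range(run)])
  } else w <- spec$wGrid[tied]
  new("AttentionFit", w = w, rho = best, tie = tie, grid = spec$wGrid,
      relevantDimension = relevantDimension)
}

#' @describeIn fitAttention fitted weight accessor
#' @export
attentionWeight <- function(x) x@w

setMethod("show", "AttentionFit", function(object) {
  cat(sprintf("AttentionFit: w(%s) = %.3f, training rho = %.4f%s\n",
              object@relevantDimension, object@w, object@rho,
              if (object@tie) " (tied argmax run)" else ""))
})

# Seeded stimulus-stratified fold assignment: within every session each
# stimulus's trials are shuffled and dealt round-robin over k folds, so
# every fold contains every stimulus whenever trialsPerStimulus >= k.
assignFolds <- function(sessions, k, context, seed) {
  out <- list()
  for (si in seq_along(sessions)) {
    sess <- sessions[[si]]
    meta <- sess@trialMeta
    rows <- which(meta$context == context)
    fold <- rep(NA_integer_, nrow(meta))
    for (stim in unique(meta$stimulusId[rows])) {
      r <- rows[meta$stimulusId[rows] == stim]
      r <- r[order(meta$trial[r])]
      perm <- withSeed(mixSeed(seed, sess@session, stim), sample(seq_along(r)))
      fold[r[perm]] <- rep_len(seq_len(k), length(r))
    }
    out[[si]] <- fold
  }
  out
}

#' Cross-validated attention-model fitting
#'
#' Trials of each subject and task context are split into `k`
#' stimulus-stratified, seeded folds. Per iteration the RDM built from the
#' k-1 training folds is fitted by [fitAttention()] and the fitted
#' geometry is scored against the RDM built from the held-out fold. With
#' the default `k = 5` over 2 contexts x 2 subjects the procedure yields
#' 20 held-out evaluations.
#'
#' @param sessions list of [SessionRecording-class] objects (all subjects;
#'   filtered internally by subject and context).
#' @param k number of folds (default 5).
#' @param contexts,subjects which contexts/subjects to run; defaults to
#'   all present in `sessions`.
#' @param stimset the [StimulusSet-class].
#' @param spec an [attentionModelSpec()].
#' @param measure dissimilarity measure for the RDMs (default `"ISI"`).
#' @param window analysis window.
#' @param seed seed for fold assignment and RDM pair subsampling.
#' @param baseline if `TRUE`, run the mixed-context baseline: training
#'   pools `k - 1` folds drawn half from the color task and half from the
#'   motion task (for `k = 5`: two color + two motion folds) instead of
#'   the `k - 1` folds of the target context; evaluation stays on the
#'   held-out fold of the target context.
#' @param cap,rateSites passed to the RDM builders.
#' @return a [CVResult-class].
#' @export
crossvalAttention <- function(sessions, k = 5L, contexts = NULL,
                              subjects = NULL, stimset = makeStimulusSet(),
                              spec = attentionModelSpec(), measure = "ISI",
                              window = c(0, 0.25), seed = 1L,
                              baseline = FALSE, cap = 200L,
                              rateSites = 30L) {
  sessSubjects <- vapply(sessions, function(s) s@subject, character(1))
  if (is.null(subjects)) subjects <- sort(unique(sessSubjects))
  if (is.null(contexts))
    contexts <- sort(unique(unlist(lapply(sessions, function(s)
      unique(s@trialMeta$context)))))
  gridRanks <- attentionGridRanks(stimset, spec, "motion")
  rows <- list(); assignment <- list()
  for (subj in subjects) {
    subjSessions <- sessions[sessSubjects == subj]
    folds <- lapply(contexts, function(cx)
      assignFolds(subjSessions, k, cx, mixSeed(seed, subj, cx)))
    names(folds) <- contexts
    for (cx in contexts) {
      assignment[[paste(subj, cx, sep = ".")]] <- folds[[cx]]
      for (f in seq_len(k)) {
        if (baseline) {
          nOther <- (k - 1L) %/% 2L
          nSame <- (k - 1L) - nOther
          other <- setdiff(contexts, cx)[1L]
          sameFolds <- setdiff(seq_len(k), f)[seq_len(nSame)]
          otherFolds <- seq_len(k)[seq_len(nOther)]
          trainRows <- lapply(seq_along(subjSessions), function(si)
            c(which(folds[[cx]][[si]] %in% sameFolds),
              which(folds[[other]][[si]] %in% otherFolds)))
        } else {
          trainRows <- lapply(seq_along(subjSessions), function(si)
            which(folds[[cx]][[si]] %in% setdiff(seq_len(k), f)))
        }
        testRows <- lapply(seq_along(subjSessions), function(si)
          which(folds[[cx]][[si]] == f))
        trainRdm <- buildPooledRDM(subjSessions, trainRows, measure,
                                   window, stimset, cap = cap,
                                   seed = mixSeed(seed, subj, cx, f, 1L),
                                   rateSites = rateSites)
        testRdm <- buildPooledRDM(subjSessions, testRows, measure, window,
                                  stimset, cap = cap,
                                  seed = mixSeed(seed, subj, cx, f, 2L),
                                  rateSites = rateSites)
        fit <- fitAttention(trainRdm, stimset, spec, "motion",
                            gridRanks = gridRanks)
        ae <- attentionRDM(stimset, fit@w, c = spec$c,
                           relevantDimension = "motion")
        held <- tryCatch(rsaRho(rsaSpearman(ae, testRdm)),
                         error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, context = cx, fold = f,
          model = if (baseline) "baseline" else "cognitive",
          wFit = fit@w, rhoTrain = fit@rho, rhoHeldout = held,
          stringsAsFactors = FALSE)
      }
    }
  }
  new("CVResult", folds = do.call(rbind, rows), k = as.integer(k),
      assignment = assignment)
}

#' @describeIn crossvalAttention convenience wrapper for the mixed-context
#'   baseline model
#' @param ... passed to `crossvalAttention`.
#' @export
baselineCrossval <- function(sessions, ...)
  crossvalAttention(sessions, ..., baseline = TRUE)

#' @describeIn crossvalAttention per-fold results accessor
#' @param x a `CVResult`.
#' @export
cvFolds <- function(x) x@folds

setMethod("show", "CVResult", function(object) {
  f <- object@folds
  cat(sprintf("CVResult: %d held-out evaluations (k = %d), mean held-out rho = %.4f\n",
              nrow(f), object@k, mean(f$rhoHeldout, na.rm = TRUE)))
})

#' Compare cognitive and baseline cross-validated models
#'
#' One-way repeated-measures comparison of held-out correlation scores
#' with a fixed model factor (cognitive vs baseline) and subject
#' intercepts as the grouping term; folds missing in either model are
#' excluded listwise with a warning. A `"layered"` design additionally
#' expects `step` and `layer` columns (continuous covariates, as for a
#' model trained over steps and layers) with `sim` as the grouping unit.
#'
#' @param cvCog,cvBase [CVResult-class] objects (or data.frames in the
#'   layered design) with matched held-out folds.
#' @param design `"brain"` (subject grouping) or `"layered"`
#'   (simulation grouping with step and layer covariates).
#' @return data.frame with the model-effect F, df1, df2, p plus the
#'   per-model mean held-out scores.
#' @export
modelComparison <- function(cvCog, cvBase, design = c("brain", "layered")) {
  design <- match.arg(design)
  fc <- if (is(cvCog, "CVResult")) cvCog@folds else cvCog
  fb <- if (is(cvBase, "CVResult")) cvBase@folds else cvBase
  d <- rbind(fc, fb)
  if (anyNA(d$rhoHeldout)) {
    warning("dropping folds with missing held-out scores (listwise)")
    keyCols <- intersect(c("subject", "context", "fold", "sim", "step",
                           "layer"), names(d))
    key <- do.call(paste, c(d[keyCols], sep = "|"))
    badKeys <- unique(key[is.na(d$rhoHeldout)])
    d <- d[!(key %in% badKeys), ]
  }
  d$model <- factor(d$model, levels = c("baseline", "cognitive"))
  if (design == "brain") {
    fit <- stats::lm(rhoHeldout ~ subject + model, data = d)
  } else {
    fit <- stats::lm(rhoHeldout ~ sim + model * step * layer, data = d)
  }
  at <- suppressWarnings(stats::anova(fit))
  Fv <- at["model", "F value"]; pv <- at["model", "Pr(>F)"]
  if (at["model", "Sum Sq"] < 1e-20) { Fv <- 0; pv <- 1 }
  data.frame(F = Fv, df1 = at["model", "Df"],
             df2 = at["Residuals", "Df"], p = pv,
             meanCognitive = mean(d$rhoHeldout[d$model == "cognitive"]),
             meanBaseline = mean(d$rhoHeldout[d$model == "baseline"]))
}
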