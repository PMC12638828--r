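# Stacked LSTM task classifier, written against base matrix ops: a small
# trainable recurrent stack over fixed per-frame features, a two-stage
# linear readout with softmax, cross-entropy loss, Adam, trial-by-trial
# updates (batch size 1), full backprop through time.

.classLevels <- c("L", "R", "N")

sigmoid <- function(x) 1 / (1 + exp(-x))

# parameter initialisation: uniform +/- 1/sqrt(fan-in), forget-gate bias 1
lstmInit <- function(d, config, seed) {
  h <- config$hidden; L <- config$layers
  ht <- config$ht; m <- config$classes
  withSeed(seed, {
    p <- list()
    din <- d
    for (l in seq_len(L)) {
      s <- 1 / sqrt(din)
      p[[paste0("W", l)]] <- matrix(stats::runif(din * 4 * h, -s, s), din, 4 * h)
      s <- 1 / sqrt(h)
      p[[paste0("U", l)]] <- matrix(stats::runif(h * 4 * h, -s, s), h, 4 * h)
      b <- numeric(4 * h); b[(h + 1):(2 * h)] <- 1
      p[[paste0("b", l)]] <- b
      din <- h
    }
    s <- 1 / sqrt(h)
    p$Wo1 <- matrix(stats::runif(h * ht, -s, s), h, ht)
    p$bo1 <- numeric(ht)
    s <- 1 / sqrt(ht)
    p$Wo2 <- matrix(stats::runif(ht * m, -s, s), ht, m)
    p$bo2 <- numeric(m)
    p
  })
}

# forward pass over one trial; returns per-layer caches, per-frame class
# probabilities and the cross-entropy loss against labelIdx (if given)
lstmForward <- function(params, X, config, labelIdx = NULL) {
  L <- config$layers; h <- config$hidden
  Tn <- nrow(X)
  caches <- vector("list", L)
  input <- X
  for (l in seq_len(L)) {
    A <- input %*% params[[paste0("W", l)]]
    A <- sweep(A, 2, params[[paste0("b", l)]], "+")
    U <- params[[paste0("U", l)]]
    I <- F_ <- O <- G <- C <- Th <- H <- matrix(0, Tn, h)
    hprev <- numeric(h); cprev <- numeric(h)
    i1 <- 1:h; i2 <- (h + 1):(2 * h); i3 <- (2 * h + 1):(3 * h)
    i4 <- (3 * h + 1):(4 * h)
    for (t in seq_len(Tn)) {
      a <- A[t, ] + drop(hprev %*% U)
      i <- sigmoid(a[i1]); f <- sigmoid(a[i2])
      o <- sigmoid(a[i3]); g <- tanh(a[i4])
      cc <- f * cprev + i * g
      th <- tanh(cc)
      hh <- o * th
      I[t, ] <- i; F_[t, ] <- f; O[t, ] <- o; G[t, ] <- g
      C[t, ] <- cc; Th[t, ] <- th; H[t, ] <- hh
      hprev <- hh; cprev <- cc
    }
    caches[[l]] <- list(X = input, I = I, F = F_, O = O, G = G, C = C,
                        Th = Th, H = H)
    input <- H
  }
  U1 <- sweep(input %*% params$Wo1, 2, params$bo1, "+")
  logits <- sweep(U1 %*% params$Wo2, 2, params$bo2, "+")
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  loss <- NA_real_
  if (!is.null(labelIdx)) {
    loss <- if (config$lossMode == "final") -log(P[Tn, labelIdx])
            else mean(-log(P[, labelIdx]))
  }
  list(caches = caches, U1 = U1, P = P, loss = loss)
}

lstmBackward <- function(params, fwd, X, config, labelIdx) {
  L <- config$layers; h <- config$hidden
  Tn <- nrow(X); m <- config$classes
  P <- fwd$P
  Y <- matrix(0, Tn, m); Y[, labelIdx] <- 1
  dLogits <- if (config$lossMode == "final") {
    d <- matrix(0, Tn, m); d[Tn, ] <- P[Tn, ] - Y[Tn, ]; d
  } else (P - Y) / Tn
  Htop <- fwd$caches[[L]]$H
  g <- list()
  g$Wo2 <- t(fwd$U1) %*% dLogits
  g$bo2 <- colSums(dLogits)
  dU1 <- dLogits %*% t(params$Wo2)
  g$Wo1 <- t(Htop) %*% dU1
  g$bo1 <- colSums(dU1)
  dH <- dU1 %*% t(params$Wo1)
  i1 <- 1:h; i2 <- (h + 1):(2 * h); i3 <- (2 * h + 1):(3 * h)
  i4 <- (3 * h + 1):(4 * h)
  for (l in rev(seq_len(L))) {
    cc <- fwd$caches[[l]]
    U <- params[[paste0("U", l)]]
    dA <- matrix(0, Tn, 4 * h)
    dhNext <- numeric(h); dc <- numeric(h)
    for (t in rev(seq_len(Tn))) {
      dh <- dH[t, ] + dhNext
      o <- cc$O[t, ]; th <- cc$Th[t, ]; i <- cc$I[t, ]
      f <- cc$F[t, ]; gg <- cc$G[t, ]
      cprev <- if (t > 1L) cc$C[t - 1L, ] else numeric(h)
      do_ <- dh * th
      dc <- dc + dh * o * (1 - th^2)
      di <- dc * gg; df <- dc * cprev; dg <- dc * i
      da <- c(di * i * (1 - i), df * f * (1 - f), do_ * o * (1 - o),
              dg * (1 - gg^2))
      dA[t, ] <- da
      dhNext <- drop(da %*% t(U))
      dc <- dc * f
    }
    Hshift <- rbind(numeric(h), cc$H[-Tn, , drop = FALSE])
    g[[paste0("W", l)]] <- t(cc$X) %*% dA
    g[[paste0("U", l)]] <- t(Hshift) %*% dA
    g[[paste0("b", l)]] <- colSums(dA)
    dH <- dA %*% t(params[[paste0("W", l)]])
  }
  g
}

adamInit <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, clip = Inf) {
  nrm <- sqrt(sum(vapply(grads, function(x) sum(x^2), numeric(1))))
  if (is.finite(clip) && nrm > clip)
    grads <- lapply(grads, function(x) x * (clip / nrm))
  state$t <- state$t + 1L
  corr1 <- 1 - 0.9^state$t; corr2 <- 1 - 0.999^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

#' Train the stacked recurrent task classifier
#'
#' Trial-by-trial (batch size 1) training with cross-entropy loss and
#' Adam, fully seeded. The model is evaluated on `evalData` after every
#' epoch; the parameters achieving the best held-out micro-F1 across
#' checkpoints are retained.
#'
#' @param data training set from [prepareTrialData()].
#' @param config a [taskConfig()].
#' @param seed seed for initialisation and epoch shuffling.
#' @param epochs training epochs.
#' @param evalData optional held-out set from [prepareTrialData()] used
#'   for checkpoints.
#' @param evalEvery checkpoint spacing in training steps; `NULL` evaluates
#'   at the end of every epoch.
#' @return a [TaskModel-class] with the best-checkpoint parameters, the
#'   per-trial loss trace and the checkpoint table.
#' @export
trainTaskModel <- function(data, config = taskConfig(), seed = 1L,
                           epochs = 10L, evalData = NULL,
                           evalEvery = NULL) {
  labels <- match(data$meta$label, .classLevels)
  if (length(unique(labels)) < length(.classLevels))
    stop("training set must contain all three labels (L, R, N)")
  d <- ncol(data$features[[1]])
  params <- lstmInit(d, config, mixSeed(seed, "init"))
  state <- adamInit(params)
  lossTrace <- numeric(0)
  checkpoints <- data.frame(epoch = integer(0), step = integer(0),
                            f1 = numeric(0))
  best <- list(params = params, f1 = -Inf)
  step <- 0L
  checkpoint <- function(ep) {
    f1 <- microF1(predictWithParams(params, evalData, config),
                  evalData$meta$label)
    checkpoints <<- rbind(checkpoints,
                          data.frame(epoch = ep, step = step, f1 = f1))
    if (f1 > best$f1) best <<- list(params = params, f1 = f1)
  }
  decayEpochs <- config$lrDecayEpochs
  if (is.null(decayEpochs)) decayEpochs <- integer(0)
  decayFactor <- if (is.null(config$lrDecayFactor)) 1 else config$lrDecayFactor
  for (ep in seq_len(epochs)) {
    lrEp <- config$lr * decayFactor^sum(ep >= decayEpochs)
    ord <- withSeed(mixSeed(seed, "epoch", ep),
                    sample(seq_along(data$features)))
    epLoss <- numeric(length(ord))
    for (k in seq_along(ord)) {
      i <- ord[k]
      X <- data$features[[i]]
      fwd <- lstmForward(params, X, config, labels[i])
      if (!is.finite(fwd$loss))
        stop("non-finite loss at step ", step, "; lower the learning rate")
      grads <- lstmBackward(params, fwd, X, config, labels[i])
      upd <- adamStep(params, grads, state, lrEp, clip = config$clip)
      params <- upd$params; state <- upd$state
      epLoss[k] <- fwd$loss
      step <- step + 1L
      if (!is.null(evalData) && !is.null(evalEvery) &&
          step %% evalEvery == 0L)
        checkpoint(ep)
    }
    lossTrace <- c(lossTrace, epLoss)
    if (!is.null(evalData) && is.null(evalEvery)) checkpoint(ep)
  }
  if (!is.null(evalData) && !is.null(evalEvery) &&
      step %% evalEvery != 0L) checkpoint(epochs)
  if (is.null(evalData)) best$params <- params
  new("TaskModel", params = best$params, config = unclass(config),
      lossTrace = lossTrace, checkpoints = checkpoints)
}

predictWithParams <- function(params, data, config) {
  vapply(data$features, function(X) {
    fwd <- lstmForward(params, X, config)
    .classLevels[which.max(fwd$P[nrow(X), ])]
  }, character(1))
}

#' Predict trial responses with a trained task model
#'
#' Classification is read from the trial-final output frame.
#'
#' @param model a [TaskModel-class].
#' @param data a trial set from [prepareTrialData()].
#' @return character vector of predicted labels (`L`, `R`, `N`).
#' @export
taskModelPredict <- function(model, data)
  predictWithParams(model@params, data, model@config)

setMethod("show", "TaskModel", function(object) {
  bestF1 <- if (nrow(object@checkpoints)) max(object@checkpoints$f1) else NA
  cat(sprintf("TaskModel: %d-layer LSTM (h = %d), %d training steps, best checkpoint F1 = %s\n",
              object@config$layers, object@config$hidden,
              length(object@lossTrace),
              ifelse(is.na(bestF1), "n/a", sprintf("%.3f", bestF1))))
})

#' Micro-averaged F1 score
#'
#' Pools true positives, false positives and false negatives across
#' classes to compute micro precision and recall, and returns their
#' harmonic mean. For single-label multiclass predictions this equals
#' accuracy.
#'
#' @param predictions,labels equal-length character vectors over
#'   `c("L", "R", "N")`.
#' @return score in `[0, 1]`.
#' @examples
#' microF1(c("L", "R", "N", "L"), c("L", "R", "N", "R"))  # 0.75
#' @export
microF1 <- function(predictions, labels) {
  if (!length(predictions) || length(predictions) != length(labels))
    stop("predictions and labels must be equal-length and non-empty")
  tp <- fp <- fn <- 0
  for (cl in unique(c(predictions, labels))) {
    tp <- tp + sum(predictions == cl & labels == cl)
    fp <- fp + sum(predictions == cl & labels != cl)
    fn <- fn + sum(predictions != cl & labels == cl)
  }
  P <- tp / (tp + fp); R <- tp / (tp + fn)
  if (!is.finite(P) || !is.finite(R) || (P + R) == 0) return(0)
  2 * P * R / (P + R)
}

#' Per-layer RDMs from the recurrent model's hidden states
#'
#' Runs the trained model over test trials, averages each layer's hidden
#' state over the frames that the LSTM-time mapping assigns to the
#' requested bin (counted from stimulus onset), and builds one 16 x 16
#' RDM per layer and context from the mean pairwise Euclidean (or cosine)
#' distance between cross-trial stimulus representations. In `"sliding"`
#' mode the bin advances one frame per step.
#'
#' @param model a [TaskModel-class].
#' @param data test trials from [prepareTrialData()].
#' @param stimset the stimulus set (ambiguous stimuli are excluded).
#' @param timing `"whole"` (one bin covering `period`) or `"sliding"`.
#' @param period numeric(2) analysis period in seconds for whole-bin mode.
#' @param binWidth sliding bin width in seconds.
#' @param measure `"euclidean"` or `"cosine"`.
#' @return `"whole"`: nested list `layer -> context -> RDM`;
#'   `"sliding"`: list per start frame of such nested lists, named by the
#'   bin start time in seconds.
#' @export
layerRDMs <- function(model, data, stimset = makeStimulusSet(),
                      timing = c("whole", "sliding"), period = c(0, 0.25),
                      binWidth = 0.05, measure = c("euclidean", "cosine")) {
  timing <- match.arg(timing)
  measure <- match.arg(measure)
  config <- model@config
  L <- config$layers
  onset <- config$framesFix + config$framesCue
  H <- lapply(data$features, function(X)
    lapply(lstmForward(model@params, X, config)$caches, `[[`, "H"))
  ids <- analyzedStimuli(stimset)
  keep <- which(data$meta$stimulusId %in% ids)
  binRdms <- function(frameIdx, tag) {
    out <- list()
    for (l in seq_len(L)) {
      byCtx <- list()
      for (cx in unique(data$meta$context[keep])) {
        rows <- keep[data$meta$context[keep] == cx]
        reps <- t(vapply(rows, function(i)
          colMeans(H[[i]][[l]][frameIdx, , drop = FALSE]),
          numeric(config$hidden)))
        dm <- if (measure == "euclidean") as.matrix(stats::dist(reps))
              else 1 - crossprod(t(reps / sqrt(rowSums(reps^2) + 1e-12)))
        stim <- factor(data$meta$stimulusId[rows], levels = ids)
        m <- matrix(NA_real_, length(ids), length(ids),
                    dimnames = list(ids, ids))
        for (a in seq_along(ids)) for (b in seq_len(a)) {
          ra <- which(stim == ids[a]); rb <- which(stim == ids[b])
          if (!length(ra) || !length(rb)) next
          v <- if (a == b) 0 else mean(dm[ra, rb])
          m[a, b] <- v; m[b, a] <- v
        }
        byCtx[[cx]] <- rdm(m, ids = ids,
                           measure = paste0("lstm-", measure),
                           context = cx, source = tag)
      }
      out[[paste0("layer", l)]] <- byCtx
    }
    out
  }
  nWhole <- min(lstmFrameCount(diff(period), config$frameRate),
                config$framesStim)
  if (timing == "whole")
    return(binRdms(onset + seq_len(nWhole), "whole-period"))
  nBin <- min(lstmFrameCount(binWidth, config$frameRate), config$framesStim)
  starts <- 0:(config$framesStim - nBin)
  out <- lapply(starts, function(s)
    binRdms(onset + s + seq_len(nBin), sprintf("bin@%d", s)))
  names(out) <- sprintf("%.3f", starts / config$frameRate)
  out
}
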