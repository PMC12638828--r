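#' Spearman comparison of two RDMs
#'
#' Spearman rank correlation over the off-diagonal upper-triangle cells
#' (120 for 16 stimuli), excluding cells missing in either RDM; ties get
#' average ranks. Being rank-based, the comparison is invariant to any
#' strictly increasing transform of either RDM's entries.
#'
#' @param r1,r2 [RDM-class] objects with identical stimulus ordering.
#' @return an [RSAResult-class] with the correlation and cell count.
#' @examples
#' E <- referenceRDM(makeStimulusSet())
#' rsaRho(rsaSpearman(E, E))  # 1
#' @export
rsaSpearman <- function(r1, r2) {
  if (length(r1@ids) != length(r2@ids) || !all(r1@ids == r2@ids))
    stop("RDMs must share one stimulus ordering")
  s <- spearmanVec(upperCells(r1@mat), upperCells(r2@mat))
  new("RSAResult", rho = s$rho, nCells = s$n,
      window = r1@window, measure = paste(r1@measure, "vs", r2@measure))
}

#' @describeIn rsaSpearman extract the correlation from an RSAResult
#' @param x an `RSAResult`.
#' @export
rsaRho <- function(x) x@rho

setMethod("show", "RSAResult", function(object) {
  cat(sprintf("RSA: Spearman rho = %.4f over %d cells (%s)\n",
              object@rho, object@nCells, object@measure))
})

#' Time-resolved RSA with a sliding window
#'
#' Builds one RDM per session per sliding window and Spearman-compares it
#' to a reference geometry; summarises with the across-session mean and a
#' t-based 95% confidence interval per window.
#'
#' @param sessions list of [SessionRecording-class] objects.
#' @param reference reference [RDM-class].
#' @param measure dissimilarity measure (see [buildSessionRDM()]).
#' @param width window width in seconds (default 0.05).
#' @param step window step in seconds (default 0.01).
#' @param startRange numeric(2) inclusive range of window starts.
#' @param context restrict each session to this context (`NULL`: all).
#' @param ... passed on to [buildSessionRDM()] (`cap`, `seed`, `stimset`,
#'   `rateSites`).
#' @return list with `perSession` (long data.frame: session, windowStart,
#'   rho) and `summary` (windowStart, mean, lo, hi, n). Windows where a
#'   session yields too few comparable cells are propagated as `NA`.
#' @export
slidingWindowRSA <- function(sessions, reference, measure = "ISI",
                             width = 0.05, step = 0.01,
                             startRange = c(-0.05, 0.21), context = NULL,
                             ...) {
  starts <- slidingWindowStarts(startRange, step)
  if (!length(starts)) stop("empty window set")
  rows <- list()
  for (k in seq_along(sessions)) {
    sess <- sessions[[k]]
    for (s0 in starts) {
      r <- tryCatch({
        m <- buildSessionRDM(sess, measure = measure,
                             window = c(s0, s0 + width),
                             context = context, ...)
        rsaRho(rsaSpearman(m, reference))
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(session = sess@session, windowStart = s0, rho = r,
                   stringsAsFactors = FALSE)
    }
  }
  perSession <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(perSession, perSession$windowStart),
                                function(d) {
    ci <- tCI95(d$rho)
    data.frame(windowStart = d$windowStart[1], mean = ci[["mean"]],
               lo = ci[["lo"]], hi = ci[["hi"]], n = ci[["n"]])
  }))
  rownames(summ) <- NULL
  list(perSession = perSession, summary = summ[order(summ$windowStart), ])
}

#' Compare candidate dissimilarity measures by RSA
#'
#' Scores every candidate measure by the Spearman correlation between each
#' session's RDM and the reference geometry over the analysis period, then
#' tests for a measure effect with a one-way ANOVA and Bonferroni-corrected
#' two-tailed paired t-tests.
#'
#' @param sessions list of [SessionRecording-class] objects (>= 2).
#' @param reference reference [RDM-class].
#' @param measures character vector of candidate measures.
#' @param window analysis window (default the 0-0.25 s whole period).
#' @param context restrict to this context (`NULL`: all).
#' @param ... passed to [buildSessionRDM()].
#' @return list with `scores` (session, measure, rho), `anova`
#'   (data.frame with F, df1, df2, p), and `pairwise` (the
#'   [stats::pairwise.t.test()] result, paired, Bonferroni).
#' @export
measureComparison <- function(sessions, reference, measures = validMeasures,
                              window = c(0, 0.25), context = NULL, ...) {
  if (length(sessions) < 2L) stop("need at least 2 sessions")
  rows <- list()
  for (sess in sessions)
    for (m in measures) {
      r <- tryCatch({
        x <- buildSessionRDM(sess, measure = m, window = window,
                             context = context, ...)
        rsaRho(rsaSpearman(x, reference))
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(session = sess@session, measure = m, rho = r,
                   stringsAsFactors = FALSE)
    }
  scores <- do.call(rbind, rows)
  scores$measure <- factor(scores$measure, levels = measures)
  fit <- stats::aov(rho ~ measure, data = scores)
  at <- stats::anova(fit)
  if (at[1, "Sum Sq"] < 1e-20) { # identical scores: F indistinguishable from 0
    Fv <- 0; pv <- 1
  } else {
    Fv <- at[1, "F value"]; pv <- at[1, "Pr(>F)"]
  }
  pw <- stats::pairwise.t.test(scores$rho, scores$measure, paired = TRUE,
                               p.adjust.method = "bonferroni",
                               alternative = "two.sided")
  list(scores = scores,
       anova = data.frame(F = Fv, df1 = at[1, "Df"], df2 = at[2, "Df"],
                          p = pv),
       pairwise = pw)
}

#' Region-by-layer alignment of brain and model geometries
#'
#' Spearman-correlates every (region, context) brain RDM with every
#' (simulation, layer, context) model RDM, and tests the region x task
#' interaction with an ANCOVA on the correlations (fixed factors region,
#' task, continuous layer, full factorial; simulation intercepts as the
#' grouping term).
#'
#' @param brainRdms nested named list: `region -> context -> RDM` (a
#'   missing context yields missing grid cells).
#' @param modelRdms nested named list:
#'   `simulation -> layer -> context -> RDM`.
#' @return list with `long` (region, layer, context, sim, rho), `grid`
#'   (region x layer x context array of across-simulation means), and
#'   `interaction` (data.frame F, df1, df2, p for region x task).
#' @export
alignmentMatrix <- function(brainRdms, modelRdms) {
  regions <- names(brainRdms)
  sims <- names(modelRdms)
  layers <- names(modelRdms[[1]])
  contexts <- unique(unlist(lapply(brainRdms, names)))
  rows <- list()
  for (rg in regions) for (sim in sims) for (ly in layers)
    for (cx in contexts) {
      b <- brainRdms[[rg]][[cx]]
      m <- modelRdms[[sim]][[ly]][[cx]]
      r <- if (is.null(b) || is.null(m)) NA_real_
           else tryCatch(rsaRho(rsaSpearman(b, m)), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, layer = match(ly, layers), context = cx,
                   sim = sim, rho = r, stringsAsFactors = FALSE)
    }
  long <- do.call(rbind, rows)
  grid <- tapply(long$rho, list(region = long$region,
                                layer = factor(long$layer),
                                context = long$context),
                 mean, na.rm = TRUE)
  d <- long[!is.na(long$rho), ]
  interaction <- data.frame(F = NA_real_, df1 = NA_integer_,
                            df2 = NA_integer_, p = NA_real_)
  if (nrow(d) > 8L && length(unique(d$region)) > 1L &&
      length(unique(d$context)) > 1L) {
    d$region <- factor(d$region); d$task <- factor(d$context)
    d$sim <- factor(d$sim)
    form <- if (nlevels(d$sim) > 1L)
      rho ~ sim + region * task * layer else rho ~ region * task * layer
    at <- stats::anova(stats::lm(form, data = d))
    row <- "region:task"
    interaction <- data.frame(F = at[row, "F value"], df1 = at[row, "Df"],
                              df2 = at["Residuals", "Df"],
                              p = at[row, "Pr(>F)"])
  }
  list(long = long, grid = grid, interaction = interaction)
}
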