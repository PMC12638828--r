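#' Long table of mismatch-pair dissimilarities by context
#'
#' Pulls, for every mismatch pair of both dimensions, the RDM entry in
#' each task context for each grouping unit (subject, simulation or
#' layer). Rows whose RDM cell is missing are dropped and counted.
#'
#' @param rdms nested named list `unit -> context -> RDM` (or, for the
#'   layered design, `unit -> layer -> context -> RDM`).
#' @param stimset the [StimulusSet-class].
#' @return data.frame of class `stretchingTable` with columns `unit`
#'   (+ `layer` when nested), `context`, `dimension`, `pair`,
#'   `dissimilarity`; attribute `nDropped` counts missing cells.
#' @export
stretchingTable <- function(rdms, stimset = makeStimulusSet()) {
  pairs <- rbind(mismatchPairs(stimset, "color"),
                 mismatchPairs(stimset, "motion"))
  rows <- list(); dropped <- 0L
  pull <- function(unit, layer, byContext) {
    for (cx in names(byContext)) {
      m <- byContext[[cx]]@mat
      for (p in seq_len(nrow(pairs))) {
        v <- m[pairs$id1[p], pairs$id2[p]]
        if (is.na(v)) { dropped <<- dropped + 1L; next }
        rows[[length(rows) + 1L]] <<- data.frame(
          unit = unit, layer = layer, context = cx,
          dimension = pairs$dimension[p],
          pair = paste(pairs$id1[p], pairs$id2[p], sep = "-"),
          dissimilarity = v, stringsAsFactors = FALSE)
      }
    }
  }
  layered <- !is(rdms[[1]][[1]], "RDM")
  for (unit in names(rdms)) {
    if (layered) {
      for (ly in names(rdms[[unit]]))
        pull(unit, match(ly, names(rdms[[unit]])), rdms[[unit]][[ly]])
    } else pull(unit, NA_integer_, rdms[[unit]])
  }
  out <- do.call(rbind, rows)
  if (!layered) out$layer <- NULL
  attr(out, "nDropped") <- dropped
  class(out) <- c("stretchingTable", "data.frame")
  out
}

#' Model-free dimensional-stretching test
#'
#' Tests whether dissimilarity between mismatch pairs is greatest when the
#' mismatching dimension is task relevant. Reports (a) two-tailed paired t
#' statistics for the per-dimension task contrasts
#' `D_color^color - D_color^motion` and `D_motion^motion - D_motion^color`
#' (paired over pair x unit cells), and (b) the task x mismatch-dimension
#' interaction from a repeated-measures-style linear model with unit,
#' unit x task (session-level) and pair intercepts (`"brain"` design), or
#' the three-way
#' task x dimension x layer interaction with a continuous layer covariate
#' (`"layered"` design). Stretching is declared when the interaction is
#' significant with dissimilarity greatest for task-relevant mismatches.
#'
#' @param table a [stretchingTable()] (>= 2 grouping units).
#' @param design `"brain"` or `"layered"`.
#' @return list with `contrasts` (per-dimension paired t data.frame),
#'   `interaction` (F, df1, df2, p), `stretching` (logical: significant
#'   interaction in the stretching direction at 5%), and the fitted model.
#' @export
stretchingTest <- function(table, design = c("brain", "layered")) {
  design <- match.arg(design)
  d <- as.data.frame(table)
  if (length(unique(d$unit)) < 2L)
    stop("need >= 2 grouping units")
  d$relevant <- ifelse(d$context == d$dimension, "relevant", "irrelevant")
  contrasts <- do.call(rbind, lapply(c("color", "motion"), function(dim) {
    sub <- d[d$dimension == dim, ]
    aggCols <- c("pair", "unit", if ("layer" %in% names(d)) "layer")
    wide <- merge(
      stats::aggregate(sub[sub$context == dim, "dissimilarity",
                           drop = FALSE],
                       sub[sub$context == dim, aggCols, drop = FALSE], mean),
      stats::aggregate(sub[sub$context != dim, "dissimilarity",
                           drop = FALSE],
                       sub[sub$context != dim, aggCols, drop = FALSE], mean),
      by = aggCols, suffixes = c(".rel", ".irr"))
    diff <- wide$dissimilarity.rel - wide$dissimilarity.irr
    if (stats::sd(diff) == 0) {
      data.frame(dimension = dim, t = 0, df = length(diff) - 1L, p = 1,
                 meanDiff = mean(diff))
    } else {
      tt <- stats::t.test(diff)
      data.frame(dimension = dim, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 meanDiff = mean(diff))
    }
  }))
  d$task <- factor(d$context); d$dim <- factor(d$dimension)
  d$unit <- factor(d$unit); d$pair <- factor(d$pair)
  # unit x task intercepts absorb session-level shifts; pair intercepts
  # absorb the geometric spread between pairs
  form <- if (design == "brain")
    dissimilarity ~ unit * task + pair + task * dim
  else dissimilarity ~ unit * task + pair + task * dim * layer
  fit <- stats::lm(form, data = d)
  at <- suppressWarnings(stats::anova(fit))
  row <- if (design == "brain") "task:dim" else "task:dim:layer"
  Fv <- at[row, "F value"]; pv <- at[row, "Pr(>F)"]
  if (!is.finite(Fv) || at[row, "Sum Sq"] < 1e-20) { Fv <- 0; pv <- 1 }
  interaction <- data.frame(F = Fv, df1 = at[row, "Df"],
                            df2 = at["Residuals", "Df"], p = pv)
  rightSign <- mean(contrasts$meanDiff) > 0
  list(contrasts = contrasts, interaction = interaction,
       stretching = isTRUE(pv < 0.05 && rightSign), model = fit)
}
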