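#' The cued color/motion stimulus set
#'
#' Builds the 21-stimulus set: 16 analysed stimuli tiling the 4x4
#' (color, motion) grid plus 5 ambiguous stimuli at or near the origin of
#' the color-motion space, labelled `N` in both contexts. Grid coordinate
#' `g` on a dimension maps to step `c(1, 2, 6, 7)[g]` of the underlying
#' 7-step physical axis, so analysed stimuli sit in the four quadrants and
#' ambiguous stimuli occupy the boundary steps 3-5. Response labels per
#' context split the relevant dimension at the boundary: coordinates 1-2
#' map to `L` (greenish color / upward motion), 3-4 to `R`.
#'
#' @return a [StimulusSet-class] with 21 stimuli.
#' @examples
#' ss <- makeStimulusSet()
#' nrow(stimulusCoords(ss))            # 21
#' sum(!stimulusCoords(ss)$ambiguous)  # 16 analysed
#' @export
makeStimulusSet <- function() {
  gridStep <- c(1L, 2L, 6L, 7L)
  g <- expand.grid(colorCoord = 1:4, motionCoord = 1:4)
  grid <- data.frame(
    stimulusId = sprintf("s%02d", seq_len(16L)),
    colorCoord = g$colorCoord, motionCoord = g$motionCoord,
    colorStep = gridStep[g$colorCoord], motionStep = gridStep[g$motionCoord],
    ambiguous = FALSE,
    labelColor = ifelse(g$colorCoord <= 2L, "L", "R"),
    labelMotion = ifelse(g$motionCoord <= 2L, "L", "R"),
    stringsAsFactors = FALSE)
  ambSteps <- rbind(c(4L, 4L), c(3L, 4L), c(5L, 4L), c(4L, 3L), c(4L, 5L))
  amb <- data.frame(
    stimulusId = sprintf("s%02d", 16L + seq_len(5L)),
    colorCoord = NA_integer_, motionCoord = NA_integer_,
    colorStep = ambSteps[, 1L], motionStep = ambSteps[, 2L],
    ambiguous = TRUE, labelColor = "N", labelMotion = "N",
    stringsAsFactors = FALSE)
  new("StimulusSet", stimuli = rbind(grid, amb))
}

#' @describeIn makeStimulusSet stimulus table accessor
#' @param x a `StimulusSet`.
#' @export
stimulusCoords <- function(x) x@stimuli

#' @describeIn makeStimulusSet ids of the 16 analysed (non-ambiguous)
#'   stimuli, in canonical RDM order
#' @export
analyzedStimuli <- function(x) x@stimuli$stimulusId[!x@stimuli$ambiguous]

setMethod("show", "StimulusSet", function(object) {
  s <- object@stimuli
  cat(sprintf("StimulusSet: %d stimuli (%d analysed on the 4x4 grid, %d ambiguous)\n",
              nrow(s), sum(!s$ambiguous), sum(s$ambiguous)))
})

# grid coordinate matrix (color, motion) for the analysed stimuli, rows
# named by stimulus id
analyzedGrid <- function(stimset) {
  s <- stimset@stimuli[!stimset@stimuli$ambiguous, ]
  m <- cbind(color = s$colorCoord, motion = s$motionCoord)
  rownames(m) <- s$stimulusId
  m
}

#' Mismatch stimulus pairs along one dimension
#'
#' All unordered pairs of analysed stimuli that share their coordinate on
#' the other dimension and differ (by any amount) on `dimension`. On the
#' full 4x4 grid each dimension yields 4 shared values x choose(4, 2) = 24
#' pairs, and the color- and motion-mismatch sets are disjoint.
#'
#' @param stimset a [StimulusSet-class].
#' @param dimension `"color"` or `"motion"`: the mismatching dimension.
#' @return data.frame with columns `id1`, `id2`, `dimension`.
#' @export
mismatchPairs <- function(stimset, dimension = c("color", "motion")) {
  dimension <- match.arg(dimension)
  grid <- analyzedGrid(stimset)
  nc <- length(unique(grid[, "color"])); nm <- length(unique(grid[, "motion"]))
  if (nrow(grid) != nc * nm || anyDuplicated(grid))
    stop("mismatch pairs require a complete non-ambiguous coordinate grid")
  other <- setdiff(c("color", "motion"), dimension)
  ids <- rownames(grid)
  out <- list()
  for (i in seq_len(nrow(grid) - 1L)) {
    for (j in seq(i + 1L, nrow(grid))) {
      if (grid[i, other] == grid[j, other] &&
          grid[i, dimension] != grid[j, dimension])
        out[[length(out) + 1L]] <- c(ids[i], ids[j])
    }
  }
  m <- do.call(rbind, out)
  data.frame(id1 = m[, 1L], id2 = m[, 2L], dimension = dimension,
             stringsAsFactors = FALSE)
}
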