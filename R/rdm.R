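#' Construct an RDM object
#'
#' @param mat square symmetric nonnegative matrix with zero diagonal;
#'   `NA` entries mark missing dissimilarities.
#' @param ids character stimulus ordering; defaults to rownames of `mat`.
#' @param measure,context,source character provenance fields.
#' @param window numeric(2) analysis window, or `NA`.
#' @return an [RDM-class].
#' @export
rdm <- function(mat, ids = rownames(mat), measure = "unknown",
                window = c(NA_real_, NA_real_), context = "none",
                source = "user") {
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  dimnames(mat) <- list(ids, ids)
  new("RDM", mat = mat, ids = as.character(ids), measure = measure,
      window = as.numeric(window), context = context, source = source)
}

#' @describeIn rdm dissimilarity matrix accessor
#' @param x an `RDM`.
#' @export
rdmMatrix <- function(x) x@mat

#' @describeIn rdm stimulus ordering accessor
#' @export
rdmIds <- function(x) x@ids

#' @describeIn rdm measure provenance accessor
#' @export
rdmMeasure <- function(x) x@measure

setMethod("show", "RDM", function(object) {
  nmiss <- sum(is.na(upperCells(object@mat)))
  cat(sprintf("RDM: %d x %d (%s, context %s), %d missing cells\n",
              nrow(object@mat), ncol(object@mat), object@measure,
              object@context, nmiss))
})

#' Plot an RDM as a heat map
#'
#' @param x an [RDM-class].
#' @param y ignored.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
setMethod("plot", signature(x = "RDM", y = "missing"),
          function(x, y, main = x@measure, ...) {
  m <- x@mat[, rev(seq_len(ncol(x@mat))), drop = FALSE]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m, main = main,
                  xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::axis(1, at = seq_along(x@ids), labels = x@ids, las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_along(x@ids), labels = rev(x@ids), las = 2,
                 cex.axis = 0.6)
  invisible(x)
})

#' Experimenter-intended reference geometry
#'
#' Pairwise dissimilarity of the analysed stimuli from their grid
#' coordinates: `E(a, b) = 1 - exp(-sqrt(|ax - bx|^2 + |ay - by|^2))`,
#' a strictly increasing transform of grid Euclidean distance.
#'
#' @param stimset a [StimulusSet-class] with the full 4x4 analysed grid.
#' @return an [RDM-class] over the 16 analysed stimuli.
#' @examples
#' E <- referenceRDM(makeStimulusSet())
#' rdmMatrix(E)["s01", "s05"]   # 1 - exp(-1)
#' @export
referenceRDM <- function(stimset) {
  grid <- analyzedGrid(stimset)
  if (anyDuplicated(grid)) stop("duplicate grid coordinates")
  d <- as.matrix(stats::dist(grid))
  m <- 1 - exp(-d)
  diag(m) <- 0
  rdm(m, ids = rownames(grid), measure = "reference", source = "grid")
}

#' Attention-weighted stimulus geometry
#'
#' Pairwise dissimilarity under an attention weight `w` on the relevant
#' dimension:
#' `AE(a, b) = 1 - exp(-c * sqrt(w * dRel^2 + (1 - w) * dIrr^2))`, where
#' `dRel`/`dIrr` are coordinate differences on the relevant/irrelevant
#' dimension. `w = 0.5` is a monotone transform of the reference geometry;
#' `w = 1` collapses the irrelevant dimension entirely.
#'
#' @param stimset a [StimulusSet-class].
#' @param w attention weight in `[0, 1]` on the relevant dimension.
#' @param c positive scale constant (irrelevant to rank-based comparison).
#' @param relevantDimension `"color"` or `"motion"`.
#' @return an [RDM-class] over the 16 analysed stimuli.
#' @export
attentionRDM <- function(stimset, w, c = 1,
                         relevantDimension = c("motion", "color")) {
  relevantDimension <- match.arg(relevantDimension)
  if (is.na(w) || w < 0 || w > 1)
    stop("attention weight w must lie in [0, 1]")
  if (c <= 0) stop("scale constant c must be positive")
  grid <- analyzedGrid(stimset)
  rel <- grid[, relevantDimension]
  irr <- grid[, setdiff(c("color", "motion"), relevantDimension)]
  dRel <- outer(rel, rel, "-")
  dIrr <- outer(irr, irr, "-")
  m <- 1 - exp(-c * sqrt(w * dRel^2 + (1 - w) * dIrr^2))
  diag(m) <- 0
  rdm(m, ids = rownames(grid),
      measure = sprintf("attention(w=%g,%s)", w, relevantDimension),
      context = "none", source = "model")
}

#' Write / read an RDM as CSV with a JSON metadata sidecar
#'
#' The matrix is written with stimulus ids as header row and column; the
#' sidecar `<file>.json` records measure, window, context and source.
#'
#' @param x an [RDM-class].
#' @param file CSV path.
#' @return `writeRDM` the file path invisibly; `readRDM` an [RDM-class].
#' @export
writeRDM <- function(x, file) {
  utils::write.csv(as.data.frame(x@mat), file, row.names = TRUE)
  meta <- list(measure = x@measure, window = x@window,
               context = x@context, source = x@source, ids = x@ids)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeRDM
#' @export
readRDM <- function(file) {
  m <- as.matrix(utils::read.csv(file, row.names = 1, check.names = FALSE))
  metaFile <- paste0(file, ".json")
  meta <- if (file.exists(metaFile)) jsonlite::read_json(metaFile,
                                                         simplifyVector = TRUE)
          else list(measure = "unknown", window = c(NA, NA),
                    context = "none", source = file)
  rdm(m, ids = rownames(m), measure = meta$measure,
      window = as.numeric(meta$window), context = meta$context,
      source = meta$source)
}
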