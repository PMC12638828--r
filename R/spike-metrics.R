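#' Construct a SpikeTrain
#'
#' @param times numeric spike times in seconds, strictly increasing.
#' @param window numeric(2) closed observation interval `c(t0, t1)`.
#' @return a [SpikeTrain-class] object.
#' @examples
#' spikeTrain(c(0.1, 0.35, 0.6), window = c(0, 1))
#' @export
spikeTrain <- function(times = numeric(0), window) {
  new("SpikeTrain", times = as.numeric(times), window = as.numeric(window))
}

#' @describeIn spikeTrain spike times accessor
#' @param x a `SpikeTrain`.
#' @export
spikeTimes <- function(x) x@times

#' @describeIn spikeTrain observation window accessor
#' @export
spikeWindow <- function(x) x@window

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes in [%g, %g] s\n",
              length(object@times), object@window[1], object@window[2]))
})

setMethod("length", "SpikeTrain", function(x) length(x@times))

#' Construct a TrialSiteMatrix
#'
#' @param trains named list of [SpikeTrain-class] objects (one per site);
#'   names are used as site ids when `sites` is missing.
#' @param sites optional character site ids.
#' @return a [TrialSiteMatrix-class].
#' @export
trialSiteMatrix <- function(trains, sites = names(trains)) {
  if (is.null(sites)) sites <- paste0("site", seq_along(trains))
  new("TrialSiteMatrix", trains = unname(trains), sites = as.character(sites))
}

setMethod("show", "TrialSiteMatrix", function(object) {
  cat(sprintf("TrialSiteMatrix: %d sites, window [%g, %g] s\n",
              length(object@sites), object@trains[[1]]@window[1],
              object@trains[[1]]@window[2]))
})

# restrict + augment: spikes outside the window are dropped, auxiliary
# spikes are inserted at both edges (an empty train becomes the two-edge
# train whose single interval spans the window)
augmentTimes <- function(times, t0, t1) {
  t <- times[times >= t0 & times <= t1]
  unique(c(t0, t, t1))
}

checkSharedWindow <- function(x, y) {
  if (any(abs(x@window - y@window) > 1e-12))
    stop("window mismatch: both trains must share the same observation window")
  if (!(x@window[1] < x@window[2])) stop("zero-length window")
  x@window
}

#' ISI dissimilarity profile of two spike trains
#'
#' Both trains are augmented with auxiliary spikes at the window edges. At
#' time `t` the instantaneous interspike interval `x_isi(t)` is the length
#' of the augmented-train interval containing `t`, and the profile value is
#' `|x_isi(t) - y_isi(t)| / max(x_isi(t), y_isi(t))`, piecewise constant
#' between the union of augmented spike times.
#'
#' @param x,y [SpikeTrain-class] objects sharing one window.
#' @return a [DissimilarityProfile-class] of kind `"ISI"`.
#' @seealso [isiDistance()], [spikeProfile()]
#' @export
isiProfile <- function(x, y) {
  w <- checkSharedWindow(x, y)
  xa <- augmentTimes(x@times, w[1], w[2])
  ya <- augmentTimes(y@times, w[1], w[2])
  u <- sort(unique(c(xa, ya)))
  mids <- (u[-1] + u[-length(u)]) / 2
  xisi <- isiAt(xa, mids)
  yisi <- isiAt(ya, mids)
  vals <- abs(xisi - yisi) / pmax(xisi, yisi)
  new("DissimilarityProfile", breakpoints = u,
      values = matrix(vals, ncol = 1L), kind = "ISI", window = w)
}

# interval length of the augmented train containing each time point
isiAt <- function(aug, t) {
  idx <- findInterval(t, aug, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(aug) - 1L)
  aug[idx + 1L] - aug[idx]
}

#' SPIKE dissimilarity profile of two spike trains
#'
#' For train `x` at time `t`, with bracketing augmented spikes
#' `tP <= t <= tF`, `dtP`/`dtF` are the distances from `tP`/`tF` to the
#' nearest spike of the other train, and
#' `S_x(t) = (dtP * (tF - t) + dtF * (t - tP)) / x_isi(t)`. The profile is
#' `S(t) = (S_x * y_isi + S_y * x_isi) / (2 * ((x_isi + y_isi)/2)^2)`,
#' piecewise linear between the union of augmented spike times.
#'
#' @inheritParams isiProfile
#' @return a [DissimilarityProfile-class] of kind `"SPIKE"` whose `values`
#'   matrix holds the profile at each segment's start and end.
#' @export
spikeProfile <- function(x, y) {
  w <- checkSharedWindow(x, y)
  xa <- augmentTimes(x@times, w[1], w[2])
  ya <- augmentTimes(y@times, w[1], w[2])
  u <- sort(unique(c(xa, ya)))
  ns <- length(u) - 1L
  vals <- matrix(0, ns, 2L)
  for (k in seq_len(ns)) {
    a <- u[k]; b <- u[k + 1L]
    xp <- xa[findInterval(a, xa, rightmost.closed = TRUE)]
    xf <- xa[findInterval(a, xa, rightmost.closed = TRUE) + 1L]
    yp <- ya[findInterval(a, ya, rightmost.closed = TRUE)]
    yf <- ya[findInterval(a, ya, rightmost.closed = TRUE) + 1L]
    dxp <- nearestDist(ya, xp); dxf <- nearestDist(ya, xf)
    dyp <- nearestDist(xa, yp); dyf <- nearestDist(xa, yf)
    vals[k, 1L] <- spikeValueAt(a, xp, xf, dxp, dxf, yp, yf, dyp, dyf)
    vals[k, 2L] <- spikeValueAt(b, xp, xf, dxp, dxf, yp, yf, dyp, dyf)
  }
  new("DissimilarityProfile", breakpoints = u, values = vals,
      kind = "SPIKE", window = w)
}

nearestDist <- function(v, s) min(abs(v - s))

spikeValueAt <- function(t, xp, xf, dxp, dxf, yp, yf, dyp, dyf) {
  xisi <- xf - xp; yisi <- yf - yp
  Sx <- (dxp * (xf - t) + dxf * (t - xp)) / xisi
  Sy <- (dyp * (yf - t) + dyf * (t - yp)) / yisi
  m <- (xisi + yisi) / 2
  (Sx * yisi + Sy * xisi) / (2 * m * m)
}

#' Evaluate a dissimilarity profile at arbitrary times
#'
#' Within a segment the ISI profile is constant and the SPIKE profile is
#' linearly interpolated between its segment endpoint values. At a
#' breakpoint the right-continuous (following-segment) value is returned.
#'
#' @param profile a [DissimilarityProfile-class].
#' @param t numeric evaluation times within the window.
#' @return numeric profile values.
#' @export
profileEval <- function(profile, t) {
  b <- profile@breakpoints
  idx <- findInterval(t, b, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(b) - 1L)
  if (profile@kind == "ISI") return(profile@values[idx, 1L])
  frac <- (t - b[idx]) / (b[idx + 1L] - b[idx])
  profile@values[idx, 1L] * (1 - frac) + profile@values[idx, 2L] * frac
}

#' Exact time average of a dissimilarity profile
#'
#' Piecewise-constant (ISI) segments contribute `value * length`;
#' piecewise-linear (SPIKE) segments contribute their trapezoid.
#'
#' @param profile a [DissimilarityProfile-class].
#' @return scalar time average over the window.
#' @export
profileAverage <- function(profile) {
  len <- diff(profile@breakpoints)
  v <- profile@values
  seg <- if (profile@kind == "ISI") v[, 1L] else (v[, 1L] + v[, 2L]) / 2
  sum(seg * len) / sum(len)
}

setMethod("show", "DissimilarityProfile", function(object) {
  cat(sprintf("%s dissimilarity profile: %d segments on [%g, %g] s, mean %.4g\n",
              object@kind, nrow(object@values), object@window[1],
              object@window[2], profileAverage(object)))
})

#' ISI-distance between two spike trains
#'
#' Exact time average of the ISI profile; lies in `[0, 1)`, is symmetric,
#' zero on identical trains, and invariant to global time translation.
#'
#' @inheritParams isiProfile
#' @return scalar dissimilarity.
#' @examples
#' w <- c(0, 10)
#' a <- spikeTrain(seq(0.5, 9.5, by = 1), w)
#' b <- spikeTrain(seq(1, 9, by = 2), w)
#' isiDistance(a, b)
#' @export
isiDistance <- function(x, y) {
  w <- checkSharedWindow(x, y)
  .cppBivariateDistance(x@times, y@times, w[1], w[2], 0L)
}

#' SPIKE-distance between two spike trains
#'
#' Exact time average of the piecewise-linear SPIKE profile; nonnegative
#' and zero iff the trains are identical.
#'
#' @inheritParams isiProfile
#' @return scalar dissimilarity.
#' @export
spikeDistance <- function(x, y) {
  w <- checkSharedWindow(x, y)
  .cppBivariateDistance(x@times, y@times, w[1], w[2], 1L)
}

validMeasures <- c("ISI", "SPIKE", "euclidean", "cosine", "pearson")

#' Multi-site dissimilarity between two trials
#'
#' Timing measures (`ISI`, `SPIKE`) take the unweighted mean over sites of
#' the bivariate distance restricted to `window`. Rate measures reduce each
#' trial to a per-site spike-count vector within `window` and compare the
#' two vectors by Euclidean distance, cosine distance (1 - cosine
#' similarity), or Pearson distance (1 - correlation). Cosine/Pearson on a
#' zero/constant count vector is undefined and returned as `NA`.
#'
#' @param a,b [TrialSiteMatrix-class] objects with matching site sets.
#' @param measure one of `"ISI"`, `"SPIKE"`, `"euclidean"`, `"cosine"`,
#'   `"pearson"`.
#' @param window numeric(2) analysis window within the trains' window;
#'   defaults to the full recording window.
#' @return scalar dissimilarity (possibly `NA` for undefined
#'   cosine/Pearson values).
#' @export
multisiteDistance <- function(a, b, measure = validMeasures, window = NULL) {
  measure <- match.arg(measure)
  if (length(a@sites) != length(b@sites) || !all(a@sites == b@sites))
    stop("site-set mismatch between trials")
  w0 <- a@trains[[1]]@window
  if (is.null(window)) window <- w0
  if (window[1] < w0[1] - 1e-12 || window[2] > w0[2] + 1e-12)
    stop("analysis window must lie within the recording window")
  if (measure %in% c("ISI", "SPIKE")) {
    kind <- if (measure == "ISI") 0L else 1L
    return(.cppPooledDistance(lapply(a@trains, spikeTimes),
                              lapply(b@trains, spikeTimes),
                              window[1], window[2], kind))
  }
  ca <- vapply(a@trains, function(s) countInWindow(s@times, window), numeric(1))
  cb <- vapply(b@trains, function(s) countInWindow(s@times, window), numeric(1))
  rateVectorDistance(ca, cb, measure)
}

countInWindow <- function(times, window)
  sum(times >= window[1] & times <= window[2])

rateVectorDistance <- function(ca, cb, measure) {
  switch(measure,
    euclidean = sqrt(sum((ca - cb)^2)),
    cosine = {
      na <- sqrt(sum(ca^2)); nb <- sqrt(sum(cb^2))
      if (na == 0 || nb == 0) NA_real_ else 1 - sum(ca * cb) / (na * nb)
    },
    pearson = {
      if (stats::sd(ca) == 0 || stats::sd(cb) == 0) NA_real_
      else 1 - stats::cor(ca, cb)
    })
}

#' Export a dissimilarity profile as two-column text
#'
#' Writes breakpoint/value rows (SPIKE segments contribute their two
#' endpoint values at the segment's endpoints) suitable for plotting.
#'
#' @param profile a [DissimilarityProfile-class].
#' @param file path of the output text file.
#' @return the file path, invisibly.
#' @export
exportProfile <- function(profile, file) {
  b <- profile@breakpoints
  n <- length(b) - 1L
  if (profile@kind == "ISI") {
    t <- as.vector(rbind(b[-length(b)], b[-1]))
    v <- rep(profile@values[, 1L], each = 2L)
  } else {
    t <- as.vector(rbind(b[-length(b)], b[-1]))
    v <- as.vector(t(profile@values))
  }
  utils::write.table(data.frame(time_s = t, value = v), file,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
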