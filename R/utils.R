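# internal utilities: local seeding, seed mixing, window bookkeeping

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically fold identifiers into a 31-bit seed. Character ids are
# folded bytewise so that seeds are reproducible across platforms.
mixSeed <- function(seed, ...) {
  ids <- list(...)
  s <- as.numeric(seed) %% 2147483647
  for (id in ids) {
    ks <- if (is.character(id)) as.numeric(utf8ToInt(paste(id, collapse = ""))) else as.numeric(id)
    for (k in ks) s <- (s * 69069 + k + 1) %% 2147483647
  }
  as.integer(s)
}

#' Sliding-window start times
#'
#' Enumerates the start times of analysis windows advanced by a fixed step
#' over an inclusive start range, robust to floating-point step accumulation.
#'
#' @param startRange numeric(2): first and last window start (s).
#' @param step step between window starts (s), default 0.01.
#' @return numeric vector of window starts.
#' @examples
#' length(slidingWindowStarts(c(-0.05, 0.21)))  # 27
#' length(slidingWindowStarts(c(0, 0.22)))      # 23
#' @export
slidingWindowStarts <- function(startRange, step = 0.01) {
  stopifnot(length(startRange) == 2L, step > 0,
            startRange[2] >= startRange[1])
  n <- floor((startRange[2] - startRange[1]) / step + 1e-9)
  startRange[1] + step * (0:n)
}

# Upper-triangle (off-diagonal) cell values of an RDM matrix, fixed order.
upperCells <- function(m) m[upper.tri(m)]

# Spearman rho between two numeric vectors with NA-pair exclusion.
# Returns list(rho, n). Ties get average ranks (stats::rank default).
spearmanVec <- function(a, b, minCells = 3L) {
  keep <- !(is.na(a) | is.na(b))
  n <- sum(keep)
  if (n < minCells)
    stop("insufficient data: fewer than ", minCells, " comparable cells")
  rho <- suppressWarnings(stats::cor(rank(a[keep]), rank(b[keep])))
  list(rho = rho, n = as.integer(n))
}

# t-based 95% confidence interval for a mean across sessions
tCI95 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  half <- stats::qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}
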