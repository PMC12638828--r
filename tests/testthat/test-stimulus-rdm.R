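ss <- makeStimulusSet()

test_that("stimulus set has the study's counts and grid structure", {
  s <- stimulusCoords(ss)
  expect_equal(nrow(s), 21L)
  expect_equal(sum(!s$ambiguous), 16L)
  expect_equal(sum(s$ambiguous), 5L)
  grid <- s[!s$ambiguous, c("colorCoord", "motionCoord")]
  # bijection onto {1..4} x {1..4}
  expect_equal(nrow(unique(grid)), 16L)
  expect_setequal(grid$colorCoord, 1:4)
  expect_setequal(grid$motionCoord, 1:4)
  amb <- s[s$ambiguous, ]
  expect_true(all(amb$labelColor == "N" & amb$labelMotion == "N"))
  # analysed labels split each relevant dimension in half
  expect_equal(sum(s$labelColor == "L"), 8L)
  expect_equal(sum(s$labelMotion == "R"), 8L)
})

test_that("mismatch pairs: 24 per dimension, disjoint, relabel invariant", {
  pm <- mismatchPairs(ss, "motion")
  pc <- mismatchPairs(ss, "color")
  expect_equal(nrow(pm), 24L)
  expect_equal(nrow(pc), 24L)
  key <- function(p) paste(pmin(p$id1, p$id2), pmax(p$id1, p$id2))
  expect_length(intersect(key(pm), key(pc)), 0L)
  # pairs share the matched coordinate and differ on the mismatching one
  g <- stimulusCoords(ss)
  rownames(g) <- g$stimulusId
  expect_true(all(g[pm$id1, "colorCoord"] == g[pm$id2, "colorCoord"]))
  expect_true(all(g[pm$id1, "motionCoord"] != g[pm$id2, "motionCoord"]))
  # relabeling stimuli while preserving coordinates preserves the pair set
  perm <- sample(21)
  s2 <- stimulusCoords(ss)
  s2$stimulusId <- s2$stimulusId[perm]
  ss2 <- new("StimulusSet", stimuli = s2)
  pm2 <- mismatchPairs(ss2, "motion")
  coordKey <- function(p, tab) {
    rownames(tab) <- tab$stimulusId
    apply(cbind(tab[p$id1, c("colorCoord", "motionCoord")],
                tab[p$id2, c("colorCoord", "motionCoord")]), 1,
          function(r) paste(sort(c(paste(r[1], r[2]), paste(r[3], r[4]))),
                            collapse = "|"))
  }
  expect_setequal(unname(coordKey(pm2, s2)),
                  unname(coordKey(pm, stimulusCoords(ss))))
})

test_that("mismatch pairs on a 2x2 subgrid give 2 pairs per dimension", {
  s <- stimulusCoords(ss)
  sub <- s[!s$ambiguous & s$colorCoord <= 2 & s$motionCoord <= 2, ]
  ss2 <- new("StimulusSet", stimuli = sub)
  expect_equal(nrow(mismatchPairs(ss2, "color")), 2L)
  expect_equal(nrow(mismatchPairs(ss2, "motion")), 2L)
  # incomplete grid rejected
  ss3 <- new("StimulusSet", stimuli = sub[-1, ])
  expect_error(mismatchPairs(ss3, "color"), "complete")
})

test_that("reference geometry follows the exponential grid distance", {
  E <- referenceRDM(ss)
  m <- rdmMatrix(E)
  expect_equal(unname(diag(m)), rep(0, 16))
  expect_equal(m, t(m))
  # adjacent pair (grid distance 1) and the far corner (sqrt 18)
  expect_equal(m["s01", "s05"], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(m["s01", "s16"], 1 - exp(-sqrt(18)), tolerance = 1e-12)
  # strictly monotone in grid Euclidean distance
  grid <- stimulusCoords(ss)[!stimulusCoords(ss)$ambiguous, ]
  d <- as.matrix(dist(grid[, c("colorCoord", "motionCoord")]))
  up <- upper.tri(m)
  expect_equal(order(m[up]), order(d[up]))
  dup <- stimulusCoords(ss)
  dup$motionCoord[2] <- dup$motionCoord[1]
  dup$colorCoord[2] <- dup$colorCoord[1]
  expect_error(referenceRDM(new("StimulusSet", stimuli = dup)))
})

test_that("attention geometry weights the relevant dimension", {
  # w = 1: pairs matching on the relevant dimension collapse to 0
  a1 <- rdmMatrix(attentionRDM(ss, 1, relevantDimension = "motion"))
  sameMotion <- mismatchPairs(ss, "color")  # motion matches within pairs
  for (k in seq_len(nrow(sameMotion)))
    expect_equal(a1[sameMotion$id1[k], sameMotion$id2[k]], 0)
  # relevant coordinates 1 vs 4 at w = 1, c = 1
  expect_equal(a1["s01", "s13"], 1 - exp(-3), tolerance = 1e-12)
  # w = 0.5 is a monotone transform of the reference geometry
  a5 <- attentionRDM(ss, 0.5, c = 2.3)
  expect_equal(rsaRho(rsaSpearman(a5, referenceRDM(ss))), 1)
  expect_error(attentionRDM(ss, 1.2), "\\[0, 1\\]")
  expect_error(attentionRDM(ss, 0.5, c = -1), "positive")
})

test_that("rsaSpearman ranks upper-triangle cells with NA exclusion", {
  E <- referenceRDM(ss)
  expect_equal(rsaRho(rsaSpearman(E, E)), 1)
  # strictly decreasing monotone transform of the off-diagonal entries
  m2 <- exp(-rdmMatrix(E)); diag(m2) <- 0
  dec <- rdm(m2, ids = rdmIds(E))
  expect_equal(rsaRho(rsaSpearman(E, dec)), -1)
  # 3-stimulus toy: off-diagonals (1,2,3) vs (2,1,3)
  t1 <- matrix(0, 3, 3); t1[upper.tri(t1)] <- c(1, 2, 3)
  t2 <- matrix(0, 3, 3); t2[upper.tri(t2)] <- c(2, 1, 3)
  r1 <- rdm(t1 + t(t1)); r2 <- rdm(t2 + t(t2))
  expect_equal(rsaRho(rsaSpearman(r1, r2)), 0.5)
  expect_equal(rsaSpearman(r1, r2)@nCells, 3L)
  # missing cells excluded from the comparison
  mNA <- rdmMatrix(E); mNA[1, 2] <- mNA[2, 1] <- NA
  rNA <- rdm(mNA, ids = rdmIds(E))
  expect_equal(rsaSpearman(rNA, E)@nCells, 119L)
  # invariance to strictly increasing transforms (rank-based)
  set.seed(7)
  for (k in 1:5) {
    v <- matrix(0, 16, 16)
    v[upper.tri(v)] <- runif(120); v <- v + t(v)
    rv <- rdm(v)
    tr <- rdm(1 - exp(-3 * v) + diag(0, 16))
    expect_equal(rsaRho(rsaSpearman(rdm(v, ids = rdmIds(E)), E)),
                 rsaRho(rsaSpearman(rdm(1 - exp(-3 * v) + diag(0, 16),
                                        ids = rdmIds(E)), E)),
                 tolerance = 1e-12)
  }
  # too few comparable cells
  few <- matrix(NA_real_, 16, 16); diag(few) <- 0
  few[1, 2] <- few[2, 1] <- 1; few[1, 3] <- few[3, 1] <- 2
  expect_error(rsaSpearman(rdm(few, ids = rdmIds(E)), E), "insufficient")
})

test_that("RDM objects validate and round-trip through CSV + sidecar", {
  m <- rdmMatrix(referenceRDM(ss))
  expect_error(rdm(m + diag(1, 16)), "diagonal")
  expect_error(rdm(-m), "nonnegative")
  bad <- m; bad[1, 2] <- bad[1, 2] + 1
  expect_error(rdm(bad), "symmetric")
  f <- tempfile(fileext = ".csv")
  r <- rdm(m, measure = "ISI", window = c(0, 0.25), context = "motion",
           source = "test")
  writeRDM(r, f)
  r2 <- readRDM(f)
  expect_equal(rdmMatrix(r2), rdmMatrix(r), tolerance = 1e-12)
  expect_equal(rdmMeasure(r2), "ISI")
  expect_equal(r2@context, "motion")
  expect_equal(r2@window, c(0, 0.25))
})
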