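ss <- makeStimulusSet()

test_that("grid search recovers exact and symmetric geometries", {
  # exact AE(0.8) data: rank orderings are piecewise-constant in w, so a
  # tied run of weights scores rho = 1; the fit returns its midpoint
  f <- fitAttention(attentionRDM(ss, 0.8), ss)
  expect_lte(abs(attentionWeight(f) - 0.8), 0.02)
  expect_equal(f@rho, 1)
  # reference geometry is the balanced case
  f5 <- fitAttention(referenceRDM(ss), ss)
  expect_equal(attentionWeight(f5), 0.5)
  # training rho is the grid maximum (exhaustive check)
  set.seed(12)
  m <- rdmMatrix(attentionRDM(ss, 0.3))
  n <- matrix(0, 16, 16); n[upper.tri(n)] <- rnorm(120, sd = 0.05)
  noisy <- rdm(pmax(m + n + t(n), 0) - diag(diag(pmax(m + n + t(n), 0))),
               ids = analyzedStimuli(ss))
  fit <- fitAttention(noisy, ss)
  all_rhos <- vapply(fit@grid, function(w)
    rsaRho(rsaSpearman(attentionRDM(ss, w), noisy)), numeric(1))
  expect_equal(fit@rho, max(all_rhos), tolerance = 1e-12)
  expect_true(all(all_rhos <= fit@rho + 1e-12))
})

test_that("fits are invariant to the scale constant c", {
  set.seed(3)
  for (rep in 1:3) {
    m <- matrix(0, 16, 16); m[upper.tri(m)] <- runif(120)
    x <- rdm(m + t(m), ids = analyzedStimuli(ss))
    ws <- vapply(c(0.5, 1, 2), function(cc)
      attentionWeight(fitAttention(x, ss, attentionModelSpec(c = cc))),
      numeric(1))
    # identical up to a possible half-grid-step shift of a tied-run edge
    # (float rank collisions under stronger exponential compression)
    expect_lte(max(ws) - min(ws), 0.005 + 1e-9)
  }
})

test_that("degenerate RDMs are rejected", {
  const <- rdm(matrix(1, 16, 16) - diag(1, 16), ids = analyzedStimuli(ss))
  expect_error(fitAttention(const, ss), "unidentified|constant")
  sparse <- matrix(NA_real_, 16, 16); diag(sparse) <- 0
  sparse[1, 2] <- sparse[2, 1] <- 0.3
  expect_error(fitAttention(rdm(sparse, ids = analyzedStimuli(ss)), ss),
               "insufficient")
})

test_that("tied argmax runs resolve to the midpoint and are recorded", {
  x <- attentionRDM(ss, 0.8)
  fit <- fitAttention(x, ss)
  # independent re-derivation of the tied run and its midpoint
  rhos <- vapply(fit@grid, function(w)
    rsaRho(rsaSpearman(attentionRDM(ss, w), x)), numeric(1))
  tied <- which(rhos >= max(rhos) - 1e-10)
  expect_gt(length(tied), 1L)
  runs <- split(tied, cumsum(c(1, diff(tied) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  expect_true(fit@tie)
  expect_equal(fit@w, mean(fit@grid[range(run)]))
  expect_true(0.8 %in% fit@grid[run])  # the true weight lies in the run
})

test_that("5-fold CV yields 20 held-out evaluations and recovers weights", {
  cfg <- cohortConfig("modulated", sessionsPerContext = 1, sites = 64,
                      trialsPerStimulus = 5, noise = 0, seed = 21)
  cohort <- simulateCohort(cfg)
  cv <- crossvalAttention(cohort, k = 5, seed = 2)
  f <- cvFolds(cv)
  expect_equal(nrow(f), 20L)
  expect_equal(as.integer(table(f$context)), c(10L, 10L))
  expect_equal(as.integer(table(f$subject)), c(10L, 10L))
  # noiseless: every fold recovers the planted weight (up to the tied-run
  # midpoint), held-out rho ~ 1
  expect_true(all(abs(f$wFit[f$context == "motion"] - 0.8) <= 0.05))
  expect_true(all(abs(f$wFit[f$context == "color"] - 0.2) <= 0.05))
  expect_true(all(f$rhoHeldout > 0.95))
  # determinism
  cv2 <- crossvalAttention(cohort, k = 5, seed = 2)
  expect_identical(cvFolds(cv2), f)
  expect_identical(cv2@assignment, cv@assignment)
  cv3 <- crossvalAttention(cohort, k = 5, seed = 3)
  expect_false(identical(cv3@assignment, cv@assignment))
})

test_that("fold assignment stratifies every stimulus into every fold", {
  cfg <- cohortConfig("null", sessionsPerContext = 1, sites = 4,
                      trialsPerStimulus = 5, noise = 0.2, seed = 4)
  sess <- simulateSession(cfg, 1, "color", 1)
  folds <- dimstretch:::assignFolds(list(sess), 5L, "color", 77)[[1]]
  meta <- sess@trialMeta
  tab <- table(meta$stimulusId, folds)
  expect_true(all(tab == 1))  # 5 trials per stimulus -> one per fold
})

test_that("baseline pools mixed-context folds and underperforms when the
          planted geometry tracks context", {
  cfg <- cohortConfig("modulated", sessionsPerContext = 1, sites = 10,
                      trialsPerStimulus = 5, noise = 0.1, seed = 8)
  cohort <- simulateCohort(cfg)
  cv <- crossvalAttention(cohort, k = 5, seed = 5)
  cvb <- baselineCrossval(cohort, k = 5, seed = 5)
  fb <- cvFolds(cvb)
  expect_equal(nrow(fb), 20L)  # k per context per subject
  expect_equal(unname(table(fb$context, fb$subject)), matrix(5L, 2, 2))
  expect_gt(mean(cvFolds(cv)$rhoHeldout), mean(fb$rhoHeldout))
  mcmp <- modelComparison(cv, cvb)
  expect_equal(mcmp$df1, 1L)
  expect_equal(mcmp$df2, 37L)  # 40 scores - subject - model - intercept
  expect_lt(mcmp$p, 0.05)
  expect_gt(mcmp$meanCognitive, mcmp$meanBaseline)
})

test_that("context-independent geometry: cognitive ~ baseline", {
  cfg <- cohortConfig("null", sessionsPerContext = 1, sites = 10,
                      trialsPerStimulus = 5, noise = 0.1, seed = 14)
  cohort <- simulateCohort(cfg)
  cv <- crossvalAttention(cohort, k = 5, seed = 5)
  cvb <- baselineCrossval(cohort, k = 5, seed = 5)
  expect_lt(abs(mean(cvFolds(cv)$rhoHeldout) -
                  mean(cvFolds(cvb)$rhoHeldout)), 0.05)
})

test_that("model comparison handles identical and missing scores", {
  f <- expand.grid(subject = c("m1", "m2"), context = c("color", "motion"),
                   fold = 1:5, stringsAsFactors = FALSE)
  f$rhoHeldout <- 0.6
  fc <- cbind(f, model = "cognitive", wFit = 0.5, rhoTrain = 0.9)
  fb <- cbind(f, model = "baseline", wFit = 0.5, rhoTrain = 0.9)
  out <- modelComparison(fc, fb)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  fcNA <- fc; fcNA$rhoHeldout[3] <- NA
  expect_warning(out2 <- modelComparison(fcNA, fb), "listwise")
  expect_equal(out2$df2, 35L)  # one matched fold dropped from both models
})

test_that("layered model comparison reports the model effect", {
  set.seed(6)
  g <- expand.grid(sim = paste0("sim", 1:4), step = 1:5, layer = 1:3,
                   fold = 1:2, stringsAsFactors = FALSE)
  fc <- cbind(g, model = "cognitive")
  fb <- cbind(g, model = "baseline")
  fc$rhoHeldout <- 0.7 + 0.02 * g$layer + rnorm(nrow(g), sd = 0.02)
  fb$rhoHeldout <- 0.5 + 0.02 * g$layer + rnorm(nrow(g), sd = 0.02)
  out <- modelComparison(fc, fb, design = "layered")
  expect_lt(out$p, 0.001)
  expect_gt(out$meanCognitive, out$meanBaseline)
})
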