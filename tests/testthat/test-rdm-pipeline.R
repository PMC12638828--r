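ss <- makeStimulusSet()
w01 <- c(0, 1)

test_that("session RDM: zeros for identical trains, NA for absent stimuli", {
  tr <- list(list(c(0.2, 0.5, 0.8), c(0.1, 0.6)))  # one trial, two sites
  sess <- manualSession(
    list(s01 = rep(tr, 2), s02 = rep(tr, 2)),      # identical trains
    sites = c("a", "b"), window = w01)
  r <- buildSessionRDM(sess, "ISI", window = w01, stimset = ss)
  m <- rdmMatrix(r)
  expect_equal(m["s01", "s02"], 0)
  expect_true(all(is.na(m["s03", colnames(m) != "s03"])))
  expect_equal(m["s03", "s03"], 0)  # diagonal forced to zero
})

test_that("session RDM is deterministic and trial-order equivariant", {
  cfg <- cohortConfig("modulated", sessionsPerContext = 1, sites = 5,
                      trialsPerStimulus = 3, noise = 0.3, seed = 42)
  sess <- simulateSession(cfg, 1, "motion", 1)
  r1 <- buildSessionRDM(sess, "ISI", context = "motion", seed = 9)
  r2 <- buildSessionRDM(sess, "ISI", context = "motion", seed = 9)
  expect_identical(rdmMatrix(r1), rdmMatrix(r2))
  # permute stored trial order; sampling is keyed to trial ids
  perm <- sample(length(sess@trials))
  sessP <- new("SessionRecording", subject = sess@subject,
               session = sess@session, sites = sess@sites,
               window = sess@window, trials = sess@trials[perm],
               trialMeta = sess@trialMeta[perm, ])
  r3 <- buildSessionRDM(sessP, "ISI", context = "motion", seed = 9)
  expect_equal(rdmMatrix(r3), rdmMatrix(r1), tolerance = 1e-12)
  # cap binds and stays deterministic
  r4 <- buildSessionRDM(sess, "ISI", context = "motion", seed = 9, cap = 4L)
  r5 <- buildSessionRDM(sessP, "ISI", context = "motion", seed = 9, cap = 4L)
  expect_equal(rdmMatrix(r4), rdmMatrix(r5), tolerance = 1e-12)
  expect_error(buildSessionRDM(sess, "mahalanobis"), "arg")
})

test_that("low-noise timing sessions recover the planted geometry", {
  cfg <- cohortConfig("modulated", sessionsPerContext = 1, sites = 20,
                      trialsPerStimulus = 10, noise = 0.05, seed = 7)
  sess <- simulateSession(cfg, 1, "motion", 1)
  r <- buildSessionRDM(sess, "ISI", context = "motion")
  ae <- attentionRDM(ss, cfg$wTrue[["motion"]], relevantDimension = "motion")
  expect_gte(rsaRho(rsaSpearman(r, ae)), 0.8)
})

test_that("sliding-window bookkeeping and RSA summaries", {
  expect_length(slidingWindowStarts(c(-0.05, 0.21), 0.01), 27L)
  expect_length(slidingWindowStarts(c(0, 0.22), 0.01), 23L)
  cfg <- cohortConfig("modulated", sessionsPerContext = 2, sites = 8,
                      trialsPerStimulus = 4, noise = 0.1, seed = 13)
  sessions <- lapply(1:2, function(k) simulateSession(cfg, 1, "motion", k))
  ae <- attentionRDM(ss, 0.8)
  sw <- slidingWindowRSA(sessions, ae, startRange = c(0, 0.1), step = 0.05,
                         context = "motion")
  expect_equal(nrow(sw$summary), 3L)
  expect_equal(nrow(sw$perSession), 6L)
  expect_equal(sw$summary$n, rep(2L, 3))
  expect_true(all(sw$summary$lo <= sw$summary$mean &
                  sw$summary$mean <= sw$summary$hi))
  expect_error(slidingWindowRSA(sessions, ae, startRange = c(0.2, 0.1)),
               "startRange")
  # degenerate constant reference propagates as missing, not an error
  const <- rdm(matrix(1, 16, 16) - diag(1, 16), ids = rdmIds(ae))
  swc <- slidingWindowRSA(sessions[1], const, startRange = c(0, 0),
                          context = "motion")
  expect_true(is.na(swc$summary$mean))
})

test_that("measure comparison: timing beats rate on timing-coded cohorts", {
  cfg <- cohortConfig("modulated", sessionsPerContext = 2, sites = 12,
                      trialsPerStimulus = 6, noise = 0.2, seed = 11)
  sessions <- lapply(1:2, function(k) simulateSession(cfg, 1, "motion", k))
  ae <- attentionRDM(ss, 0.8)
  mc <- measureComparison(sessions, ae, context = "motion")
  means <- tapply(mc$scores$rho, mc$scores$measure, mean, na.rm = TRUE)
  expect_gt(means[["ISI"]], means[["euclidean"]])
  expect_gt(mc$anova$F, 1)
  expect_lt(mc$anova$p, 0.05)
  expect_s3_class(mc$pairwise, "pairwise.htest")
  expect_error(measureComparison(sessions[1], ae), "2 sessions")
})

test_that("rate-coded cohorts show no timing advantage", {
  cfg <- cohortConfig("modulated", sessionsPerContext = 1, sites = 20,
                      trialsPerStimulus = 8, noise = 0.05, seed = 19,
                      coding = "rate")
  sess <- simulateSession(cfg, 1, "motion", 1)
  ae <- attentionRDM(ss, 0.8)
  rhoE <- rsaRho(rsaSpearman(buildSessionRDM(sess, "euclidean",
                                             context = "motion"), ae))
  rhoI <- rsaRho(rsaSpearman(buildSessionRDM(sess, "ISI",
                                             context = "motion"), ae))
  expect_gte(rhoE, 0.6)
  expect_gte(rhoE, rhoI - 0.1)  # Euclidean comparable or better
})

test_that("alignment grid and region x task interaction", {
  set.seed(31)
  noisyAe <- function(w, sd = 0.02) {
    m <- rdmMatrix(attentionRDM(ss, w))
    n <- matrix(0, 16, 16)
    n[upper.tri(n)] <- rnorm(120, sd = sd); n <- n + t(n)
    m <- pmax(m + n, 0); diag(m) <- 0
    rdm(m, ids = analyzedStimuli(ss))
  }
  # MT-like region: motion-weighted in both contexts; V4-like: color
  brain <- list(MT = list(color = noisyAe(0.95), motion = noisyAe(0.95)),
                V4 = list(color = noisyAe(0.05), motion = noisyAe(0.05)))
  # model layers track the task context
  model <- lapply(1:4, function(sim)
    lapply(setNames(nm = paste0("layer", 1:3)), function(ly)
      list(color = noisyAe(0.1), motion = noisyAe(0.9))))
  names(model) <- paste0("sim", 1:4)
  al <- alignmentMatrix(brain, model)
  expect_equal(dim(al$grid), c(2L, 3L, 2L))  # regions x layers x contexts
  expect_equal(nrow(al$long), 2 * 4 * 3 * 2)
  # MT-like aligns better in the motion context, V4-like in color
  expect_gt(al$grid["MT", 1, "motion"], al$grid["MT", 1, "color"])
  expect_gt(al$grid["V4", 1, "color"], al$grid["V4", 1, "motion"])
  expect_lt(al$interaction$p, 0.05)
  # identical model geometries across contexts: interaction vanishes
  modelFlat <- lapply(model, function(sim) lapply(sim, function(ly) {
    ly$motion <- ly$color; ly
  }))
  brainFlat <- lapply(brain, function(rg) { rg$motion <- rg$color; rg })
  alFlat <- alignmentMatrix(brainFlat, modelFlat)
  expect_lt(alFlat$interaction$F, 1e-6)
  # missing context yields missing cells
  brainNA <- brain; brainNA$MT$color <- NULL
  alNA <- alignmentMatrix(brainNA, model)
  expect_true(all(is.na(alNA$long$rho[alNA$long$region == "MT" &
                                      alNA$long$context == "color"])))
})
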