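test_that("LSTM backprop matches numerical gradients", {
  cfg <- taskConfig(layers = 2L, hidden = 5L, ht = 4L)
  ns <- asNamespace("dimstretch")
  set.seed(1)
  X <- matrix(rnorm(3 * 6), 3, 6)
  p <- ns$lstmInit(6, cfg, 99)
  for (mode in c("final", "all")) {
    cfg$lossMode <- mode
    fwd <- ns$lstmForward(p, X, cfg, 2L)
    gr <- ns$lstmBackward(p, fwd, X, cfg, 2L)
    for (nm in names(p)) {
      idx <- sample(length(p[[nm]]), min(4, length(p[[nm]])))
      for (ii in idx) {
        eps <- 1e-5
        p2 <- p; p2[[nm]][ii] <- p2[[nm]][ii] + eps
        l1 <- ns$lstmForward(p2, X, cfg, 2L)$loss
        p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
        l0 <- ns$lstmForward(p2, X, cfg, 2L)$loss
        num <- (l1 - l0) / (2 * eps)
        expect_lt(abs(num - gr[[nm]][ii]) /
                    max(1e-8, abs(num) + abs(gr[[nm]][ii])), 1e-4)
      }
    }
  }
})

test_that("micro-F1 pools counts across classes", {
  expect_equal(microF1(c("L", "R", "N"), c("L", "R", "N")), 1)
  expect_equal(microF1(c("R", "N", "L"), c("L", "R", "N")), 0)
  expect_equal(microF1(c("L", "R", "N", "L"), c("L", "R", "N", "R")), 0.75)
  expect_error(microF1(character(0), character(0)), "non-empty")
  expect_error(microF1("L", c("L", "R")), "equal-length")
})

test_that("trial rendering follows the task structure and kinematics", {
  cfg <- taskConfig()
  tr <- renderTrial("s01", "motion", cfg, seed = 4)
  expect_equal(dim(tr@frames)[4], cfg$framesPerTrial)
  expect_equal(as.vector(table(tr@phase)[c("fixation", "cue", "stimulus")]),
               c(cfg$framesFix, cfg$framesCue, cfg$framesStim))
  # full-scale preset: 270 frames with the 0.5 s / 1 s / 3 s proportions
  full <- taskConfig("full")
  expect_equal(full$framesPerTrial, 270L)
  expect_equal(full$frameRate, 60)
  # unwrapped per-frame displacement equals direction x speed exactly
  v <- cfg$speed * c(cos(dimstretch:::stepAngle(1)),
                     sin(dimstretch:::stepAngle(1)))  # s01: up
  for (f in 2:dim(tr@dotTracks)[1]) {
    expect_equal(tr@dotTracks[f, , 1] - tr@dotTracks[f - 1, , 1],
                 rep(v[1], cfg$nDots), tolerance = 1e-12)
    expect_equal(tr@dotTracks[f, , 2] - tr@dotTracks[f - 1, , 2],
                 rep(v[2], cfg$nDots), tolerance = 1e-12)
  }
  # same stimulus, different seeds: same label, different pixels
  tr2 <- renderTrial("s01", "motion", cfg, seed = 5)
  expect_equal(tr2@label, tr@label)
  expect_false(identical(tr2@frames, tr@frames))
  # deterministic given the seed
  tr3 <- renderTrial("s01", "motion", cfg, seed = 4)
  expect_identical(tr3@frames, tr@frames)
  # labels: cue context selects the relevant dimension; ambiguous -> N
  expect_equal(renderTrial("s01", "color", cfg, 1)@label, "L")
  expect_equal(renderTrial("s16", "color", cfg, 1)@label, "R")
  expect_equal(renderTrial("s17", "color", cfg, 1)@label, "N")
  expect_equal(renderTrial("s17", "motion", cfg, 1)@label, "N")
  expect_error(renderTrial("nope", "motion", cfg, 1), "unknown stimulus")
})

test_that("feature extraction pools frames and adds temporal differences", {
  cfg <- taskConfig()
  tr <- renderTrial("s06", "color", cfg, seed = 2)
  X <- dimstretch:::extractFeatures(tr@frames, cfg)
  expect_equal(dim(X), c(cfg$framesPerTrial, 2 * 3 * cfg$poolTo^2 + 2L))
  # static phases have zero temporal difference and zero flow
  expect_equal(max(abs(X[2, 193:384] - (X[2, 1:192] - X[1, 1:192]))), 0)
  expect_equal(unname(X[2, 385:386]), c(0, 0))
  # the flow channel recovers the dot field's drift direction: upward
  # motion (s01: motion coordinate 1) has positive vertical flow during
  # the stimulus phase
  trUp <- renderTrial("s01", "motion", cfg, seed = 6)
  Xup <- dimstretch:::extractFeatures(trUp@frames, cfg)
  stimFrames <- which(trUp@phase == "stimulus")[-1]
  expect_gt(mean(Xup[stimFrames, 386]), 0)
  cfgP <- taskConfig(extractor = "proj", projDim = 32L)
  Xp <- dimstretch:::extractFeatures(tr@frames, cfgP)
  expect_equal(ncol(Xp), 32L)
})

test_that("untrained model is near chance; training reduces the loss", {
  cfg <- taskConfig()
  specs <- makeTrialSpecs(1, seed = 31)
  dat <- prepareTrialData(specs, cfg)
  ns <- asNamespace("dimstretch")
  p0 <- ns$lstmInit(ncol(dat$features[[1]]), cfg, 7)
  l0 <- ns$lstmForward(p0, dat$features[[1]], cfg, 1L)$loss
  expect_lt(abs(l0 - log(3)), 0.1)
  # loss over the first 100 steps decreases for the large majority of seeds
  sub <- list(features = dat$features, meta = dat$meta)
  drops <- vapply(1:5, function(sd_) {
    m <- trainTaskModel(sub, cfg, seed = sd_, epochs = 3L)
    tr <- m@lossTrace
    mean(tail(tr, 42)) < mean(head(tr, 42))
  }, logical(1))
  expect_gte(mean(drops), 0.8)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- taskConfig()
  dat <- prepareTrialData(makeTrialSpecs(1, contexts = "color", seed = 8),
                          cfg)
  m1 <- trainTaskModel(dat, cfg, seed = 5, epochs = 2L)
  m2 <- trainTaskModel(dat, cfg, seed = 5, epochs = 2L)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@lossTrace, m2@lossTrace)
  m3 <- trainTaskModel(dat, cfg, seed = 6, epochs = 2L)
  expect_false(identical(m3@params, m1@params))
  # missing label class rejected
  onlyL <- list(features = dat$features[dat$meta$label == "L"],
                meta = dat$meta[dat$meta$label == "L", ])
  expect_error(trainTaskModel(onlyL, cfg, seed = 1), "all three labels")
})

test_that("LSTM-time frame accounting matches the 60 frames/s mapping", {
  expect_equal(lstmFrameCount(0.05, 60), 3L)
  expect_equal(lstmFrameCount(0.25, 60), 15L)
  expect_equal(lstmFrameCount(0.001, 60), 1L)  # never less than one frame
})

test_that("layer RDMs: shape, zero entries for identical states, sliding", {
  cfg <- taskConfig()
  specs <- makeTrialSpecs(2, seed = 12)
  dat <- prepareTrialData(specs, cfg)
  ns <- asNamespace("dimstretch")
  model <- new("TaskModel",
               params = ns$lstmInit(ncol(dat$features[[1]]), cfg, 3),
               config = unclass(cfg), lossTrace = numeric(0),
               checkpoints = data.frame())
  lr <- layerRDMs(model, dat)
  expect_length(lr, cfg$layers)
  expect_named(lr[[1]], c("color", "motion"), ignore.order = TRUE)
  expect_s4_class(lr[[1]]$color, "RDM")
  expect_false(anyNA(rdmMatrix(lr[[1]]$color)))
  # identical hidden states for two stimuli -> zero dissimilarity entry
  dat2 <- prepareTrialData(makeTrialSpecs(1, seed = 13), cfg)
  i <- which(dat2$meta$stimulusId == "s01" & dat2$meta$context == "color")
  j <- which(dat2$meta$stimulusId == "s02" & dat2$meta$context == "color")
  dat2$features[[j]] <- dat2$features[[i]]
  lr2 <- layerRDMs(model, dat2)
  expect_equal(rdmMatrix(lr2[[2]]$color)["s01", "s02"], 0, tolerance = 1e-9)
  # sliding mode: one start per frame step, bin of >= 1 frame
  sl <- layerRDMs(model, dat, timing = "sliding", binWidth = 0.05)
  expect_gte(length(sl), 2L)
  expect_s4_class(sl[[1]][[1]]$motion, "RDM")
  # a stimulus with no test trial yields missing entries
  drop <- dat$meta$stimulusId != "s05"
  dat3 <- list(features = dat$features[drop], meta = dat$meta[drop, ])
  lr3 <- layerRDMs(model, dat3)
  expect_true(all(is.na(rdmMatrix(lr3[[1]]$color)["s05",
                    colnames(rdmMatrix(lr3[[1]]$color)) != "s05"])))
})
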