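cfgDefault <- detectorConfig()

test_that("model initialization gives the first feature full weight", {
  blk <- matrix(c(10, 20, 30, 40), 2, 2)
  v <- btcFeature(blk)
  m <- initBlockModel(v, blk, detectorConfig(K = 3))
  expect_equal(m$weights, c(1, 0, 0))
  expect_equal(m$features[, 1], as.numeric(v), ignore_attr = TRUE)
  expect_equal(m$features[, 2], rep(0, 4))
  expect_equal(m$exemplar, blk)
  m1 <- initBlockModel(v, blk, detectorConfig(K = 1))
  expect_equal(m1$weights, 1)
})

test_that("background count follows strict cumulative-weight crossing", {
  expect_equal(backgroundCount(c(0.6, 0.3, 0.1), 0.7), 2L)
  expect_equal(backgroundCount(c(0.8, 0.15, 0.05), 0.7), 1L)
  expect_equal(backgroundCount(c(1, 0, 0), 0.99), 1L)
  expect_equal(backgroundCount(c(0.7, 0.2, 0.1), 0.7), 2L)  # 0.7 is not > 0.7
})

test_that("feature distance and adaptive threshold evaluate as specified", {
  v <- c(40, 30, 20, 10)
  expect_equal(featureDistance(v, v), 0)
  expect_equal(featureDistance(v, c(38, 30, 20, 10)), 2)
  expect_equal(featureDistance(c(1, 0, 0, 0), c(0, 0, 0, 0)), 1)
  expect_equal(adaptiveThreshold(40, 0.75, 1), 70)
  expect_equal(adaptiveThreshold(40, 0.75, 0), 30)
  expect_equal(adaptiveThreshold(0, 0.75, 0.5), 0)
})

test_that("an exact repeat of the initializer stays background with stable weights", {
  blk <- matrix(c(60, 80, 100, 120), 2, 2)
  m <- initBlockModel(btcFeature(blk), blk, cfgDefault)
  res <- classifyAndUpdate(m, blk, cfgDefault, frameIndex = 2L)
  expect_equal(res$label, "background")
  expect_equal(res$model$weights, c(1, 0, 0))
  expect_equal(res$distance, 0)
  expect_error(classifyAndUpdate(list(), blk, cfgDefault), "uninitialized")
})

test_that("weight and feature updates follow the EMA match rules", {
  cfg <- detectorConfig(K = 2, alphaW = 0.1, alphaB = 0.1, TDBase = 20)
  blk <- matrix(c(10, 20, 30, 40), 2, 2)
  m <- initBlockModel(btcFeature(blk), blk, cfg)
  m$weights <- c(0.5, 0.5)
  m$features[, 2] <- c(500, 500, 500, 500)  # unreachable second entry
  res <- classifyAndUpdate(m, blk, cfg, frameIndex = 2L)
  # matched entry 1: w = 0.9 * (0.5, 0.5) + 0.1 * (1, 0) = (0.55, 0.45)
  expect_equal(res$model$weights, c(0.55, 0.45))

  # feature EMA on a background-labeled match: (1-a) v_old + a v_new
  cfg2 <- detectorConfig(K = 2, alphaB = 0.1, TDBase = 20, alpha = 0.75)
  old <- matrix(c(40, 20, 30, 10), 2, 2)    # feature (40, 30, 20, 10)
  m2 <- initBlockModel(btcFeature(old), old, cfg2)
  newBlk <- old; newBlk[1, 1] <- 50         # feature (50, 30, 20, 10)
  res2 <- classifyAndUpdate(m2, newBlk, cfg2, frameIndex = 2L)
  expect_equal(res2$label, "background")
  expect_equal(res2$model$features[, 1], c(41, 30, 20, 10), ignore_attr = TRUE)
})

test_that("an unmatched block replaces the minimum-weight entry and is object", {
  blk <- matrix(c(10, 20, 30, 40), 2, 2)
  m <- initBlockModel(btcFeature(blk), blk, cfgDefault)
  far <- blk + 200
  res <- classifyAndUpdate(m, far, cfgDefault, frameIndex = 2L)
  expect_equal(res$label, "object")
  expect_true(is.na(res$distance))
  # new entry carries the new feature at (normalized) minimum weight
  expect_equal(sum(res$model$weights), 1, tolerance = 1e-12)
  k <- which.min(abs(res$model$features[1, ] - btcFeature(far)[1]))
  expect_equal(res$model$weights[k], 0.01 / 1.01, tolerance = 1e-12)
})

test_that("weights stay normalized and sorted across a random 60-frame run", {
  set.seed(99)
  blk <- randomBlock(4L)
  m <- initBlockModel(btcFeature(blk), blk, cfgDefault)
  for (t in 2:60) {
    b <- if (runif(1) < 0.3) randomBlock(4L) else blk + round(rnorm(1, 0, 5))
    res <- classifyAndUpdate(m, b, cfgDefault, frameIndex = t)
    m <- res$model
    expect_equal(sum(m$weights), 1, tolerance = 1e-9)
    expect_true(all(diff(m$weights) <= 1e-12))
    expect_true(all(m$weights >= 0 & m$weights <= 1))
  }
})

test_that("a constant input stays background with nondecreasing dominant weight", {
  blk <- matrix(rep(c(90, 110), 8), 4, 4)
  m <- initBlockModel(btcFeature(blk), blk, cfgDefault)
  wPrev <- m$weights[1]
  for (t in 2:30) {
    res <- classifyAndUpdate(m, blk, cfgDefault, frameIndex = t)
    expect_equal(res$label, "background")
    expect_gte(res$model$weights[1], wPrev - 1e-12)
    wPrev <- res$model$weights[1]
    m <- res$model
  }
})

test_that("a matched feature converges geometrically at rate 1 - alpha_b", {
  cfg <- detectorConfig(K = 2, alphaB = 0.2, TDBase = 30)
  old <- matrix(c(100, 100, 120, 120), 2, 2)
  m <- initBlockModel(btcFeature(old), old, cfg)
  target <- old + 10
  vT <- as.numeric(btcFeature(target))
  err0 <- featureDistance(m$features[, 1], vT)
  for (t in 2:12) m <- classifyAndUpdate(m, target, cfg, frameIndex = t)$model
  # 11 updates, each shrinking the gap by factor (1 - alpha_b)
  expect_equal(featureDistance(m$features[, 1], vT), err0 * 0.8^11,
               tolerance = 1e-6)
})

test_that("a sustained appearance change is absorbed when its weight crosses 1 - T", {
  cfg <- detectorConfig(K = 3, T = 0.7, alphaW = 0.05, TDBase = 20)
  blk <- matrix(rep(c(90, 110), 8), 4, 4)
  m <- initBlockModel(btcFeature(blk), blk, cfg)
  changed <- blk + 150
  # closed form: after replacement the old entry holds w0 = 1/(1 + alpha_w);
  # m further matches decay it by (1-alpha_w)^m; background as soon as it is
  # no longer > T, i.e. m = ceil(log(T (1 + alpha_w)) / log(1 - alpha_w))
  w0 <- 1 / (1 + cfg$alphaW)
  mNeeded <- ceiling(log(cfg$T / w0) / log(1 - cfg$alphaW))
  labels <- character(0)
  for (t in 2:(2 + mNeeded + 1)) {
    res <- classifyAndUpdate(m, changed, cfg, frameIndex = t)
    labels <- c(labels, res$label)
    m <- res$model
  }
  expect_equal(labels[seq_len(mNeeded + 1)], rep("object", mNeeded + 1))
  expect_equal(labels[mNeeded + 2], "background")
})

test_that("labels are invariant under a global additive intensity shift", {
  set.seed(5)
  seqA <- replicate(15, randomBlock(4L, 40, 200), simplify = FALSE)
  shift <- 30
  cfg <- cfgDefault
  mA <- initBlockModel(btcFeature(seqA[[1]]), seqA[[1]], cfg)
  mB <- initBlockModel(btcFeature(seqA[[1]] + shift), seqA[[1]] + shift, cfg)
  for (t in 2:15) {
    rA <- classifyAndUpdate(mA, seqA[[t]], cfg, frameIndex = t)
    rB <- classifyAndUpdate(mB, seqA[[t]] + shift, cfg, frameIndex = t)
    expect_equal(rA$label, rB$label)
    expect_equal(rA$S, rB$S, tolerance = 1e-9)
    mA <- rA$model; mB <- rB$model
  }
})
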