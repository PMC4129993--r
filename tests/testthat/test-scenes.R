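test_that("a degenerate static configuration yields identical frames", {
  cfg <- sceneConfig(height = 32, width = 32, nFrames = 4, seed = 3,
                     noiseSigma = 0)
  scn <- generateScene(cfg)
  expect_equal(nFrames(scn), 4L)
  for (t in 2:4) expect_identical(sceneFrames(scn)[[t]], sceneFrames(scn)[[1]])
  expect_false(any(vapply(truthMasks(scn), any, logical(1))))
})

test_that("truth masks follow the rendered object exactly", {
  cfg <- sceneConfig(height = 40, width = 40, nFrames = 6, seed = 5,
                     noiseSigma = 0,
                     objects = list(list(shape = "disk", size = 8,
                                         start = c(20, 10), velocity = c(0, 1),
                                         intensityOffset = 60,
                                         textureContrast = 10)))
  scn <- generateScene(cfg)
  cents <- vapply(truthMasks(scn), function(m) {
    w <- which(m, arr.ind = TRUE); mean(w[, 2])
  }, numeric(1))
  expect_equal(diff(cents), rep(1, 5))  # 1 column per frame
  # object pixels sit near background level + offset
  for (t in c(1, 6)) {
    supp <- truthMasks(scn)[[t]]
    expect_equal(mean(sceneFrames(scn)[[t]][supp]), 110 + 60, tolerance = 4)
    off <- abs(mean(sceneFrames(scn)[[t]][supp]) - mean(sceneFrames(scn)[[t]][!supp]))
    expect_gt(off, 40)
  }
})

test_that("scene generation is deterministic and leaves the global RNG alone", {
  cfg <- sceneConfig(height = 24, width = 24, nFrames = 3, seed = 12)
  set.seed(1); before <- runif(1)
  set.seed(1)
  s1 <- generateScene(cfg)
  after <- runif(1)
  expect_identical(before, after)  # generator restored the RNG state
  s2 <- generateScene(cfg)
  expect_identical(sceneFrames(s1), sceneFrames(s2))
  expect_identical(truthMasks(s1), truthMasks(s2))
})

test_that("an additive ramp with integer gains shifts whole frames uniformly", {
  cfg <- sceneConfig(height = 24, width = 24, nFrames = 5, seed = 2,
                     noiseSigma = 0,
                     illumination = list(mode = "additive_ramp",
                                         start = 0, end = 4))
  scn <- generateScene(cfg)
  for (t in 2:5) {
    d <- sceneFrames(scn)[[t]] - sceneFrames(scn)[[1]]
    expect_equal(max(d) - min(d), 0)
    expect_equal(d[1, 1], t - 1)
  }
})

test_that("objects that would leave the frame are rejected", {
  cfg <- sceneConfig(height = 24, width = 24, nFrames = 10, seed = 2,
                     objects = list(list(shape = "disk", size = 8,
                                         start = c(12, 18), velocity = c(0, 1),
                                         intensityOffset = 40,
                                         textureContrast = 10)))
  expect_error(generateScene(cfg), "leaves the frame")
})

test_that("the standard suite spans the documented scene families", {
  suite <- standardSuite()
  expect_setequal(names(suite),
    c("static_clean", "static_degraded", "close_clean", "close_degraded",
      "distant_clean", "distant_degraded", "multi_clean", "multi_degraded"))
  expect_length(suite$close_degraded$objects, 1L)
  expect_length(suite$multi_degraded$objects, 2L)
  expect_length(suite$static_degraded$objects, 0L)
  expect_lt(suite$distant_degraded$objects[[1]]$size,
            suite$close_degraded$objects[[1]]$size)

  # degraded static: frames vary over time, truth stays empty
  scn <- suiteScene("static_degraded")
  expect_false(identical(sceneFrames(scn)[[1]], sceneFrames(scn)[[30]]))
  expect_false(any(vapply(truthMasks(scn), any, logical(1))))
})

test_that("ripple oscillates only inside its region", {
  cfg <- sceneConfig(height = 30, width = 30, nFrames = 8, seed = 4,
                     noiseSigma = 0,
                     ripple = list(region = c(10, 20, 5, 15), amplitude = 10,
                                   period = 4))
  scn <- generateScene(cfg)
  d <- sceneFrames(scn)[[1]] - sceneFrames(scn)[[3]]  # opposite ripple phases
  expect_true(any(d[10:20, 5:15] != 0))
  outside <- d; outside[10:20, 5:15] <- 0
  expect_true(all(outside == 0))
})
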