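test_that("frame sequences round-trip through PGM and PNG in numeric order", {
  d <- withr::local_tempdir()
  f <- matrix(round(runif(16, 0, 255)), 4, 4)
  writePGM <- hierbg:::writePGM
  writePGM(f, file.path(d, "f2.pgm"))
  writePGM(f, file.path(d, "f10.pgm"))
  writePGM(f, file.path(d, "f1.pgm"))
  frames <- loadFrames(d)
  expect_length(frames, 3L)
  for (fr in frames) expect_equal(fr, f, ignore_attr = TRUE)

  # numeric, not lexicographic, ordering
  d2 <- withr::local_tempdir()
  for (k in c(2, 10, 1))
    writePGM(matrix(k, 4, 4), file.path(d2, sprintf("f%d.pgm", k)))
  got <- vapply(loadFrames(d2), function(m) m[1, 1], numeric(1))
  expect_equal(got, c(1, 2, 10))
})

test_that("inconsistent frame shapes and empty inputs are rejected", {
  d <- withr::local_tempdir()
  hierbg:::writePGM(matrix(0, 4, 4), file.path(d, "f1.pgm"))
  hierbg:::writePGM(matrix(0, 5, 5), file.path(d, "f2.pgm"))
  expect_error(loadFrames(d), "shape mismatch")
  expect_error(loadFrames(withr::local_tempdir()), "no frames")
  expect_error(loadFrames(file.path(d, "nope.png")), "does not exist")
})

test_that("grayscale conversion follows BT.601 luma", {
  gray <- array(77, dim = c(2, 2, 3))
  expect_equal(toGrayscale(gray), matrix(77, 2, 2))
  white <- array(255, dim = c(1, 1, 3))
  expect_equal(toGrayscale(white)[1, 1], 255)
  red <- array(0, dim = c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(toGrayscale(red)[1, 1], 0.299 * 255)  # 76.245
  expect_error(toGrayscale(array(0, dim = c(2, 2, 4))), "3 array")
})

test_that("block partitioning tiles with edge replication and exact bookkeeping", {
  g <- partitionBlocks(matrix(1:256, 16, 16), 8, 8)
  expect_equal(g@gridDim, c(2L, 2L))
  expect_equal(g@padRows + g@padCols, 0L)

  g2 <- partitionBlocks(matrix(0, 17, 16), 8, 8)
  expect_equal(g2@gridDim, c(3L, 2L))
  expect_equal(g2@padRows, 7L)

  f <- matrix(5, 8, 8)
  g3 <- partitionBlocks(f, 8, 8)
  expect_equal(blockAt(g3, 1, 1), f)
  expect_error(blockAt(g3, 2, 1), "out of range")
  expect_error(partitionBlocks(f, 1, 8), "at least 2")
})

test_that("partition then crop reproduces the frame; block count is ceiling arithmetic", {
  set.seed(7)
  for (k in 1:20) {
    H <- sample(4:30, 1); W <- sample(4:30, 1)
    M <- sample(2:9, 1); N <- sample(2:9, 1)
    f <- matrix(round(runif(H * W, 0, 255)), H, W)
    g <- partitionBlocks(f, M, N)
    expect_equal(g@padded[seq_len(H), seq_len(W)], f)
    expect_equal(prod(g@gridDim), ceiling(H / M) * ceiling(W / N))
    # last block replicates the frame edge
    if (g@padRows > 0)
      expect_true(all(g@padded[H + seq_len(g@padRows), , drop = FALSE] ==
                      matrix(g@padded[H, ], g@padRows, ncol(g@padded), byrow = TRUE)))
  }
})

test_that("masks round-trip through files with the 0/255 convention", {
  set.seed(11)
  masks <- list(matrix(runif(64) > 0.5, 8, 8), matrix(FALSE, 8, 8),
                matrix(TRUE, 8, 8))
  for (fmt in c("png", "pgm")) {
    d <- withr::local_tempdir()
    writeMasks(masks, d, format = fmt)
    back <- loadMasks(d)
    expect_equal(back, masks)
  }
  d <- withr::local_tempdir()
  writeMasks(masks[2:3], d, format = "pgm")
  raw <- loadFrames(d)
  expect_true(all(raw[[1]] == 0))    # all-background file is all zeros
  expect_true(all(raw[[2]] == 255))  # all-foreground file is all 255s
})
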