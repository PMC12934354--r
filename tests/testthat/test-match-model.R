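test_that("detectCorresponding links nearest same-diagonal forward successors", {
  m <- data.frame(start = c(0, 100, 200, 300),
                  refStart = c(50, 150, 400, 350),
                  length = c(50, 50, 50, 50),
                  rc = c(FALSE, FALSE, FALSE, FALSE))
  ## diagonals: 50, 50, 200, 50 — match 1 links 2, match 2 links 4
  lk <- detectCorresponding(m)
  expect_equal(lk$link, c(2L, 4L, NA, NA))
  ## reverse-complement matches never link
  m$rc[2] <- TRUE
  lk <- detectCorresponding(m)
  expect_equal(lk$link, c(4L, NA, NA, NA))
})

test_that("the correspondence window bounds intervening matches", {
  m <- data.frame(start = seq(0, 500, by = 100),
                  refStart = c(10, 1000, 2000, 3000, 4000, 510),
                  length = rep(50, 6), rc = rep(FALSE, 6))
  ## matches 1 and 6 share diagonal 10 with 4 matches between them
  expect_equal(detectCorresponding(m, window = 5)$link[1], 6L)
  expect_true(is.na(detectCorresponding(m, window = 4)$link[1]))
})

test_that("gapBreaksFilter removes short matches between corresponding neighbors", {
  m <- data.frame(start = c(0, 300, 400),
                  refStart = c(100, 1000, 500),
                  length = c(200, 80, 200),
                  rc = rep(FALSE, 3))
  ## neighbors 1 and 3 share diagonal 100; match 2 (80 < 256) is dropped
  f <- gapBreaksFilter(m, maxLen = 256)
  expect_equal(nrow(f), 2L)
  expect_equal(f$refStart, c(100, 500))
  ## a long interrupting match survives
  m$length[2] <- 300
  expect_equal(nrow(gapBreaksFilter(m, maxLen = 256)), 3L)
  ## neighbors on different diagonals do not trigger removal
  m$length[2] <- 80; m$refStart[3] <- 600
  expect_equal(nrow(gapBreaksFilter(m, maxLen = 256)), 3L)
})

test_that("gaps-delta encoding emits offsets only for underived matches", {
  m <- workedExampleMatches()
  f <- gapBreaksFilter(detectCorresponding(m))
  expect_equal(nrow(f), 6L)          # the short 3rd match is removed
  enc <- gapsDeltaEncode(f)
  expect_equal(length(enc$offsets), 3L)
  expect_equal(enc$offsets, f$refStart[enc$explicit] * 2)
  expect_equal(sum(!enc$explicit) + length(enc$offsets), nrow(f))
})

test_that("gaps-delta decoding inverts encoding over the skeleton", {
  m <- workedExampleMatches()
  f <- gapBreaksFilter(detectCorresponding(m))
  enc <- gapsDeltaEncode(f)
  skel <- f[, c("start", "length")]
  dec <- gapsDeltaDecode(skel, enc$offsets, enc$deltas)
  expect_equal(dec$refStart, f$refStart)
  expect_equal(dec$rc, f$rc)
})

test_that("gaps-delta round-trips on randomized match lists", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    len <- sample(24:60, n, replace = TRUE)
    gap <- sample(0:30, n, replace = TRUE) * sample(0:1, n, replace = TRUE)
    start <- cumsum(c(0, (len + gap)[-n]))
    diagPool <- sample(100:400, 3)
    m <- data.frame(start = start,
                    refStart = start + sample(diagPool, n, replace = TRUE),
                    length = len,
                    rc = runif(n) < 0.2)
    m$refStart[m$rc] <- sample(1000:2000, sum(m$rc))
    m <- detectCorresponding(m)
    enc <- gapsDeltaEncode(m)
    dec <- gapsDeltaDecode(m[, c("start", "length")], enc$offsets, enc$deltas)
    expect_equal(dec$refStart, m$refStart, label = sprintf("case %d", i))
    expect_equal(dec$rc, m$rc, label = sprintf("case %d strands", i))
  }
})

test_that("disabling gaps delta stores every offset explicitly", {
  m <- detectCorresponding(workedExampleMatches())
  enc <- gapsDeltaEncode(m, useGapsDelta = FALSE)
  expect_equal(length(enc$offsets), nrow(m))
  expect_true(all(enc$deltas == 0))
})

test_that("decoder rejects inconsistent delta streams with typed errors", {
  skel <- data.frame(start = c(0, 100), length = c(50, 50))
  expect_error(gapsDeltaDecode(skel, numeric(0), 0),
               class = "famec_corrupt_error")
  expect_error(gapsDeltaDecode(skel, c(10, 20, 30), c(0)),
               class = "famec_corrupt_error")
  ## delta pointing past the list
  expect_error(gapsDeltaDecode(skel, 10, 2),
               class = "famec_corrupt_error")
})
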