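test_that("the reference buffer uppercases, maps non-ACGT and indexes", {
  buf <- newReferenceBuffer(k = 8)
  refAppend(buf, "acgtacgtNNgg")
  expect_equal(refLength(buf), 12L)
  expect_identical(rawToChar(refSequence(buf)), "ACGTACGTAAGG")
  expect_gt(indexedPositionCount(buf), 0L)
  expect_error(newReferenceBuffer(k = 4), class = "famec_usage_error")
  expect_error(refAppend(buf, makeAncestor(100, seed = 1), sizeCap = 50),
               class = "famec_usage_error")
})

test_that("findMems locates a planted exact match with 0-based coordinates", {
  set.seed(1)
  ref <- makeAncestor(400, seed = 1)
  buf <- newReferenceBuffer(k = 12)
  refAppend(buf, ref)
  contig <- c(makeAncestor(37, seed = 99), ref[101:160], makeAncestor(20, seed = 98))
  m <- findMems(buf, contig, minLen = 30)
  planted <- m[!m$rc & m$length >= 60, ]
  expect_true(any(planted$start <= 37 & planted$refStart <= 100 &
                  planted$start + planted$length >= 97))
})

test_that("reverse-complement matches map back to forward contig coordinates", {
  ref <- makeAncestor(300, seed = 5)
  buf <- newReferenceBuffer(k = 12)
  refAppend(buf, ref)
  seg <- ref[51:130]
  contig <- famec:::revComp(seg)
  m <- findMems(buf, contig, minLen = 40)
  expect_true(any(m$rc & m$start == 0 & m$length == 80 & m$refStart == 50))
  ## and the claimed identity holds
  hit <- m[m$rc, ][1, ]
  cseg <- contig[(hit$start + 1):(hit$start + hit$length)]
  rseg <- refSequence(buf, hit$refStart + 1, hit$refStart + hit$length)
  expect_identical(famec:::revComp(cseg), rseg)
})

test_that("non-ACGT bytes break matches", {
  ref <- makeAncestor(200, seed = 8)
  buf <- newReferenceBuffer(k = 10)
  refAppend(buf, ref)
  contig <- ref
  contig[100] <- charToRaw("N")
  m <- findMems(buf, contig, minLen = 10)
  fw <- m[!m$rc, ]
  expect_false(any(fw$start < 99 & fw$start + fw$length > 100))
})

test_that("findMems equals the brute-force oracle on random small instances", {
  set.seed(100)
  for (i in 1:25) {
    ref <- makeAncestor(sample(50:250, 1), gc = runif(1, 0.3, 0.7),
                        seed = 1000 + i)
    contig <- if (i %% 3 == 0) {
      ## derived contig: many matches
      x <- ref
      p <- sample(length(x), 5)
      x[p] <- charToRaw("N")
      x
    } else makeAncestor(sample(30:200, 1), seed = 2000 + i)
    buf <- newReferenceBuffer(k = 8)
    refAppend(buf, ref, mapACGT = FALSE)
    got <- normMatches(findMems(buf, contig, minLen = 10))
    want <- normMatches(bruteMems(famec:::upperBytes(ref), contig, 10))
    expect_equal(got, want, label = sprintf("instance %d", i))
  }
})

test_that("sampled indexing finds exactly the anchor-visible runs", {
  ref <- makeAncestor(500, seed = 31)
  buf <- newReferenceBuffer(k = 10, sampling = 4)
  refAppend(buf, ref)
  contig <- ref[101:200]
  m <- findMems(buf, contig, minLen = 10)
  expect_true(any(!m$rc & m$length == 100))
})

test_that("selectMatches yields disjoint intervals and trims overlaps", {
  mems <- data.frame(start = c(0L, 5L, 30L), refStart = c(100L, 200L, 300L),
                     length = c(20L, 30L, 15L), rc = c(FALSE, FALSE, FALSE))
  sel <- selectMatches(mems, minLen = 10)
  expect_true(all(sel$start[-1] >= sel$start[-nrow(sel)] +
                    sel$length[-nrow(sel)]))
  ## the second match is trimmed on the contig side, refStart advances too
  expect_equal(sel$start[2], 20L)
  expect_equal(sel$refStart[2], 215L)
  expect_equal(sel$length[2], 15L)
})

test_that("alignedCoverage counts matches plus same-diagonal forward junctions", {
  m <- data.frame(start = c(0, 30), refStart = c(100, 130), length = c(20, 20),
                  rc = c(FALSE, FALSE))
  ## 40 matched + 10 gap bases on the shared diagonal, over 60
  expect_equal(alignedCoverage(m, 60), 50 / 60)
  ## different diagonals: the junction does not count
  m2 <- m; m2$refStart[2] <- 140
  expect_equal(alignedCoverage(m2, 60), 40 / 60)
  ## reverse strand neighbor: junction does not count
  m3 <- m; m3$rc[2] <- TRUE
  expect_equal(alignedCoverage(m3, 60), 40 / 60)
  expect_equal(alignedCoverage(famec:::emptyMatches(), 0), 0)
})

test_that("updateReference appends exactly when coverage is below threshold", {
  buf <- newReferenceBuffer(k = 8)
  refAppend(buf, makeAncestor(100, seed = 3))
  contig <- makeAncestor(50, seed = 4)
  expect_true(updateReference(buf, contig, famec:::emptyMatches()))
  expect_equal(refLength(buf), 150L)
  ## fully covered contig is not appended
  m <- data.frame(start = 0L, refStart = 0L, length = 50L, rc = FALSE)
  expect_false(updateReference(buf, contig, m))
  expect_equal(refLength(buf), 150L)
})
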