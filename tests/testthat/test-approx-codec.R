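test_that("the mismatch matrix is exclusive and invertible", {
  bases <- c("A", "C", "G", "T")
  for (r in bases) {
    others <- setdiff(bases, r)
    codes <- vapply(others, function(b) mismatchCode(r, b), integer(1))
    expect_setequal(codes, 0:2)                        # exclusive
    for (b in others)
      expect_equal(rawToChar(mismatchDecode(r, mismatchCode(r, b))), b)
  }
  ## transition partner is always code 0: A<->G, C<->T
  expect_equal(mismatchCode("A", "G"), 0L)
  expect_equal(mismatchCode("G", "A"), 0L)
  expect_equal(mismatchCode("C", "T"), 0L)
  expect_equal(mismatchCode("T", "C"), 0L)
  ## non-ACGT bases take the escape code
  expect_equal(mismatchCode("A", "N"), 3L)
})

test_that("the scoring automaton follows the integer score walk", {
  ## defaults: Y=25, x=10 (10 points per base in percent terms)
  ## 8 consecutive mismatches from 25: 25+80 >= 100 terminates at base 8
  a <- scoreAutomaton(rep(FALSE, 20))
  expect_true(a$terminated)
  expect_equal(a$consumed, 8L)
  ## all matches never terminate
  a <- scoreAutomaton(rep(TRUE, 50))
  expect_false(a$terminated)
  expect_equal(a$consumed, 50L)
  ## matches pull the score back down to the floor at 0, so termination
  ## afterwards needs the full 10-mismatch climb
  eq <- c(rep(FALSE, 5), rep(TRUE, 20), rep(FALSE, 10))
  a <- scoreAutomaton(eq)
  expect_true(a$terminated)
  expect_equal(a$consumed, 35L)
})

test_that("encodeAdjacent requires a known mismatch and reports its extent", {
  ref <- paste(rep("ACGT", 10), collapse = "")
  contig <- ref
  substr(contig, 11, 11) <- "T"   # mismatch at position 11 (ref has 'G')
  e <- encodeAdjacent(contig, ref, pos = 11, refPos = 11, direction = "right")
  expect_equal(e$consumed, 1L + e$extent)
  expect_true(e$truncated)        # clean tail: span ends before the score does
  expect_equal(e$lastPos, 11L + e$extent)
  expect_error(encodeAdjacent(ref, ref, pos = 5, refPos = 5,
                              direction = "right"),
               class = "famec_usage_error")
})

test_that("encodeAdjacent honors the span limit and direction", {
  ref <- "AAAAAAAAAAAA"
  contig <- "AAAAATAAAAAA"
  e <- encodeAdjacent(contig, ref, pos = 6, refPos = 6, direction = "right",
                      spanLimit = 3)
  expect_lte(e$consumed, 3L)
  e <- encodeAdjacent(contig, ref, pos = 6, refPos = 6, direction = "left",
                      spanLimit = 4)
  expect_lte(e$consumed, 4L)
  expect_equal(e$lastPos, 6L - e$extent)
})

test_that("gap coding round-trips, with flag-free first and last bases", {
  ref <- charToRaw("ACGTACGTAC")
  contig <- charToRaw("TCGTAGGTAG")   # mismatches at 1, 6, 10
  g <- encodeGap(contig, ref)
  expect_equal(length(g$flags), 8L)   # interior bases only
  expect_equal(sum(g$flags), 1L)      # one interior mismatch
  expect_identical(decodeGap(ref, g$flags, g$lits), contig)
  ## single-base gap
  g1 <- encodeGap(charToRaw("T"), charToRaw("A"))
  expect_length(g1$flags, 0)
  expect_identical(decodeGap(charToRaw("A"), g1$flags, g1$lits), charToRaw("T"))
  ## border base equal to the reference (after match trimming) still round-trips
  g2 <- encodeGap(charToRaw("AT"), charToRaw("AA"))
  expect_identical(decodeGap(charToRaw("AA"), g2$flags, g2$lits), charToRaw("AT"))
  expect_error(encodeGap("ACG", "AC"), class = "famec_usage_error")
  expect_error(decodeGap(ref, logical(0), g$lits), class = "famec_corrupt_error")
})

test_that("encodeContig/decodeContig round-trip a single contig", {
  cfg <- CodecConfig()
  ref <- makeAncestor(3000, seed = 41)
  mdl <- MutationModel(snpRate = 0.02, seed = 42)
  contig <- mutateGenome(ref, mdl)@residues[[1]]
  buf <- newReferenceBuffer(cfg@k, cfg@sampling)
  refAppend(buf, ref)
  m <- contigMatches(buf, contig, cfg)
  expect_gt(nrow(m), 0)
  ss <- newStreamSet()
  encodeContig(contig, m, buf, cfg, ss)
  rd <- famec:::newStreamReader(ss)
  dec <- decodeContig(rd, buf, cfg)
  expect_identical(dec$contig, contig)
  expect_equal(dec$matches$refStart, m$refStart)
})

roundTripContig <- function(contig, ref, cfg) {
  buf <- newReferenceBuffer(cfg@k, cfg@sampling)
  if (length(ref)) refAppend(buf, ref)
  m <- contigMatches(buf, contig, cfg)
  ss <- newStreamSet()
  encodeContig(contig, m, buf, cfg, ss)
  rd <- famec:::newStreamReader(ss)
  decodeContig(rd, buf, cfg)$contig
}

test_that("contig round trips cover structural edge cases in every config", {
  ref <- makeAncestor(2000, seed = 51)
  cases <- list(
    identical = ref,
    unrelated = makeAncestor(500, seed = 52),
    revcomp = famec:::revComp(ref[201:900]),
    shortSeq = makeAncestor(10, seed = 53),
    empty = raw(0),
    withN = { x <- ref; x[500:540] <- charToRaw("N"); x },
    snpHeavy = mutateGenome(ref, MutationModel(snpRate = 0.1, indelRate = 0,
                                               inversionRate = 0,
                                               rearrangeRate = 0, nRunRate = 0,
                                               seed = 54))@residues[[1]])
  for (cfgName in names(allConfigs())) {
    cfg <- allConfigs()[[cfgName]]
    for (nm in names(cases)) {
      expect_identical(roundTripContig(cases[[nm]], ref, cfg), cases[[nm]],
                       label = sprintf("%s under %s", nm, cfgName))
    }
  }
})

test_that("property: randomized mutated contigs round-trip in every config", {
  set.seed(60)
  configs <- allConfigs()
  for (i in 1:12) {
    ref <- makeAncestor(sample(1000:4000, 1), gc = runif(1, 0.35, 0.6),
                        seed = 6000 + i)
    contig <- mutateGenome(ref, MutationModel(
      snpRate = runif(1, 0, 0.06), indelRate = runif(1, 0, 1e-3),
      inversionRate = runif(1, 0, 3), rearrangeRate = runif(1, 0, 1),
      nRunRate = runif(1, 0, 2), seed = 6100 + i))@residues[[1]]
    cfg <- configs[[(i %% length(configs)) + 1L]]
    expect_identical(roundTripContig(contig, ref, cfg), contig,
                     label = sprintf("random contig %d", i))
  }
})

test_that("decoding corrupted code bytes raises typed errors", {
  cfg <- CodecConfig()
  ref <- makeAncestor(1000, seed = 71)
  contig <- mutateGenome(ref, MutationModel(snpRate = 0.03, seed = 72))@residues[[1]]
  buf <- newReferenceBuffer(cfg@k, cfg@sampling)
  refAppend(buf, ref)
  m <- contigMatches(buf, contig, cfg)
  ss <- newStreamSet()
  encodeContig(contig, m, buf, cfg, ss)
  ss <- famec:::streamFinalize(ss)
  ## drop the record terminator
  ss$literals <- ss$literals[-length(ss$literals)]
  rd <- famec:::newStreamReader(ss)
  expect_error(decodeContig(rd, buf, cfg), class = "famec_corrupt_error")
})
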