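# Seeded study collections: one ancestor, genomes with SNPs, indels,
# inversions, translocations, N runs, mixed soft-masking and mixed line
# widths across files.
studyCollection <- function(seed, ancestorLength = 10000L) {
  set.seed(seed)
  nG <- sample(5:10, 1)
  anc <- makeAncestor(ancestorLength, gc = runif(1, 0.35, 0.55),
                      seed = seed + 500000L)
  lapply(seq_len(nG), function(i) {
    mdl <- if (i == 1L) {
      MutationModel(snpRate = 0, indelRate = 0, inversionRate = 0,
                    rearrangeRate = 0, nRunRate = 0, seed = seed * 100L + i)
    } else {
      MutationModel(snpRate = runif(1, 0.005, 0.05),
                    indelRate = runif(1, 1e-4, 1e-3),
                    inversionRate = runif(1, 0, 2),
                    rearrangeRate = runif(1, 0, 1),
                    nRunRate = runif(1, 0, 2),
                    seed = seed * 100L + i)
    }
    mutateGenome(anc, mdl, name = sprintf("g%03d", i),
                 nContigs = sample(1:3, 1),
                 lineWidth = sample(c(60L, 70L, 80L), 1),
                 softMask = i %% 2L == 0L)
  })
}

# Compress `files` to a fresh archive, decompress, and compare every file
# byte-for-byte. Returns the compression statistics invisibly.
expectLosslessRoundTrip <- function(files, config) {
  src <- withr_tempdir()
  writeFastaCollection(files, src)
  arc <- tempfile(fileext = ".famec")
  st <- compressCollection(src, arc, config)
  dst <- withr_tempdir()
  decompressArchive(arc, dst)
  for (p in sort(list.files(src, recursive = TRUE))) {
    a <- readBin(file.path(src, p), "raw", file.size(file.path(src, p)))
    b <- readBin(file.path(dst, p), "raw", file.size(file.path(dst, p)))
    if (!identical(a, b)) {
      testthat::fail(sprintf("byte mismatch after round trip: %s", p))
      return(invisible(st))
    }
  }
  testthat::succeed()
  unlink(c(src, dst), recursive = TRUE)
  unlink(arc)
  invisible(st)
}

# Minimal tempdir helper (no extra dependencies).
withr_tempdir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}

allConfigs <- function() list(
  full = CodecConfig(),
  noGapsDelta = CodecConfig(useGapsDelta = FALSE),
  noGapBreaks = CodecConfig(useGapBreaks = FALSE),
  noGapEncoding = CodecConfig(useGapEncoding = FALSE),
  noAdjacent = CodecConfig(useAdjacentEncoding = FALSE),
  noMatrix = CodecConfig(useMismatchMatrix = FALSE))

# The seven-match worked-example structure: matches 2, 4, 6 share one
# diagonal, matches 5 and 7 another; match 3 is short and flanked by the
# corresponding pair (2, 4).
workedExampleMatches <- function() {
  data.frame(
    start    = c(0, 310, 620, 680, 990, 1300, 1610),
    refStart = c(0, 410, 1520, 780, 1490, 1400, 2110),
    length   = c(300, 300, 50, 300, 300, 300, 300),
    rc       = rep(FALSE, 7))
}

# The scoring walk-through pair: reference of 18 bases with a match at
# positions 11-18; known mismatch at contig position 10; going right-to-left,
# matches at 9 and 6 and mismatches at 8, 7, 5, 4, 3.
scoringExamplePair <- function() {
  ref <- charToRaw("ACGTACGTACGTACGTAC")
  ref[10L] <- charToRaw("T")
  contig <- ref
  mm <- c(3L, 4L, 5L, 7L, 8L)
  contig[mm] <- as.raw(ifelse(ref[mm] == charToRaw("A"),
                              as.integer(charToRaw("C")),
                              as.integer(charToRaw("A"))))
  contig[10L] <- charToRaw("G")   # known mismatch: G against reference T
  list(contig = contig, ref = ref)
}
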