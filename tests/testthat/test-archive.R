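smallCollection <- function(seed = 301, n = 3, len = 4000) {
  makeCollection(n, MutationModel(snpRate = 0.01, seed = as.integer(seed)),
                 ancestorLength = len, lineWidth = c(60L, 70L, 80L),
                 softMask = c(FALSE, TRUE, FALSE))
}

writeSmall <- function(files) {
  d <- withr_tempdir()
  writeFastaCollection(files, d)
  d
}

test_that("compress/decompress restores every input byte-for-byte", {
  src <- writeSmall(smallCollection())
  arc <- tempfile(fileext = ".famec")
  st <- compressCollection(src, arc, CodecConfig())
  expect_equal(st$files, 3L)
  expect_gt(st$ratio, 1)
  dst <- withr_tempdir()
  decompressArchive(arc, dst)
  for (p in list.files(src, recursive = TRUE)) {
    a <- readBin(file.path(src, p), "raw", file.size(file.path(src, p)))
    b <- readBin(file.path(dst, p), "raw", file.size(file.path(dst, p)))
    expect_identical(b, a, label = p)
  }
})

test_that("listing reads metadata without decoding the sequence payload", {
  src <- writeSmall(smallCollection())
  arc <- tempfile(fileext = ".famec")
  compressCollection(src, arc, CodecConfig())
  li <- listArchive(arc)
  expect_equal(nrow(li), 3L)
  expect_setequal(li$path, c("genome001.fa", "genome002.fa", "genome003.fa"))
  expect_equal(li$bytes, as.numeric(file.size(file.path(src, li$path))))
  ## corrupt the literals payload: listing must still work, decoding must not
  ar <- famec:::.openArchive(arc)
  sec <- ar$sections$literals
  bytes <- readBin(arc, "raw", file.size(arc))
  bytes[(sec$start + 1):(sec$start + sec$size)] <-
    as.raw(rev(as.integer(bytes[(sec$start + 1):(sec$start + sec$size)])))
  bad <- tempfile(fileext = ".famec")
  writeBin(bytes, bad)
  expect_equal(listArchive(bad)$records, li$records)
  expect_error(decompressArchive(bad, withr_tempdir()),
               class = "famec_corrupt_error")
})

test_that("the stored configuration round-trips through the archive header", {
  src <- writeSmall(smallCollection())
  arc <- tempfile(fileext = ".famec")
  cfg <- CodecConfig(k = 16, minMatchLength = 20, scoreInitial = 30,
                     useAdjacentEncoding = FALSE)
  compressCollection(src, arc, cfg)
  got <- archiveConfig(arc)
  expect_equal(got@k, 16L)
  expect_equal(got@minMatchLength, 20L)
  expect_equal(got@scoreInitial, 30)
  expect_false(got@useAdjacentEncoding)
  expect_true(got@useGapsDelta)
})

test_that("selective extraction equals the matching files of a full extract", {
  src <- writeSmall(smallCollection())
  arc <- tempfile(fileext = ".famec")
  compressCollection(src, arc, CodecConfig())
  full <- withr_tempdir(); decompressArchive(arc, full)
  sel <- withr_tempdir()
  decompressArchive(arc, sel, files = "genome002.fa")
  expect_equal(list.files(sel, recursive = TRUE), "genome002.fa")
  expect_identical(
    readBin(file.path(sel, "genome002.fa"), "raw",
            file.size(file.path(sel, "genome002.fa"))),
    readBin(file.path(full, "genome002.fa"), "raw",
            file.size(file.path(full, "genome002.fa"))))
  ## glob patterns select multiple files
  sel2 <- withr_tempdir()
  decompressArchive(arc, sel2, files = "genome*.fa")
  expect_equal(sort(list.files(sel2)), sort(list.files(full)))
  expect_error(decompressArchive(arc, withr_tempdir(), files = "nosuch*"),
               class = "famec_notfound_error")
})

test_that("append-then-extract equals compressing the union directly", {
  first <- smallCollection(seed = 310, n = 2)
  more <- smallCollection(seed = 311, n = 2)
  for (i in seq_along(more)) more[[i]]@path <- sprintf("extra%03d.fa", i)
  arc <- tempfile(fileext = ".famec")
  compressCollection(first, arc, CodecConfig())
  appendToArchive(arc, more)
  dst <- withr_tempdir(); decompressArchive(arc, dst)
  expect_setequal(list.files(dst),
                  c("genome001.fa", "genome002.fa", "extra001.fa", "extra002.fa"))
  for (f in c(first, more)) {
    p <- file.path(dst, f@path)
    expect_identical(readBin(p, "raw", file.size(p)), fastaFileBytes(f),
                     label = f@path)
  }
  ## duplicate paths are rejected before any work
  expect_error(appendToArchive(arc, first), class = "famec_usage_error")
})

test_that("repacking with another configuration stays lossless", {
  src <- writeSmall(smallCollection(seed = 320))
  arc <- tempfile(fileext = ".famec")
  compressCollection(src, arc, CodecConfig())
  repackArchive(arc, CodecConfig(useGapEncoding = FALSE, useGapsDelta = FALSE))
  expect_false(archiveConfig(arc)@useGapEncoding)
  dst <- withr_tempdir(); decompressArchive(arc, dst)
  for (p in list.files(src, recursive = TRUE)) {
    expect_identical(
      readBin(file.path(dst, p), "raw", file.size(file.path(dst, p))),
      readBin(file.path(src, p), "raw", file.size(file.path(src, p))))
  }
})

test_that("fault-injected archives fail with typed errors", {
  src <- writeSmall(smallCollection(seed = 330))
  arc <- tempfile(fileext = ".famec")
  compressCollection(src, arc, CodecConfig())
  bytes <- readBin(arc, "raw", file.size(arc))

  inject <- function(mutate) {
    p <- tempfile(fileext = ".famec")
    writeBin(mutate(bytes), p)
    p
  }
  ## bad magic
  expect_error(listArchive(inject(function(b) { b[1] <- as.raw(0); b })),
               class = "famec_corrupt_error")
  ## truncation
  expect_error(decompressArchive(inject(function(b) b[1:(length(b) %/% 2)]),
                                 withr_tempdir()),
               class = "famec_corrupt_error")
  ## bit flip inside the literals payload
  sec <- famec:::.openArchive(arc)$sections$literals
  flip <- inject(function(b) { i <- sec$start + sec$size %/% 2L
                               b[i] <- xor(b[i], as.raw(0xFF)); b })
  expect_error(decompressArchive(flip, withr_tempdir()),
               class = "famec_error")
  ## missing file
  expect_error(listArchive(tempfile()), class = "famec_usage_error")
})

test_that("identical genomes barely grow the archive", {
  base <- smallCollection(seed = 340, n = 1, len = 6000)
  one <- tempfile(fileext = ".famec")
  compressCollection(base, one, CodecConfig())
  copies <- lapply(1:4, function(i) {
    f <- base[[1]]
    f@path <- sprintf("copy%03d.fa", i)
    f
  })
  five <- tempfile(fileext = ".famec")
  compressCollection(c(base, copies), five, CodecConfig())
  perCopy <- (file.size(five) - file.size(one)) / 4
  expect_lt(perCopy, 0.02 * totalBases(base[[1]]))
})

test_that("collections with empty files and odd records survive the archive", {
  d <- withr_tempdir()
  writeBin(raw(0), file.path(d, "empty.fa"))
  writeBin(charToRaw(">only header\n"), file.path(d, "header_only.fa"))
  writeBin(charToRaw(">r\nACGTacgtNNN-RY\nAC\n"), file.path(d, "mixed.fa"))
  arc <- tempfile(fileext = ".famec")
  compressCollection(d, arc, CodecConfig(k = 8, minMatchLength = 8))
  dst <- withr_tempdir(); decompressArchive(arc, dst)
  for (p in list.files(d)) {
    expect_identical(
      readBin(file.path(dst, p), "raw", file.size(file.path(dst, p))),
      readBin(file.path(d, p), "raw", file.size(file.path(d, p))), label = p)
  }
})
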