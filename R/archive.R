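## Archive container: stream serialization, whole-collection compression and
## decompression, listing, selective extraction, appending and repacking.
## The container layout is documented in docs/FORMAT.md.

ARCHIVE_MAGIC <- charToRaw("FAMC")
ARCHIVE_VERSION <- 1

## ---------------------------------------------------------------------------
## Byte cursor for metadata blocks

.newCursor <- function(bytes, pos = 0L) {
  e <- new.env(parent = emptyenv())
  e$b <- bytes
  e$pos <- pos
  e
}

.curVarint <- function(cur) {
  b <- cur$b; p <- cur$pos
  v <- 0; m <- 1
  repeat {
    if (p >= length(b)) stop(famecCorrupt("truncated archive metadata"))
    p <- p + 1L
    x <- as.integer(b[p])
    v <- v + (x %% 128L) * m
    if (x < 128L) break
    m <- m * 128
  }
  cur$pos <- p
  v
}

.curBytes <- function(cur, n) {
  if (n == 0) return(raw(0))
  if (cur$pos + n > length(cur$b)) stop(famecCorrupt("truncated archive metadata"))
  out <- cur$b[(cur$pos + 1L):(cur$pos + n)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

## ---------------------------------------------------------------------------
## Config (de)serialization

.packConfig <- function(cfg) {
  flags <- sum(c(1, 2, 4, 8, 16)[c(cfg@useGapsDelta, cfg@useGapBreaks,
                                   cfg@useGapEncoding, cfg@useAdjacentEncoding,
                                   cfg@useMismatchMatrix)])
  varintEncode(c(cfg@k, cfg@minMatchLength, cfg@sampling,
                 round(cfg@scoreInitial * 1000), cfg@scoreStepX,
                 cfg@gapBreaksMax, cfg@corrWindow,
                 round(cfg@refExtendThreshold * 1e6), cfg@refSizeCap, flags))
}

.unpackConfig <- function(cur) {
  v <- vapply(1:10, function(i) .curVarint(cur), numeric(1))
  fl <- as.integer(v[10])
  CodecConfig(k = v[1], minMatchLength = v[2], sampling = v[3],
              scoreInitial = v[4] / 1000, scoreStepX = v[5],
              gapBreaksMax = v[6], corrWindow = v[7],
              refExtendThreshold = v[8] / 1e6, refSizeCap = v[9],
              useGapsDelta = bitwAnd(fl, 1L) > 0L,
              useGapBreaks = bitwAnd(fl, 2L) > 0L,
              useGapEncoding = bitwAnd(fl, 4L) > 0L,
              useAdjacentEncoding = bitwAnd(fl, 8L) > 0L,
              useMismatchMatrix = bitwAnd(fl, 16L) > 0L)
}

## ---------------------------------------------------------------------------
## File metadata block

.packFileMeta <- function(f, rawBytes) {
  uniform <- !is.na(f@lineLength)
  parts <- list(
    varintEncode(length(charToRaw(f@path))), charToRaw(f@path),
    varintEncode(c(sum(c(1, 2, 4)[c(f@crlf, f@trailingNewline, uniform)]),
                   length(rawBytes), adler32(rawBytes),
                   length(f@headers))))
  if (uniform) {
    parts <- c(parts, list(varintEncode(f@lineLength)))
  } else {
    for (lb in f@lineBreaks)
      parts <- c(parts, list(varintEncode(c(length(lb), lb))))
  }
  for (res in f@residues) {
    m <- splitCase(res)$mask
    parts <- c(parts, list(varintEncode(c(
      length(m$lengths),
      if (length(m$lower)) as.numeric(m$lower[1L]) else 0,
      m$lengths))))
  }
  do.call(c, parts)
}

.unpackFileMeta <- function(cur) {
  pathLen <- .curVarint(cur)
  path <- rawToChar(.curBytes(cur, pathLen))
  fl <- as.integer(.curVarint(cur))
  rawSize <- .curVarint(cur)
  checksum <- .curVarint(cur)
  nRec <- as.integer(.curVarint(cur))
  uniform <- bitwAnd(fl, 4L) > 0L
  lineLength <- NA_integer_
  lineBreaks <- vector("list", nRec)
  if (uniform) {
    lineLength <- as.integer(.curVarint(cur))
  } else {
    for (r in seq_len(nRec)) {
      nL <- as.integer(.curVarint(cur))
      lineBreaks[[r]] <- as.integer(
        vapply(seq_len(nL), function(i) .curVarint(cur), numeric(1)))
    }
  }
  masks <- vector("list", nRec)
  for (r in seq_len(nRec)) {
    nRuns <- as.integer(.curVarint(cur))
    firstLower <- .curVarint(cur) > 0
    lens <- vapply(seq_len(nRuns), function(i) .curVarint(cur), numeric(1))
    lower <- if (nRuns) rep(c(firstLower, !firstLower),
                            length.out = nRuns) else logical(0)
    masks[[r]] <- list(lengths = as.integer(lens), lower = lower)
  }
  list(path = path, crlf = bitwAnd(fl, 1L) > 0L,
       trailingNewline = bitwAnd(fl, 2L) > 0L,
       rawSize = rawSize, checksum = checksum, nRecords = nRec,
       lineLength = lineLength, lineBreaks = lineBreaks, masks = masks)
}

## ---------------------------------------------------------------------------
## Stream section (de)serialization

## The flags stream is serialized as zero-run lengths between set flags
## (sparse representation): total count, number of set flags, then the
## zero-run before each set flag. Mismatch flags are rare, so this is far
## denser than bit packing, before and after the backend compressor.
.flagsToRaw <- function(v) {
  ones <- which(v)
  varintEncode(c(length(v), length(ones), diff(c(0L, ones)) - 1L))
}

.flagsFromRaw <- function(r) {
  vals <- varintDecode(r)
  if (length(vals) < 2L) {
    if (length(vals) == 0L) return(logical(0))
    stop(famecCorrupt("truncated flags stream"))
  }
  n <- vals[1L]; k <- vals[2L]
  if (length(vals) != 2L + k || k > n)
    stop(famecCorrupt("inconsistent flags stream"))
  out <- logical(n)
  if (k > 0L) {
    pos <- cumsum(vals[-(1:2)] + 1)
    if (pos[k] > n) stop(famecCorrupt("inconsistent flags stream"))
    out[pos] <- TRUE
  }
  out
}

.streamToRaw <- function(nm, v) {
  switch(nm,
         literals = , headers = , fileMeta = v,
         flags = .flagsToRaw(v),
         varintEncode(v))
}

.streamFromRaw <- function(nm, r) {
  switch(nm,
         literals = , headers = , fileMeta = r,
         flags = .flagsFromRaw(r),
         varintDecode(r))
}

## Two-bit nucleotide packing for sections dominated by ACGT bytes (the
## literals stream): the section is split into alternating runs of ACGT and
## non-ACGT bytes; ACGT runs are packed four bases per byte, the rest kept
## raw. Layout: varint total length, varint first-run-is-ACGT, varint run
## count, the run lengths as varints, then the concatenated run payloads.
.pack2bit <- function(r) {
  ok <- isACGTBytes(r)
  if (sum(ok) < 16L) return(NULL)
  rl <- rle(ok)
  lut <- integer(256)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  pieces <- vector("list", length(rl$lengths))
  pos <- 0L
  for (i in seq_along(rl$lengths)) {
    L <- rl$lengths[i]
    seg <- r[(pos + 1L):(pos + L)]
    pieces[[i]] <- if (rl$values[i]) {
      v <- c(lut[as.integer(seg) + 1L], integer((4L - L %% 4L) %% 4L))
      as.raw(colSums(matrix(v, nrow = 4L) * c(1L, 4L, 16L, 64L)))
    } else seg
    pos <- pos + L
  }
  c(varintEncode(c(length(r), as.integer(rl$values[1L]),
                   length(rl$lengths), rl$lengths)),
    do.call(c, pieces))
}

.unpack2bit <- function(p) {
  cur <- .newCursor(p)
  n <- .curVarint(cur)
  firstACGT <- .curVarint(cur) > 0
  k <- .curVarint(cur)
  if (k < 1L || k > n + 1) stop(famecCorrupt("invalid packed section header"))
  lens <- vapply(seq_len(k), function(i) .curVarint(cur), numeric(1))
  if (sum(lens) != n) stop(famecCorrupt("inconsistent packed section runs"))
  isACGT <- rep_len(c(firstACGT, !firstACGT), k)
  bases <- charToRaw("ACGT")
  out <- vector("list", k)
  for (i in seq_len(k)) {
    L <- as.integer(lens[i])
    out[[i]] <- if (isACGT[i]) {
      b <- as.integer(.curBytes(cur, (L + 3L) %/% 4L))
      q <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
      bases[q[seq_len(L)] + 1L]
    } else .curBytes(cur, L)
  }
  do.call(c, out)
}

.compressSection <- function(r) {
  if (length(r) == 0L) return(list(backend = 0L, payload = raw(0)))
  best <- list(backend = 0L, payload = r)
  consider <- function(backend, payload) {
    if (!is.null(payload) && length(payload) < length(best$payload))
      best <<- list(backend = backend, payload = payload)
  }
  consider(1L, memCompress(r, type = "xz"))
  packed <- .pack2bit(r)
  if (!is.null(packed)) {
    consider(2L, packed)
    consider(3L, memCompress(packed, type = "xz"))
  }
  best
}

.decompressSection <- function(backend, payload) {
  if (backend == 0L) return(payload)
  if (!backend %in% c(1L, 2L, 3L))
    stop(famecCorrupt("unknown stream backend"))
  if (backend %in% c(1L, 3L)) {
    payload <- tryCatch(memDecompress(payload, type = "xz"),
                        error = function(e) stop(famecCorrupt(
                          sprintf("corrupted stream payload: %s",
                                  conditionMessage(e)))))
  }
  if (backend >= 2L) payload <- .unpack2bit(payload)
  payload
}

## ---------------------------------------------------------------------------
## Archive writing

#' Write a finalized stream set to an archive file
#' @keywords internal
#' @noRd
.writeArchive <- function(ss, cfg, path) {
  ss <- streamFinalize(ss)
  parts <- list(ARCHIVE_MAGIC, varintEncode(ARCHIVE_VERSION), .packConfig(cfg))
  for (nm in STREAM_NAMES) {
    sec <- .compressSection(.streamToRaw(nm, ss[[nm]]))
    parts <- c(parts, list(as.raw(sec$backend),
                           varintEncode(length(sec$payload)), sec$payload))
  }
  bytes <- do.call(c, parts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(length(bytes))
}

#' Open an archive: parse the header and stream directory
#'
#' Stream payloads are located but not decompressed; `getStream` loads and
#' memoizes one stream on demand, so listing never touches the literals.
#' @keywords internal
#' @noRd
.openArchive <- function(path) {
  if (!file.exists(path))
    stop(famecUsage(sprintf("archive '%s' does not exist", path)))
  bytes <- readBin(path, what = "raw", n = file.size(path))
  if (length(bytes) < 5L || !identical(bytes[1:4], ARCHIVE_MAGIC))
    stop(famecCorrupt(sprintf("'%s' is not an archive (bad magic)", path)))
  cur <- .newCursor(bytes, pos = 4L)
  ver <- .curVarint(cur)
  if (ver != ARCHIVE_VERSION)
    stop(famecCorrupt(sprintf("unsupported archive version %d", ver)))
  cfg <- .unpackConfig(cur)
  sections <- vector("list", length(STREAM_NAMES))
  names(sections) <- STREAM_NAMES
  for (nm in STREAM_NAMES) {
    backend <- as.integer(.curBytes(cur, 1L))
    n <- .curVarint(cur)
    if (cur$pos + n > length(bytes))
      stop(famecCorrupt(sprintf("archive '%s' is truncated", path)))
    sections[[nm]] <- list(backend = backend, start = cur$pos, size = n)
    cur$pos <- cur$pos + as.integer(n)
  }
  e <- new.env(parent = emptyenv())
  e$path <- path
  e$bytes <- bytes
  e$config <- cfg
  e$sections <- sections
  e$loaded <- new.env(parent = emptyenv())
  e$getStream <- function(nm) {
    if (!is.null(e$loaded[[nm]])) return(e$loaded[[nm]])
    sec <- e$sections[[nm]]
    payload <- if (sec$size) e$bytes[(sec$start + 1L):(sec$start + sec$size)]
               else raw(0)
    v <- .streamFromRaw(nm, .decompressSection(sec$backend, payload))
    e$loaded[[nm]] <- v
    v
  }
  e
}

.archiveMeta <- function(ar) {
  fm <- ar$getStream("fileMeta")
  cur <- .newCursor(fm)
  metas <- list()
  while (cur$pos < length(fm))
    metas[[length(metas) + 1L]] <- .unpackFileMeta(cur)
  metas
}

.splitHeaders <- function(h, nRecords) {
  if (nRecords == 0L) {
    if (length(h)) stop(famecCorrupt("dangling header bytes"))
    return(character(0))
  }
  nl <- which(h == as.raw(0x0A))
  if (length(nl) != nRecords || nl[length(nl)] != length(h))
    stop(famecCorrupt("header stream does not match the record count"))
  starts <- c(1L, nl[-length(nl)] + 1L)
  vapply(seq_len(nRecords), function(r) {
    if (nl[r] > starts[r]) rawToChar(h[starts[r]:(nl[r] - 1L)]) else ""
  }, character(1))
}

## ---------------------------------------------------------------------------
## Public API

#' Compress a FASTA collection into an archive
#'
#' Encodes every record of every input file against a shared, growing
#' reference buffer and writes a single archive file. Input files are
#' restored byte-for-byte on decompression (line wrapping, letter case,
#' line-ending style and trailing newline included).
#'
#' @param input a directory, a character vector of FASTA paths, or a list of
#'   [FastaFile-class] objects.
#' @param archive output archive path.
#' @param config a [CodecConfig-class].
#' @return invisibly, a list of statistics: `files`, `records`,
#'   `inputBytes`, `archiveBytes`, `ratio`, `referenceBases` and per-stream
#'   element counts in `streams`.
#' @examples
#' tmp <- tempfile(); dir.create(tmp)
#' writeLines(c(">r1", "ACGTACGTAGA"), file.path(tmp, "a.fa"))
#' arc <- tempfile(fileext = ".famec")
#' compressCollection(tmp, arc, CodecConfig(k = 8, minMatchLength = 8))
#' listArchive(arc)
#' @export
compressCollection <- function(input, archive, config = CodecConfig()) {
  files <- if (is.character(input)) readFastaCollection(input) else input
  if (!length(files)) stop(famecUsage("no input files"))
  paths <- vapply(files, function(f) f@path, character(1))
  if (anyDuplicated(paths))
    stop(famecUsage(sprintf("duplicate path in the collection: '%s'",
                            paths[duplicated(paths)][1L])))
  ss <- newStreamSet()
  buf <- newReferenceBuffer(config@k, config@sampling)
  nRecords <- 0L
  inputBytes <- 0
  for (f in files) {
    fb <- fastaFileBytes(f)
    inputBytes <- inputBytes + length(fb)
    streamPut(ss, "fileMeta", .packFileMeta(f, fb))
    for (r in seq_along(f@headers)) {
      streamPut(ss, "headers", c(charToRaw(f@headers[r]), as.raw(0x0A)))
      contig <- splitCase(f@residues[[r]])$residues
      m <- contigMatches(buf, contig, config)
      encodeContig(contig, m, buf, config, ss)
      updateReference(buf, contig, m, config@refExtendThreshold,
                      config@refSizeCap)
      nRecords <- nRecords + 1L
    }
  }
  archiveBytes <- .writeArchive(ss, config, archive)
  invisible(list(files = length(files), records = nRecords,
                 inputBytes = inputBytes, archiveBytes = archiveBytes,
                 ratio = inputBytes / archiveBytes,
                 referenceBases = refLength(buf),
                 streams = as.list(streamSizes(ss))))
}

#' Decode every file of an archive into FastaFile objects
#' @keywords internal
#' @noRd
.decodeFiles <- function(ar, verify = TRUE) {
  cfg <- ar$config
  metas <- .archiveMeta(ar)
  nTotal <- sum(vapply(metas, function(m) m$nRecords, integer(1)))
  headers <- .splitHeaders(ar$getStream("headers"), nTotal)
  ss <- newStreamSet()
  for (nm in setdiff(STREAM_NAMES, c("headers", "fileMeta")))
    streamPut(ss, nm, ar$getStream(nm))
  rd <- newStreamReader(ss)
  buf <- newReferenceBuffer(cfg@k, cfg@sampling)
  files <- vector("list", length(metas))
  hi <- 0L
  for (i in seq_along(metas)) {
    mt <- metas[[i]]
    residues <- vector("list", mt$nRecords)
    for (r in seq_len(mt$nRecords)) {
      d <- decodeContig(rd, buf, cfg)
      updateReference(buf, d$contig, d$matches, cfg@refExtendThreshold,
                      cfg@refSizeCap)
      residues[[r]] <- applyCaseMask(d$contig, mt$masks[[r]])
    }
    f <- new("FastaFile", path = mt$path,
             headers = headers[hi + seq_len(mt$nRecords)],
             residues = residues, lineLength = mt$lineLength,
             lineBreaks = mt$lineBreaks, crlf = mt$crlf,
             trailingNewline = mt$trailingNewline)
    hi <- hi + mt$nRecords
    if (verify) {
      fb <- fastaFileBytes(f)
      if (length(fb) != mt$rawSize || adler32(fb) != mt$checksum)
        stop(famecCorrupt(sprintf(
          "checksum mismatch for '%s': the archive is corrupted", mt$path)))
    }
    files[[i]] <- f
  }
  for (nm in c("literals", "offsets", "lengths", "gapsDelta", "flags",
               "truncations"))
    if (readerRemaining(rd, nm) > 0)
      stop(famecCorrupt(sprintf("trailing data in the '%s' stream", nm)))
  files
}

#' Decompress an archive
#'
#' Restores files byte-for-byte and verifies each against its stored
#' checksum. With `files`, only matching paths are written (glob patterns
#' are allowed); decoding still replays the whole archive, as the shared
#' reference is built from all records in order.
#'
#' @param archive archive path.
#' @param destination output directory (created if needed).
#' @param files optional character vector of paths or glob patterns.
#' @return invisibly, the written paths.
#' @export
decompressArchive <- function(archive, destination, files = NULL) {
  ar <- .openArchive(archive)
  decoded <- .decodeFiles(ar)
  if (!is.null(files)) {
    paths <- vapply(decoded, function(f) f@path, character(1))
    rx <- paste0("(", paste(utils::glob2rx(files), collapse = ")|("), ")")
    keep <- grepl(rx, paths)
    if (!any(keep))
      stop(famecNotFound(sprintf(
        "no archived file matches '%s'", paste(files, collapse = "', '"))))
    decoded <- decoded[keep]
  }
  writeFastaCollection(decoded, destination)
}

#' List the contents of an archive
#'
#' Reads only the metadata streams; the sequence payload is not decoded.
#'
#' @param archive archive path.
#' @return data.frame with one row per file: `path`, `records`, `bytes`,
#'   `lineLength` (NA when irregular), `crlf`.
#' @export
listArchive <- function(archive) {
  ar <- .openArchive(archive)
  metas <- .archiveMeta(ar)
  data.frame(
    path = vapply(metas, function(m) m$path, character(1)),
    records = vapply(metas, function(m) m$nRecords, integer(1)),
    bytes = vapply(metas, function(m) m$rawSize, numeric(1)),
    lineLength = vapply(metas, function(m) m$lineLength, integer(1)),
    crlf = vapply(metas, function(m) m$crlf, logical(1)))
}

#' Codec configuration stored in an archive
#' @param archive archive path.
#' @return the [CodecConfig-class] the archive was written with.
#' @export
archiveConfig <- function(archive) .openArchive(archive)$config

#' Append files to an existing archive
#'
#' Decodes the archive, verifies it, and re-encodes the union with the new
#' files appended, using the archive's stored configuration. Duplicate
#' paths are rejected before any work is redone.
#'
#' @param archive archive path (rewritten in place).
#' @param input new files: a directory, paths, or [FastaFile-class] objects.
#' @return invisibly, the statistics of the rewritten archive.
#' @export
appendToArchive <- function(archive, input) {
  ar <- .openArchive(archive)
  newFiles <- if (is.character(input)) readFastaCollection(input) else input
  if (!length(newFiles)) stop(famecUsage("no input files"))
  metas <- .archiveMeta(ar)
  oldPaths <- vapply(metas, function(m) m$path, character(1))
  newPaths <- vapply(newFiles, function(f) f@path, character(1))
  clash <- c(newPaths[newPaths %in% oldPaths], newPaths[duplicated(newPaths)])
  if (length(clash))
    stop(famecUsage(sprintf("path already in the archive: '%s'", clash[1L])))
  decoded <- .decodeFiles(ar)
  compressCollection(c(decoded, newFiles), archive, ar$config)
}

#' Re-encode an archive with a different configuration
#'
#' @param archive archive path (rewritten in place).
#' @param config the new [CodecConfig-class].
#' @return invisibly, the statistics of the rewritten archive.
#' @export
repackArchive <- function(archive, config = CodecConfig()) {
  ar <- .openArchive(archive)
  decoded <- .decodeFiles(ar)
  compressCollection(decoded, archive, config)
}
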