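## FASTA reading/writing with byte-exact restoration: line widths, letter
## case, CRLF style, trailing newline and relative paths are all captured.

.lowerTable <- local({
  tab <- as.raw(0:255)
  up <- as.integer(charToRaw("A")):as.integer(charToRaw("Z"))
  tab[up + 1L] <- as.raw(up + 32L)
  tab
})

#' Split a residue vector into uppercase residues and a case mask
#'
#' The case mask is a minimal run-length encoding of lowercase (soft-masked)
#' stretches; applying it to the uppercased residues restores the original
#' bytes exactly.
#'
#' @param residues raw vector (or character scalar) of residues.
#' @return list with `residues` (uppercased raw vector) and `mask`, a list
#'   with integer `lengths` and logical `lower` of equal length.
#' @examples
#' splitCase(charToRaw("acgT"))
#' @export
splitCase <- function(residues) {
  if (is.character(residues)) residues <- charToRaw(residues)
  lw <- isLowerBytes(residues)
  if (length(lw) == 0L) {
    mask <- list(lengths = integer(0), lower = logical(0))
  } else {
    r <- rle(lw)
    mask <- list(lengths = r$lengths, lower = r$values)
  }
  list(residues = upperBytes(residues), mask = mask)
}

#' Re-apply a case mask to uppercased residues
#'
#' @param residues uppercased raw vector.
#' @param mask case mask as produced by [splitCase()].
#' @return raw vector with the original letter case.
#' @export
applyCaseMask <- function(residues, mask) {
  if (sum(mask$lengths) != length(residues))
    stop(famecCorrupt("case mask does not cover the record"))
  if (!any(mask$lower)) return(residues)
  lw <- rep(mask$lower, mask$lengths)
  residues[lw] <- .lowerTable[as.integer(residues[lw]) + 1L]
  residues
}

## ---------------------------------------------------------------------------

#' Detect the uniform line width of a file, if any
#'
#' Uniform means re-wrapping every record at width L reproduces the original
#' line structure: all non-terminal lines equal L, every record-terminal line
#' is in [1, L], and records without residues have no sequence lines.
#' @param lineBreaks list of integer vectors (per-record line lengths).
#' @return integer width, or NA if irregular.
#' @keywords internal
#' @noRd
detectLineLength <- function(lineBreaks) {
  nonTerm <- unlist(lapply(lineBreaks, function(b)
    if (length(b) > 1L) b[-length(b)] else integer(0)), use.names = FALSE)
  term <- unlist(lapply(lineBreaks, function(b)
    if (length(b) >= 1L) b[length(b)] else integer(0)), use.names = FALSE)
  nEmptyRecLines <- any(vapply(lineBreaks, function(b)
    length(b) == 1L && b[1L] == 0L, logical(1)))
  if (nEmptyRecLines || any(term == 0L)) return(NA_integer_)
  if (length(nonTerm)) {
    Ls <- unique(nonTerm)
    if (length(Ls) != 1L) return(NA_integer_)
    L <- Ls
    if (any(term > L)) return(NA_integer_)
    ## records must wrap canonically: guaranteed by the two rules above
    return(as.integer(L))
  }
  if (length(term) == 0L) return(NA_integer_)   # no sequence lines at all
  as.integer(max(term))
}

#' Read one FASTA file, capturing formatting metadata
#'
#' @param path path of the file on disk.
#' @param relPath relative path recorded in the collection (defaults to
#'   `basename(path)`).
#' @return a [FastaFile-class] object.
#' @export
readFastaFile <- function(path, relPath = basename(path)) {
  if (!file.exists(path))
    stop(famecUsage(sprintf("input file '%s' does not exist", path)))
  bytes <- readBin(path, what = "raw", n = file.size(path))
  parseFastaBytes(bytes, relPath, origin = path)
}

#' Parse FASTA bytes into a FastaFile
#' @keywords internal
#' @noRd
parseFastaBytes <- function(bytes, relPath, origin = relPath) {
  NL <- as.raw(0x0A); CR <- as.raw(0x0D); GT <- as.raw(0x3E)
  n <- length(bytes)
  if (n == 0L) {
    return(new("FastaFile", path = relPath, headers = character(0),
               residues = list(), lineLength = NA_integer_,
               lineBreaks = list(), crlf = FALSE, trailingNewline = FALSE))
  }
  nl <- which(bytes == NL)
  crPos <- which(bytes == CR)
  crlf <- length(crPos) > 0L
  if (crlf) {
    ## every CR must immediately precede an LF, and every LF follow a CR
    if (!identical(crPos, nl - 1L) || any(nl == 1L))
      stop(famecMalformed(sprintf(
        "file '%s': inconsistent or stray CR bytes (mixed line endings are not supported)",
        origin)))
  }
  trailingNewline <- bytes[n] == NL
  lineStarts <- c(1L, nl + 1L)
  lineEnds <- c(nl - 1L - if (crlf) 1L else 0L, n)
  if (trailingNewline) {
    lineStarts <- lineStarts[-length(lineStarts)]
    lineEnds <- lineEnds[-length(lineEnds)]
  }
  if (bytes[1L] != GT)
    stop(famecMalformed(sprintf(
      "file '%s': malformed FASTA, expected '>' at byte offset 0", origin)))

  isHeader <- bytes[lineStarts] == GT & lineStarts <= lineEnds
  recIdx <- cumsum(isHeader)
  headers <- character(sum(isHeader))
  residues <- vector("list", sum(isHeader))
  lineBreaks <- vector("list", sum(isHeader))
  hIdx <- which(isHeader)
  for (r in seq_along(hIdx)) {
    hs <- lineStarts[hIdx[r]]; he <- lineEnds[hIdx[r]]
    headers[r] <- if (he >= hs + 1L) rawToChar(bytes[(hs + 1L):he]) else ""
    seqLines <- which(recIdx == r & !isHeader)
    lens <- pmax(0L, lineEnds[seqLines] - lineStarts[seqLines] + 1L)
    lineBreaks[[r]] <- as.integer(lens)
    if (length(seqLines)) {
      idx <- unlist(Map(function(s, e) if (e >= s) s:e else integer(0),
                        lineStarts[seqLines], lineEnds[seqLines]),
                    use.names = FALSE)
      residues[[r]] <- bytes[idx]
    } else {
      residues[[r]] <- raw(0)
    }
  }
  new("FastaFile", path = relPath, headers = headers, residues = residues,
      lineLength = detectLineLength(lineBreaks), lineBreaks = lineBreaks,
      crlf = crlf, trailingNewline = trailingNewline)
}

#' Read a FASTA collection
#'
#' Accepts individual file paths and/or directories (directories are walked
#' recursively; files are taken in sorted order for determinism). Relative
#' paths inside the collection are taken against `root` when given, against
#' the directory itself for a single-directory input, and default to the
#' basename otherwise.
#'
#' @param paths character vector of files and/or directories.
#' @param root optional root directory for relative paths.
#' @return list of [FastaFile-class] objects in input order.
#' @examples
#' tmp <- tempfile(); dir.create(tmp)
#' writeLines(c(">r1", "ACGTAC"), file.path(tmp, "a.fa"))
#' fls <- readFastaCollection(tmp)
#' recordSequences(fls[[1]])
#' @export
readFastaCollection <- function(paths, root = NULL) {
  if (is.null(root) && length(paths) == 1L && dir.exists(paths))
    root <- paths
  expanded <- character(0)
  for (p in paths) {
    if (dir.exists(p)) {
      fs <- sort(list.files(p, recursive = TRUE, full.names = TRUE))
      expanded <- c(expanded, fs)
    } else {
      expanded <- c(expanded, p)
    }
  }
  if (!length(expanded))
    stop(famecUsage("no input files found"))
  lapply(expanded, function(p) {
    rel <- if (!is.null(root)) {
      rootNorm <- normalizePath(root, winslash = "/", mustWork = TRUE)
      pNorm <- normalizePath(p, winslash = "/", mustWork = TRUE)
      if (startsWith(pNorm, paste0(rootNorm, "/")))
        substring(pNorm, nchar(rootNorm) + 2L)
      else basename(p)
    } else basename(p)
    readFastaFile(p, rel)
  })
}

#' Serialize a FastaFile back to its exact on-disk bytes
#'
#' @param x a [FastaFile-class].
#' @return raw vector.
#' @export
fastaFileBytes <- function(x) {
  eol <- if (x@crlf) charToRaw("\r\n") else as.raw(0x0A)
  chunks <- vector("list", 0L)
  k <- 0L
  put <- function(v) { k <<- k + 1L; chunks[[k]] <<- v }
  nRec <- length(x@headers)
  for (r in seq_len(nRec)) {
    put(charToRaw(paste0(">", x@headers[r])))
    put(eol)
    res <- x@residues[[r]]
    lens <- if (is.na(x@lineLength)) x@lineBreaks[[r]] else {
      len <- length(res)
      if (len == 0L) integer(0) else {
        q <- len %/% x@lineLength
        rem <- len %% x@lineLength
        c(rep(x@lineLength, q), if (rem) rem)
      }
    }
    if (sum(lens) != length(res))
      stop(famecCorrupt(sprintf(
        "file '%s' record %d: line breaks do not cover the residues",
        x@path, r)))
    pos <- 0L
    for (L in lens) {
      if (L > 0L) put(res[(pos + 1L):(pos + L)])
      put(eol)
      pos <- pos + L
    }
  }
  out <- if (k) do.call(c, chunks[seq_len(k)]) else raw(0)
  if (!x@trailingNewline && length(out) >= length(eol))
    out <- out[seq_len(length(out) - length(eol))]
  out
}

#' Write a FASTA collection to a destination directory
#'
#' Files read by [readFastaCollection()] are reproduced byte-for-byte.
#' Paths are confined to the destination root (no traversal).
#'
#' @param files list of [FastaFile-class] objects.
#' @param destination directory to write into (created if needed).
#' @return character vector of written paths (invisibly).
#' @export
writeFastaCollection <- function(files, destination) {
  if (!dir.exists(destination))
    dir.create(destination, recursive = TRUE)
  destNorm <- normalizePath(destination, winslash = "/", mustWork = TRUE)
  written <- character(length(files))
  for (i in seq_along(files)) {
    f <- files[[i]]
    rel <- f@path
    if (grepl("^([A-Za-z]:)?[/\\\\]", rel) ||
        any(strsplit(rel, "[/\\\\]")[[1]] == ".."))
      stop(famecUsage(sprintf(
        "refusing to write outside the destination root: '%s'", rel)))
    out <- file.path(destNorm, rel)
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    outNorm <- normalizePath(dirname(out), winslash = "/", mustWork = TRUE)
    if (!startsWith(paste0(outNorm, "/"), paste0(destNorm, "/")))
      stop(famecUsage(sprintf(
        "refusing to write outside the destination root: '%s'", rel)))
    writeBin(fastaFileBytes(f), out)
    written[i] <- out
  }
  invisible(written)
}
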