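## Reference buffer and maximal-exact-match finding. The buffer is an
## append-only ACGT string with a sampled k-mer position index; matches are
## found by k-mer anchoring, grouping anchors by diagonal, and taking maximal
## equality runs along each diagonal (both strands).

#' Append-only reference buffer with a k-mer position index
#'
#' @slot state environment holding the bases, the index and bookkeeping;
#'   environment-backed because the buffer grows in place during encoding.
#' @export
setClass("ReferenceBuffer", representation(state = "environment"))

#' Create an empty reference buffer
#'
#' @param k k-mer anchor length (>= 8).
#' @param sampling index every `sampling`-th reference position.
#' @return a [ReferenceBuffer-class].
#' @examples
#' buf <- newReferenceBuffer(k = 8)
#' refAppend(buf, charToRaw("ACGTACGTACGT"))
#' refLength(buf)
#' @export
newReferenceBuffer <- function(k = 24L, sampling = 1L) {
  k <- as.integer(k); sampling <- as.integer(sampling)
  if (k < 8L) stop(famecUsage("k must be >= 8"))
  if (k > 26L) stop(famecUsage("k must be <= 26 (packed keys are exact doubles)"))
  if (sampling < 1L) stop(famecUsage("sampling must be >= 1"))
  st <- new.env(parent = emptyenv())
  st$bases <- raw(0)
  st$len <- 0L
  st$k <- k
  st$sampling <- sampling
  st$keys <- numeric(0)   # packed k-mer keys, sorted (2 bits/base, exact in doubles)
  st$pos <- numeric(0)    # 0-based reference positions, aligned with keys
  st$nIndexed <- 0L
  st$nextGrid <- 0L       # first grid position not yet considered (0-based)
  new("ReferenceBuffer", state = st)
}

setMethod("show", "ReferenceBuffer", function(object) {
  st <- object@state
  cat(sprintf("ReferenceBuffer: %d bases, k=%d sampling=%d, %d indexed positions\n",
              st$len, st$k, st$sampling, st$nIndexed))
})

#' Current length of a reference buffer
#' @param buf a [ReferenceBuffer-class].
#' @return integer number of bases.
#' @export
refLength <- function(buf) buf@state$len

#' Bases of a reference buffer
#' @param buf a [ReferenceBuffer-class].
#' @param from,to 1-based inclusive range (defaults to the whole buffer).
#' @return raw vector.
#' @export
refSequence <- function(buf, from = 1L, to = refLength(buf)) {
  if (to < from) return(raw(0))
  buf@state$bases[from:to]
}

#' Number of indexed k-mer positions
#' @param buf a [ReferenceBuffer-class].
#' @return integer.
#' @export
indexedPositionCount <- function(buf) buf@state$nIndexed

#' Append bases to the reference buffer and extend its index
#'
#' Bases are uppercased; with `mapACGT = TRUE` (the default, used by the
#' codec) non-ACGT bytes are mapped to 'A' so the buffer alphabet stays
#' {A,C,G,T}. Every grid position whose k-mer window is ACGT-only is indexed.
#'
#' @param buf a [ReferenceBuffer-class].
#' @param bytes raw vector (or character) of residues.
#' @param mapACGT map non-ACGT bytes to 'A' before appending.
#' @param sizeCap hard cap on the resulting buffer length.
#' @return the buffer, invisibly.
#' @export
refAppend <- function(buf, bytes, mapACGT = TRUE, sizeCap = 2^31 - 1) {
  if (is.character(bytes)) bytes <- charToRaw(bytes)
  if (!length(bytes)) return(invisible(buf))
  st <- buf@state
  bytes <- upperBytes(bytes)
  if (mapACGT) bytes <- acgtMapBytes(bytes)
  if (st$len + length(bytes) > sizeCap)
    stop(famecUsage(sprintf(
      "reference buffer would exceed the configured cap (%.0f bases); raise the cap",
      sizeCap)))
  st$bases <- c(st$bases, bytes)
  st$len <- length(st$bases)
  extendKmerIndex(st)
  invisible(buf)
}

.kmerCodeTable <- local({
  tab <- numeric(256)
  tab[as.integer(charToRaw("CGT")) + 1L] <- 1:3
  tab
})

#' Packed numeric k-mer keys of every clean window of a byte vector
#'
#' Keys pack 2 bits per base (A=0, C=1, G=2, T=3, big-endian), exact in
#' doubles for k <= 26. Windows containing non-ACGT bytes are dropped.
#' @return list with `pos0` (0-based window starts) and `keys`.
#' @keywords internal
#' @noRd
.windowKeys <- function(bytes, k) {
  n <- length(bytes)
  m <- n - k + 1L
  if (m < 1L) return(list(pos0 = integer(0), keys = numeric(0)))
  code <- .kmerCodeTable[as.integer(bytes) + 1L]
  keys <- numeric(m)
  for (j in seq_len(k)) keys <- keys * 4 + code[j:(j + m - 1L)]
  bad <- cumsum(c(0L, !isACGTBytes(bytes)))
  clean <- bad[seq_len(m) + k] == bad[seq_len(m)]
  list(pos0 = which(clean) - 1L, keys = keys[clean])
}

#' Index all complete grid k-mers not yet indexed
#'
#' The index is a pair of aligned vectors (sorted packed keys, positions);
#' lookups are binary searches via findInterval. Numeric keys avoid interning
#' k-mer strings as R symbols, which would grow the symbol table (and garbage
#' collection cost) without bound across many collections in one process.
#' @keywords internal
#' @noRd
extendKmerIndex <- function(st) {
  k <- st$k; s <- st$sampling
  lastStart <- st$len - k              # 0-based last valid start
  if (lastStart < st$nextGrid) return(invisible(NULL))
  first <- st$nextGrid
  st$nextGrid <- first + ((lastStart - first) %/% s + 1L) * s
  lo <- first + 1L
  w <- .windowKeys(st$bases[lo:st$len], k)
  abs <- first + w$pos0
  keep <- abs <= lastStart & (abs %% s) == 0
  if (!any(keep)) return(invisible(NULL))
  newKeys <- w$keys[keep]
  newPos <- abs[keep]
  o <- order(newKeys, newPos, method = "radix")
  if (length(st$keys)) {
    allKeys <- c(st$keys, newKeys[o])
    allPos <- c(st$pos, newPos[o])
    o2 <- order(allKeys, allPos, method = "radix")
    st$keys <- allKeys[o2]
    st$pos <- allPos[o2]
  } else {
    st$keys <- newKeys[o]
    st$pos <- newPos[o]
  }
  st$nIndexed <- length(st$keys)
  invisible(NULL)
}

#' Empty match table
#' @keywords internal
#' @noRd
emptyMatches <- function() {
  data.frame(start = integer(0), refStart = integer(0),
             length = integer(0), rc = logical(0))
}

#' Canonical deterministic match ordering
#' @keywords internal
#' @noRd
orderMatches <- function(m) {
  m[order(m$start, -m$length, m$refStart, m$rc), , drop = FALSE]
}

#' Find maximal exact matches of a contig against the reference
#'
#' Returns all maximal matches of at least `minLen` bases on both strands
#' (reverse-complement hits are reported in forward contig coordinates:
#' the contig segment equals the reverse complement of the reference
#' segment). Maximality is relative to sequence bounds and the ACGT
#' alphabet: non-ACGT bytes break matches. Coordinates are 0-based.
#'
#' @param buf a [ReferenceBuffer-class] with `k <= minLen`.
#' @param contig raw vector (or character) of uppercased residues.
#' @param minLen minimum match length.
#' @param bothStrands also scan the reverse complement.
#' @return data.frame with columns `start`, `refStart`, `length`, `rc`,
#'   sorted by contig start (ties: longer, lower reference start, forward
#'   strand first).
#' @export
findMems <- function(buf, contig, minLen = buf@state$k, bothStrands = TRUE) {
  if (is.character(contig)) contig <- charToRaw(contig)
  st <- buf@state
  if (minLen < st$k)
    stop(famecUsage("minLen must be >= the index k"))
  out <- scanStrand(st, contig, minLen, rc = FALSE)
  if (bothStrands) {
    rcHits <- scanStrand(st, revComp(contig), minLen, rc = TRUE)
    if (nrow(rcHits)) {
      n <- length(contig)
      rcHits$start <- n - (rcHits$start + rcHits$length)
      out <- rbind(out, rcHits)
    }
  }
  orderMatches(out)
}

#' Scan one strand of a query against the indexed reference
#' @keywords internal
#' @noRd
scanStrand <- function(st, q, minLen, rc) {
  nq <- length(q)
  k <- st$k
  if (nq < k || st$len < k || !length(st$keys)) return(emptyMatches())
  w <- .windowKeys(q, k)
  if (!length(w$keys)) return(emptyMatches())
  hi <- findInterval(w$keys, st$keys)
  lo <- findInterval(w$keys - 0.5, st$keys)
  nh <- hi - lo
  has <- nh > 0L
  if (!any(has)) return(emptyMatches())
  qAll <- rep.int(w$pos0[has], nh[has])
  rAll <- st$pos[sequence(nh[has]) + rep.int(lo[has], nh[has])]
  diags <- unique(rAll - qAll)

  qACGT <- isACGTBytes(q)
  refBytes <- st$bases
  refACGT <- isACGTBytes(refBytes)
  s <- st$sampling
  res <- vector("list", length(diags))
  for (i in seq_along(diags)) {
    d <- diags[i]
    cs <- max(0L, -d)                       # 0-based contig overlap start
    ce <- min(nq, st$len - d)               # exclusive
    if (ce - cs < minLen) next
    cIdx <- (cs + 1L):ce
    rIdx <- cIdx + d
    eq <- (q[cIdx] == refBytes[rIdx]) & qACGT[cIdx] & refACGT[rIdx]
    r <- rle(eq)
    if (!any(r$values & r$lengths >= minLen)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minLen
    runS <- cs + starts[keep] - 1L          # 0-based contig start
    runL <- r$lengths[keep]
    if (s > 1L) {
      ## anchored finder only sees runs containing an indexed grid k-mer
      rs <- runS + d
      re <- rs + runL - k
      vis <- (re %/% s) * s >= rs
      runS <- runS[vis]; runL <- runL[vis]
    }
    if (!length(runS)) next
    res[[i]] <- data.frame(start = runS, refStart = runS + d,
                           length = runL, rc = rc)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(emptyMatches())
  do.call(rbind, res)
}

#' Greedily select a non-overlapping ordered subset of matches
#'
#' Left-to-right greedy selection preferring the longest match starting
#' earliest; later matches overlapping the chosen one are trimmed on the
#' contig side and dropped if they fall below `minLen`. Ties are broken by
#' lower reference start, forward strand first.
#'
#' @param mems match data.frame from [findMems()] (sorted by contig start).
#' @param minLen minimum match length kept after trimming.
#' @return match data.frame with pairwise-disjoint contig intervals.
#' @export
selectMatches <- function(mems, minLen) {
  if (nrow(mems) == 0L) return(mems)
  m <- mems
  picked <- vector("list", nrow(m))
  np <- 0L
  cur <- 0L
  repeat {
    trim <- pmax(0L, cur - m$start)
    len <- m$length - trim
    alive <- len >= minLen
    if (!any(alive)) break
    m <- m[alive, , drop = FALSE]
    trim <- trim[alive]; len <- len[alive]
    st <- m$start + trim
    rs <- m$refStart + ifelse(m$rc, 0L, trim)
    o <- order(st, -len, rs, m$rc)[1L]
    np <- np + 1L
    picked[[np]] <- data.frame(start = st[o], refStart = rs[o],
                               length = len[o], rc = m$rc[o])
    cur <- st[o] + len[o]
    m <- m[-o, , drop = FALSE]
    if (nrow(m) == 0L) break
  }
  if (np == 0L) return(emptyMatches())
  do.call(rbind, picked[seq_len(np)])
}

#' Aligned fraction of a contig given its final match list
#'
#' Counts match bases plus the bases of every nonempty junction flanked by
#' two forward matches on the same diagonal: such regions align base-for-base
#' with the reference (they are the gap-coded regions), so they contribute to
#' similarity even though the gap-breaks filter removed their inner matches.
#'
#' @param matches final match data.frame.
#' @param n contig length in bases.
#' @return fraction in [0, 1].
#' @export
alignedCoverage <- function(matches, n) {
  if (n == 0L) return(0)
  covered <- sum(matches$length)
  m <- nrow(matches)
  if (m >= 2L) {
    gapLen <- matches$start[-1L] - (matches$start[-m] + matches$length[-m])
    diag <- matches$refStart - matches$start
    aligned <- gapLen > 0 & !matches$rc[-m] & !matches$rc[-1L] &
      diag[-m] == diag[-1L]
    covered <- covered + sum(gapLen[aligned])
  }
  covered / n
}

#' Extend the reference with a contig if its aligned coverage is low
#'
#' A contig whose aligned fraction (see [alignedCoverage()]) is strictly
#' below the threshold is appended (uppercased, non-ACGT mapped to 'A').
#' The decision is a pure function of the final matches and the contig
#' length, so the decoder replays it identically.
#'
#' @param buf a [ReferenceBuffer-class].
#' @param contig raw vector of uppercased residues.
#' @param selected final (selected, filtered) match data.frame.
#' @param threshold dissimilarity threshold (default 0.5).
#' @param sizeCap hard cap on reference length.
#' @return `TRUE` if the contig was appended.
#' @export
updateReference <- function(buf, contig, selected, threshold = 0.5,
                            sizeCap = 2^31 - 1) {
  if (is.character(contig)) contig <- charToRaw(contig)
  n <- length(contig)
  if (n == 0L) return(FALSE)
  coverage <- alignedCoverage(selected, n)
  if (coverage < threshold) {
    refAppend(buf, contig, mapACGT = TRUE, sizeCap = sizeCap)
    TRUE
  } else {
    FALSE
  }
}
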