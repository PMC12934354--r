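## Approximate-match encoder/decoder: exclusive mismatch encoding matrix,
## encoding in gaps, score-bounded adjacent encoding, and the per-contig
## literal-stream grammar.
##
## Literal grammar per record (all sentinel bytes disjoint from residues):
##   record   := region? (MATCH region?)* SEQ_MARK
##   MATCH    := MATCH_MARK                      ; span from lengths stream
##   region   := GAP | open
##   GAP      := codes*                          ; length L from the truncations
##                                               ; entry; first and last base
##                                               ; coded without flags, one flag
##                                               ; per interior base (L - 2)
##   open     := RA? LA? rawbyte*
##   RA,LA    := knowncode codes*                ; LA detected by its code byte
##   code     := 0x00..0x02 | 0x03 rawbyte       ; 0x03 escapes non-ACGT bases
## Every non-empty region that follows a match consumes one truncations
## entry e: 0 = open region without RA; odd e = gap region of (e - 1) / 2
## bases; even e >= 2 = open region with an RA block of e / 2 - 1 scored
## bases. Raw bytes colliding with sentinels are escaped with LIT_ESCAPE;
## GAP_MARK (0x05) is reserved but unused.

.mismatchLUT <- local({
  A <- as.integer(charToRaw("A")); C <- as.integer(charToRaw("C"))
  G <- as.integer(charToRaw("G")); T <- as.integer(charToRaw("T"))
  partner <- c(G, T, A, C); names(partner) <- c(A, C, G, T)
  bases <- c(A, C, G, T)
  code <- matrix(3L, nrow = 256, ncol = 256)   # default: escape
  dec <- matrix(as.raw(0), nrow = 256, ncol = 3)
  for (r in bases) {
    p <- partner[[as.character(r)]]
    rest <- setdiff(bases, c(r, p))
    atm <- rest[rest %in% c(A, T)]
    last <- setdiff(rest, atm)
    ord <- c(p, atm, last)                     # codes 0, 1, 2
    for (v in 0:2) {
      code[r + 1L, ord[v + 1L] + 1L] <- v
      dec[r + 1L, v + 1L] <- as.raw(ord[v + 1L])
    }
  }
  list(code = code, dec = dec)
})

#' Exclusive mismatch encoding matrix
#'
#' Maps a mismatched contig base to a small value relative to the aligned
#' reference base: 0 for the transition partner (A<->G, C<->T), 1 for the
#' A/T member of the remaining pair, 2 for the last base, and 3 (the escape
#' value) for any non-ACGT contig byte, whose raw byte is then emitted to
#' the literals stream. For each reference base the mapping is a bijection
#' from the three other bases onto {0,1,2}.
#'
#' @param refBase reference base(s): character or raw.
#' @param contigBase contig base(s), must differ from `refBase`.
#' @return integer vector of codes in 0..3.
#' @examples
#' mismatchCode("T", "G")  # 2
#' mismatchCode("A", "G")  # 0: transition
#' @export
mismatchCode <- function(refBase, contigBase) {
  if (is.character(refBase)) refBase <- charToRaw(paste(refBase, collapse = ""))
  if (is.character(contigBase)) contigBase <- charToRaw(paste(contigBase, collapse = ""))
  if (any(refBase == contigBase))
    stop(famecUsage("mismatchCode requires contigBase != refBase"))
  if (!all(isACGTBytes(refBase)))
    stop(famecUsage("reference base must be A, C, G or T"))
  .mismatchLUT$code[cbind(as.integer(refBase) + 1L, as.integer(contigBase) + 1L)]
}

#' Invert the mismatch encoding matrix
#'
#' @param refBase reference base(s): character or raw.
#' @param code integer codes in 0..2 (3 is the escape value and carries the
#'   raw byte alongside, so it cannot be inverted here).
#' @return raw vector of contig bases.
#' @export
mismatchDecode <- function(refBase, code) {
  if (is.character(refBase)) refBase <- charToRaw(paste(refBase, collapse = ""))
  if (any(code < 0L | code > 2L))
    stop(famecUsage("only codes 0..2 are invertible"))
  .mismatchLUT$dec[cbind(as.integer(refBase) + 1L, as.integer(code) + 1L)]
}

#' Interleave code bytes with escape raw bytes
#' @keywords internal
#' @noRd
interleaveCodes <- function(codes, rawBytes) {
  n <- length(codes)
  if (n == 0L) return(raw(0))
  esc <- codes == 3L
  ends <- cumsum(1L + esc)
  out <- raw(ends[n])
  out[ends - esc] <- as.raw(codes)
  if (any(esc)) out[ends[esc]] <- rawBytes[esc]
  out
}

#' Mismatch codes for aligned contig/reference byte pairs
#' @keywords internal
#' @noRd
codesFor <- function(refBytes, contigBytes, useMatrix) {
  if (!useMatrix) return(rep(3L, length(contigBytes)))
  .mismatchLUT$code[cbind(as.integer(refBytes) + 1L, as.integer(contigBytes) + 1L)]
}

#' Decode an interleaved code byte sequence against reference bytes
#' @param refBytes reference bytes at the mismatch positions, in order.
#' @param codes interleaved code/escape bytes.
#' @return raw vector of contig bytes.
#' @keywords internal
#' @noRd
decodeCodes <- function(refBytes, codes) {
  n <- length(refBytes)
  if (n == 0L) {
    if (length(codes)) stop(famecCorrupt("dangling mismatch codes"))
    return(raw(0))
  }
  ci <- as.integer(codes)
  if (length(codes) == n && !any(ci == 3L)) {       # fast path: no escapes
    if (any(ci > 3L)) stop(famecCorrupt("invalid mismatch code byte"))
    return(.mismatchLUT$dec[cbind(as.integer(refBytes) + 1L, ci + 1L)])
  }
  out <- raw(n)
  p <- 1L
  for (i in seq_len(n)) {
    if (p > length(codes)) stop(famecCorrupt("mismatch code stream underrun"))
    v <- ci[p]
    if (v == 3L) {
      if (p + 1L > length(codes)) stop(famecCorrupt("truncated escape code"))
      out[i] <- codes[p + 1L]
      p <- p + 2L
    } else if (v <= 2L) {
      out[i] <- .mismatchLUT$dec[as.integer(refBytes[i]) + 1L, v + 1L]
      p <- p + 1L
    } else stop(famecCorrupt("invalid mismatch code byte"))
  }
  if (p != length(codes) + 1L) stop(famecCorrupt("dangling mismatch codes"))
  out
}

## ---------------------------------------------------------------------------
## Scoring automaton

#' Run the mismatch scoring automaton over an equality vector
#'
#' Score starts at `Y` percent of the terminating threshold (100%); each
#' mismatch adds 100/x percent, each matching base subtracts the same with a
#' floor at 0. Encoding stops with (and includes) the base that lifts the
#' score to 100% or more. Exact integer arithmetic in units of 1/x percent.
#'
#' @param eq logical vector (TRUE = base matches the reference).
#' @param scoreInitial Y, percent.
#' @param scoreStepX x (step is 100/x percent).
#' @return list: `consumed` bases, `terminated` (by score) flag.
#' @export
scoreAutomaton <- function(eq, scoreInitial = 25, scoreStepX = 10L) {
  x <- as.integer(scoreStepX)
  thr <- 100L * x
  s <- as.integer(round(scoreInitial * x))
  mm <- which(!eq)
  prev <- 0L
  for (p in mm) {
    s <- max(0L, s - 100L * (p - prev - 1L)) + 100L
    if (s >= thr) return(list(consumed = p, terminated = TRUE))
    prev <- p
  }
  list(consumed = length(eq), terminated = FALSE)
}

#' Encode one adjacency block (internal, processing order)
#'
#' `cseg`/`rseg` are aligned contig/reference bytes in processing order;
#' `cseg[1]` is the known mismatch (no flag emitted for it).
#' @return list(flags, lits, scored, truncated)
#' @keywords internal
#' @noRd
.adjacentBlock <- function(cseg, rseg, scoreInitial, scoreStepX, useMatrix) {
  n <- length(cseg)
  eq <- if (n > 1L) cseg[-1L] == rseg[-1L] else logical(0)
  a <- scoreAutomaton(eq, scoreInitial, scoreStepX)
  scored <- a$consumed
  idx <- c(1L, which(!eq[seq_len(scored)]) + 1L)    # known mismatch + scored mismatches
  codes <- codesFor(rseg[idx], cseg[idx], useMatrix)
  list(flags = !eq[seq_len(scored)],
       lits = interleaveCodes(codes, cseg[idx]),
       scored = scored,
       truncated = !a$terminated)
}

#' Score-bounded adjacent encoding next to a match (forward strand)
#'
#' Encodes contig bases next to a match relative to the aligned reference
#' neighborhood: the base adjacent to the match is a guaranteed mismatch and
#' is coded without a flag; subsequent bases (moving away from the match)
#' emit a flag per base plus a mismatch code when they differ, until the
#' mismatch score reaches 100% or the span limit is hit.
#'
#' @param contig raw or character contig.
#' @param ref raw or character reference.
#' @param pos 1-based contig position of the known mismatch (the base
#'   directly next to the match).
#' @param refPos 1-based reference position aligned with `pos`.
#' @param direction `"left"` (process right-to-left, for the region before a
#'   match) or `"right"`.
#' @param spanLimit maximum bases available (contig end, previous match or
#'   gap boundary); defaults to everything up to the sequence end.
#' @param scoreInitial,scoreStepX automaton parameters (Y percent, x).
#' @param useMatrix use the exclusive mismatch matrix (else escape coding).
#' @return list with `flags`, `lits`, `extent` (scored bases after the known
#'   mismatch), `consumed` (total bases including the known mismatch),
#'   `lastPos` (1-based contig position of the last base consumed) and
#'   `truncated`.
#' @examples
#' ## all-matching neighborhood never terminates by score
#' r <- "ACGTACGTACGTACGTACGT"
#' encodeAdjacent(paste0("T", r), paste0("A", r), pos = 1, refPos = 1,
#'                direction = "right")$truncated
#' @export
encodeAdjacent <- function(contig, ref, pos, refPos,
                           direction = c("left", "right"),
                           spanLimit = NULL, scoreInitial = 25,
                           scoreStepX = 10L, useMatrix = TRUE) {
  direction <- match.arg(direction)
  if (is.character(contig)) contig <- charToRaw(contig)
  if (is.character(ref)) ref <- charToRaw(ref)
  if (direction == "left") {
    avail <- min(pos, refPos)
    if (!is.null(spanLimit)) avail <- min(avail, spanLimit)
    cseg <- contig[pos - seq_len(avail) + 1L]
    rseg <- ref[refPos - seq_len(avail) + 1L]
  } else {
    avail <- min(length(contig) - pos + 1L, length(ref) - refPos + 1L)
    if (!is.null(spanLimit)) avail <- min(avail, spanLimit)
    cseg <- contig[pos + seq_len(avail) - 1L]
    rseg <- ref[refPos + seq_len(avail) - 1L]
  }
  if (avail < 1L) stop(famecUsage("no bases available for adjacent encoding"))
  if (cseg[1L] == rseg[1L])
    stop(famecUsage("base adjacent to the match must be a mismatch"))
  b <- .adjacentBlock(cseg, rseg, scoreInitial, scoreStepX, useMatrix)
  lastPos <- if (direction == "left") pos - b$scored else pos + b$scored
  list(flags = b$flags, lits = b$lits, extent = b$scored,
       consumed = 1L + b$scored, lastPos = lastPos, truncated = b$truncated)
}

#' Encode a gap between corresponding matches
#'
#' Both segments have equal length (guaranteed by the equal diagonals of the
#' flanking corresponding matches). The first and last gap base are coded
#' without a flag: they border a maximal match on the same diagonal, so they
#' are mismatches whenever that match was not trimmed (the rare equal-base
#' case after trimming goes through the escape code, which carries the raw
#' byte). Interior bases get a flag each, plus a mismatch code when set.
#'
#' @param contigSeg,refSeg aligned raw (or character) segments.
#' @param useMatrix use the exclusive mismatch matrix.
#' @return list with `flags` (logical, one per interior base) and `lits`
#'   (raw code bytes).
#' @export
encodeGap <- function(contigSeg, refSeg, useMatrix = TRUE) {
  if (is.character(contigSeg)) contigSeg <- charToRaw(contigSeg)
  if (is.character(refSeg)) refSeg <- charToRaw(refSeg)
  L <- length(contigSeg)
  if (L != length(refSeg))
    stop(famecUsage("gap segments must have equal length"))
  if (L == 0L) stop(famecUsage("a gap has at least one base"))
  flags <- if (L > 2L) contigSeg[2:(L - 1L)] != refSeg[2:(L - 1L)] else logical(0)
  mmIdx <- c(1L, 1L + which(flags), if (L >= 2L) L)
  ## a border base equal to the reference (possible after match trimming)
  ## falls on the matrix diagonal, which is the escape code carrying the byte
  codes <- codesFor(refSeg[mmIdx], contigSeg[mmIdx], useMatrix)
  list(flags = flags, lits = interleaveCodes(codes, contigSeg[mmIdx]))
}

#' Decode a gap coded by [encodeGap()]
#'
#' @param refSeg aligned reference segment (raw).
#' @param flags logical flags, one per interior base.
#' @param lits interleaved code bytes: first base, flagged interior bases,
#'   last base.
#' @return raw contig segment.
#' @export
decodeGap <- function(refSeg, flags, lits) {
  L <- length(refSeg)
  if (length(flags) != max(0L, L - 2L))
    stop(famecCorrupt("gap flag count does not match the segment"))
  mmIdx <- c(1L, 1L + which(flags), if (L >= 2L) L)
  out <- refSeg
  out[mmIdx] <- decodeCodes(refSeg[mmIdx], lits)
  out
}

## ---------------------------------------------------------------------------
## Aligned reference neighborhoods (strand-aware, processing order)

#' Reference bytes aligned with a match's neighborhood
#'
#' Processing order: moving away from the match. For reverse-complement
#' matches the returned bytes are complemented so they compare directly with
#' forward contig bytes.
#' @keywords internal
#' @noRd
alignedRefSeg <- function(refBytes, refLen, rs, len, rc, side, maxLen) {
  if (maxLen <= 0L) return(raw(0))
  if (!rc) {
    if (side == "right") {
      from <- rs + len                      # 0-based
      avail <- min(maxLen, refLen - from)
      if (avail <= 0L) return(raw(0))
      refBytes[(from + 1L):(from + avail)]
    } else {
      avail <- min(maxLen, rs)
      if (avail <= 0L) return(raw(0))
      refBytes[rs - seq_len(avail) + 1L]    # rs, rs-1, ... (1-based rs = pos rs-1 0-based)
    }
  } else {
    if (side == "right") {
      avail <- min(maxLen, rs)
      if (avail <= 0L) return(raw(0))
      .byteTables$comp[as.integer(refBytes[rs - seq_len(avail) + 1L]) + 1L]
    } else {
      from <- rs + len
      avail <- min(maxLen, refLen - from)
      if (avail <= 0L) return(raw(0))
      .byteTables$comp[as.integer(refBytes[(from + 1L):(from + avail)]) + 1L]
    }
  }
}

#' Escape raw literal bytes that collide with stream sentinels
#' @keywords internal
#' @noRd
escapeRaw <- function(bytes) {
  hit <- bytes %in% SPECIAL_BYTES
  if (!any(hit)) return(bytes)
  ends <- cumsum(1L + hit)
  out <- raw(ends[length(bytes)])
  out[ends] <- bytes                       # escaped byte sits at the end slot
  out[ends[hit] - 1L] <- LIT_ESCAPE
  out
}

## ---------------------------------------------------------------------------
## Contig encoding

#' Final match list of a contig against the current reference
#'
#' Runs the full per-contig match pipeline: maximal exact matches on both
#' strands, greedy non-overlapping selection, the gap-breaks filter (when
#' enabled) and corresponding-match linking.
#'
#' @param buf a [ReferenceBuffer-class].
#' @param contig raw vector of uppercased residues.
#' @param cfg a [CodecConfig-class].
#' @return match data.frame with a `link` column, ready for [encodeContig()].
#' @export
contigMatches <- function(buf, contig, cfg) {
  mems <- findMems(buf, contig, minLen = cfg@minMatchLength, bothStrands = TRUE)
  sel <- selectMatches(mems, cfg@minMatchLength)
  if (cfg@useGapBreaks)
    gapBreaksFilter(sel, cfg@gapBreaksMax, cfg@corrWindow)
  else
    detectCorresponding(sel, cfg@corrWindow)
}

#' Encode one contig into the stream set
#'
#' Emits, in contig order: raw literals for open regions, adjacency blocks,
#' a MATCH_MARK per match, gap-coded regions between corresponding matches,
#' and a SEQ_MARK terminating the record; fills the offsets, lengths,
#' gaps-delta, flags and truncation streams.
#'
#' @param contig raw vector of uppercased residues.
#' @param matches final match data.frame (selected, filtered, with links).
#' @param buf the [ReferenceBuffer-class] in its pre-contig state.
#' @param cfg a [CodecConfig-class].
#' @param ss a [newStreamSet()] accumulator.
#' @return invisible `NULL`; streams are appended in place.
#' @export
encodeContig <- function(contig, matches, buf, cfg, ss) {
  st <- buf@state
  refBytes <- st$bases
  refLen <- st$len
  n <- nrow(matches)
  clen <- length(contig)
  useMx <- cfg@useMismatchMatrix
  Y <- cfg@scoreInitial; X <- cfg@scoreStepX

  enc <- gapsDeltaEncode(matches, cfg@useGapsDelta)
  streamPut(ss, "offsets", enc$offsets)
  if (n > 1L) streamPut(ss, "gapsDelta", enc$deltas)

  diag <- matches$refStart - matches$start
  gapCoded <- if (n >= 2L) {
    gc <- junctionNonEmpty(matches) & cfg@useGapEncoding &
      !matches$rc[-n] & !matches$rc[-1L] & diag[-n] == diag[-1L]
    ## ambiguity runs (N etc.) are cheaper as raw literals than as escape
    ## codes, so only code pure-ACGT junctions against the reference
    bad <- cumsum(c(0L, !isACGTBytes(contig)))
    jFrom <- matches$start[-n] + matches$length[-n]
    jTo <- matches$start[-1L]
    gc & bad[pmax(jTo, jFrom) + 1L] == bad[jFrom + 1L]
  } else logical(0)

  lits <- list(); li <- 0L
  putLit <- function(v) if (length(v)) { li <<- li + 1L; lits[[li]] <<- v }
  flags <- list(); fi <- 0L
  putFlag <- function(v) if (length(v)) { fi <<- fi + 1L; flags[[fi]] <<- v }
  lens <- numeric(0)
  truncs <- numeric(0)

  emitOpen <- function(regStart, regEnd, prevIdx, nextIdx) {
    L <- regEnd - regStart
    raTot <- 0L
    if (!is.na(prevIdx)) {
      ra <- NULL
      if (cfg@useAdjacentEncoding && L >= 1L) {
        rseg <- alignedRefSeg(refBytes, refLen, matches$refStart[prevIdx],
                              matches$length[prevIdx], matches$rc[prevIdx],
                              "right", L)
        if (length(rseg) >= 1L && contig[regStart + 1L] != rseg[1L]) {
          cseg <- contig[(regStart + 1L):(regStart + length(rseg))]
          ra <- .adjacentBlock(cseg, rseg, Y, X, useMx)
        }
      }
      if (is.null(ra)) {
        truncs <<- c(truncs, 0)
      } else {
        truncs <<- c(truncs, 2 * (ra$scored + 1))
        putFlag(ra$flags)
        putLit(ra$lits)
        raTot <- 1L + ra$scored
      }
    }
    laTot <- 0L
    if (!is.na(nextIdx)) {
      rem <- L - raTot
      if (cfg@useAdjacentEncoding && rem >= 1L) {
        rseg <- alignedRefSeg(refBytes, refLen, matches$refStart[nextIdx],
                              matches$length[nextIdx], matches$rc[nextIdx],
                              "left", rem)
        if (length(rseg) >= 1L && contig[regEnd] != rseg[1L]) {
          cseg <- contig[regEnd - seq_len(length(rseg)) + 1L]
          la <- .adjacentBlock(cseg, rseg, Y, X, useMx)
          truncs <<- c(truncs, la$scored)
          putFlag(la$flags)
          putLit(la$lits)
          laTot <- 1L + la$scored
        }
      }
    }
    if (L - raTot - laTot > 0L)
      putLit(escapeRaw(contig[(regStart + raTot + 1L):(regEnd - laTot)]))
  }

  emitRegion <- function(regStart, regEnd, prevIdx, nextIdx) {
    if (regEnd <= regStart) return(invisible(NULL))
    if (!is.na(prevIdx) && !is.na(nextIdx) && gapCoded[prevIdx]) {
      L <- regEnd - regStart
      truncs <<- c(truncs, 2 * L + 1)
      rFrom <- matches$refStart[prevIdx] + matches$length[prevIdx]
      g <- encodeGap(contig[(regStart + 1L):regEnd],
                     refBytes[(rFrom + 1L):(rFrom + L)], useMx)
      putFlag(g$flags)
      putLit(g$lits)
    } else {
      emitOpen(regStart, regEnd, prevIdx, nextIdx)
    }
    invisible(NULL)
  }

  prevEnd <- 0L
  for (i in seq_len(n)) {
    emitRegion(prevEnd, matches$start[i],
               if (i > 1L) i - 1L else NA_integer_, i)
    putLit(MATCH_MARK)
    lens <- c(lens, matches$length[i] - cfg@minMatchLength)
    prevEnd <- matches$start[i] + matches$length[i]
  }
  emitRegion(prevEnd, clen, if (n > 0L) n else NA_integer_, NA_integer_)
  putLit(SEQ_MARK)

  streamPut(ss, "literals", do.call(c, lits[seq_len(li)]))
  if (fi) streamPut(ss, "flags", do.call(c, flags[seq_len(fi)]))
  streamPut(ss, "lengths", lens)
  streamPut(ss, "truncations", truncs)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## Contig decoding

CODE_BYTES <- as.raw(0:3)

#' Decode one contig from a stream reader
#'
#' Single forward pass: (1) tokenize the record's literal segment, framing
#' gap regions and adjacency blocks from the lengths, truncations and flags
#' streams; (2) resolve every match's reference start via the offsets and
#' gaps-delta streams over the token skeleton; (3) materialize bases against
#' the replayed reference buffer.
#'
#' @param rd stream reader (see [decompressArchive()] internals).
#' @param buf the replayed [ReferenceBuffer-class].
#' @param cfg the [CodecConfig-class] the archive was written with.
#' @return list with `contig` (raw, uppercased) and `matches` (data.frame),
#'   the latter needed to replay reference-extension decisions.
#' @export
decodeContig <- function(rd, buf, cfg) {
  lit <- rd$ss$literals
  pos <- rd$pos_literals          # 0-based count consumed
  if (is.null(rd$litSpecials)) rd$litSpecials <- which(lit %in% SPECIAL_BYTES)
  spAll <- rd$litSpecials

  peek <- function() {
    if (pos >= length(lit)) stop(famecCorrupt("literals stream underrun"))
    lit[pos + 1L]
  }
  takeByte <- function() {
    b <- peek(); pos <<- pos + 1L; b
  }
  takeCodes <- function(nCodes) {
    if (nCodes == 0L) return(raw(0))
    out <- raw(2L * nCodes); oi <- 0L
    for (i in seq_len(nCodes)) {
      b <- takeByte()
      if (b > as.raw(3)) stop(famecCorrupt(sprintf(
        "invalid code byte 0x%02x in literals at offset %d", as.integer(b), pos)))
      oi <- oi + 1L; out[oi] <- b
      if (b == as.raw(3)) { oi <- oi + 1L; out[oi] <- takeByte() }
    }
    out[seq_len(oi)]
  }
  takeRawRun <- function() {
    chunks <- list(); ci <- 0L
    repeat {
      k <- findInterval(pos, spAll) + 1L    # first sentinel past the cursor
      if (k > length(spAll))
        stop(famecCorrupt("unterminated record in literals"))
      nxt <- spAll[k]                       # 1-based position
      if (nxt > pos + 1L) {
        ci <- ci + 1L; chunks[[ci]] <- lit[(pos + 1L):(nxt - 1L)]
        pos <<- nxt - 1L
      }
      b <- lit[pos + 1L]
      if (b == LIT_ESCAPE) {
        if (pos + 2L > length(lit)) stop(famecCorrupt("truncated literal escape"))
        pos <<- pos + 2L
        ci <- ci + 1L; chunks[[ci]] <- lit[pos]
      } else break
    }
    if (ci == 0L) raw(0) else do.call(c, chunks[seq_len(ci)])
  }
  takeBlock <- function(scored) {
    fl <- as.logical(readerTake(rd, "flags", scored))
    codes <- takeCodes(1L + sum(fl))
    list(flags = fl, codes = codes, total = 1L + scored)
  }

  tokens <- list(); ti <- 0L
  afterMatch <- FALSE
  repeat {
    b <- peek()
    if (b == SEQ_MARK) { pos <- pos + 1L; break }
    if (b == MATCH_MARK) {
      pos <- pos + 1L
      len <- readerTake(rd, "lengths", 1L) + cfg@minMatchLength
      ti <- ti + 1L; tokens[[ti]] <- list(type = "match", len = len)
      afterMatch <- TRUE
      next
    }
    ## non-empty region: a gap or an open region
    if (!afterMatch && ti > 0L)
      stop(famecCorrupt("unexpected literal region"))
    ra <- NULL
    if (afterMatch) {
      e <- readerTake(rd, "truncations", 1L)
      if (e %% 2 == 1) {                      # gap region, length (e - 1) / 2
        L <- (e - 1) / 2
        if (L < 1) stop(famecCorrupt("empty gap region"))
        fl <- as.logical(readerTake(rd, "flags", max(0, L - 2L)))
        codes <- takeCodes(1L + sum(fl) + (L >= 2L))
        ti <- ti + 1L
        tokens[[ti]] <- list(type = "gap", len = L, flags = fl, codes = codes)
        afterMatch <- FALSE
        next
      }
      if (e > 0) ra <- takeBlock(as.integer(e / 2) - 1L)
    }
    la <- NULL
    if (pos < length(lit) && lit[pos + 1L] %in% CODE_BYTES) {
      s <- readerTake(rd, "truncations", 1L)
      la <- takeBlock(as.integer(s))
    }
    rawRun <- takeRawRun()
    L <- length(rawRun) +
      (if (is.null(ra)) 0L else ra$total) +
      (if (is.null(la)) 0L else la$total)
    ti <- ti + 1L
    tokens[[ti]] <- list(type = "open", len = L, ra = ra, la = la,
                         raw = rawRun)
    afterMatch <- FALSE
  }
  rd$pos_literals <- pos
  tokens <- tokens[seq_len(ti)]

  ## skeleton and reference-start resolution
  isMatch <- vapply(tokens, function(t) t$type == "match", logical(1))
  lensAll <- vapply(tokens, function(t) as.numeric(t$len), numeric(1))
  startsAll <- cumsum(c(0, head(lensAll, -1L)))
  skeleton <- data.frame(start = startsAll[isMatch], length = lensAll[isMatch])
  nM <- nrow(skeleton)
  deltas <- if (nM > 1L) readerTake(rd, "gapsDelta", nM - 1L) else numeric(0)
  matches <- .decodeMatchRefs(skeleton, deltas, rd)

  ## materialize
  st <- buf@state
  refBytes <- st$bases
  refLen <- st$len
  out <- vector("list", length(tokens))
  mi <- 0L
  prevMatch <- NA_integer_
  for (t in seq_along(tokens)) {
    tok <- tokens[[t]]
    if (tok$type == "match") {
      mi <- mi + 1L
      rs <- matches$refStart[mi]; len <- matches$length[mi]
      if (rs + len > refLen)
        stop(famecCorrupt("match extends past the reference buffer"))
      seg <- refBytes[(rs + 1L):(rs + len)]
      out[[t]] <- if (matches$rc[mi]) revComp(seg) else seg
      prevMatch <- mi
    } else if (tok$type == "gap") {
      rFrom <- matches$refStart[prevMatch] + matches$length[prevMatch]
      if (rFrom + tok$len > refLen)
        stop(famecCorrupt("gap extends past the reference buffer"))
      out[[t]] <- decodeGap(refBytes[(rFrom + 1L):(rFrom + tok$len)],
                            tok$flags, tok$codes)
    } else {
      pieces <- list()
      if (!is.null(tok$ra)) {
        rseg <- alignedRefSeg(refBytes, refLen, matches$refStart[prevMatch],
                              matches$length[prevMatch],
                              matches$rc[prevMatch], "right", tok$ra$total)
        pieces$ra <- .materializeBlock(tok$ra, rseg)
      }
      laBytes <- NULL
      if (!is.null(tok$la)) {
        nextM <- mi + 1L
        if (nextM > nM)
          stop(famecCorrupt("adjacency block with no following match"))
        rseg <- alignedRefSeg(refBytes, refLen, matches$refStart[nextM],
                              matches$length[nextM], matches$rc[nextM],
                              "left", tok$la$total)
        laBytes <- rev(.materializeBlock(tok$la, rseg))
      }
      pieces$m <- tok$raw
      pieces$la <- laBytes
      out[[t]] <- unname(
        do.call(c, pieces[!vapply(pieces, is.null, logical(1))]))
    }
  }
  contig <- if (length(out)) do.call(c, out) else raw(0)
  list(contig = contig, matches = matches)
}

#' Materialize one adjacency block (processing order)
#' @keywords internal
#' @noRd
.materializeBlock <- function(blk, rseg) {
  if (length(rseg) < blk$total)
    stop(famecCorrupt("adjacency block extends past the reference"))
  mmIdx <- c(1L, which(blk$flags) + 1L)
  bases <- decodeCodes(rseg[mmIdx], blk$codes)
  out <- rseg[seq_len(blk$total)]
  out[mmIdx] <- bases
  out
}

#' Reader-driven gaps-delta resolution
#' @keywords internal
#' @noRd
.decodeMatchRefs <- function(skeleton, deltas, rd) {
  n <- nrow(skeleton)
  if (n == 0L) return(emptyMatches())
  jun <- junctionNonEmpty(skeleton)
  dg <- rep(NA_real_, n)
  rs <- numeric(n); rc <- logical(n)
  for (m in seq_len(n)) {
    if (!is.na(dg[m])) {
      rs[m] <- dg[m] + skeleton$start[m]
      rc[m] <- FALSE
    } else {
      v <- readerTake(rd, "offsets", 1L)
      rc[m] <- (v %% 2) == 1
      rs[m] <- (v - v %% 2) / 2
    }
    if (m < n && deltas[m] > 0) {
      if (rc[m])
        stop(famecCorrupt("gaps-delta link from a reverse-complement match"))
      j <- resolveGapTarget(m, as.integer(deltas[m]), which(!is.na(dg)), jun, n)
      if (is.na(j) || !is.na(dg[j]))
        stop(famecCorrupt("unresolvable gaps-delta value"))
      dg[j] <- rs[m] - skeleton$start[m]
    }
  }
  data.frame(start = skeleton$start, refStart = rs,
             length = skeleton$length, rc = rc)
}
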