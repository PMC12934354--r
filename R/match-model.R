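## Structural relations among a contig's matches: corresponding-match links
## (equal diagonal within a window), the gap-breaks filter, and gaps-delta
## coding of reference offsets. A "gap" is a nonempty contig region between
## two consecutive encoded matches; gaps adjacent to matches whose offsets
## are correspondence-derived merge when counting.

#' Link each match to its closest subsequent corresponding match
#'
#' Two matches correspond when both are forward-strand and share a diagonal
#' (equal `refStart - start`), so the contig distance between them equals
#' the reference distance. A pair is linked only if fewer than `window`
#' other matches lie between them in the list; each match links only its
#' nearest qualifying successor.
#'
#' @param matches match data.frame (disjoint, sorted by contig start).
#' @param window correspondence window (default 64).
#' @return the data.frame with an integer `link` column (row index of the
#'   linked match, `NA` if none).
#' @export
detectCorresponding <- function(matches, window = 64L) {
  n <- nrow(matches)
  link <- rep(NA_integer_, n)
  if (n >= 2L) {
    diag <- ifelse(matches$rc, NA_real_, matches$refStart - matches$start)
    for (i in seq_len(n - 1L)) {
      if (is.na(diag[i])) next
      hi <- min(n, i + window)           # j - i - 1 < window  =>  j <= i + window
      js <- (i + 1L):hi
      hit <- js[!is.na(diag[js]) & diag[js] == diag[i]]
      if (length(hit)) link[i] <- hit[1L]
    }
  }
  matches$link <- link
  matches
}

#' Drop short matches interrupting a gap between corresponding matches
#'
#' A match shorter than `maxLen` whose two neighbors are corresponding to
#' each other (forward strand, equal diagonal) is removed; its bases rejoin
#' the surrounding gap and are coded with the encoding-in-gaps technique.
#' Removal decisions use the original neighbor structure (single pass);
#' correspondence links are recomputed afterwards.
#'
#' @param matches match data.frame with or without links.
#' @param maxLen strict upper bound on removable match length (default 256).
#' @param window correspondence window for the recomputation.
#' @return filtered match data.frame with a recomputed `link` column.
#' @export
gapBreaksFilter <- function(matches, maxLen = 256L, window = 64L) {
  n <- nrow(matches)
  if (n >= 3L) {
    diag <- ifelse(matches$rc, NA_real_, matches$refStart - matches$start)
    i <- 2:(n - 1L)
    drop <- matches$length[i] < maxLen &
      !is.na(diag[i - 1L]) & !is.na(diag[i + 1L]) &
      diag[i - 1L] == diag[i + 1L]
    if (any(drop)) matches <- matches[-(i[drop]), , drop = FALSE]
  }
  rownames(matches) <- NULL
  detectCorresponding(matches, window)
}

#' Junction emptiness between consecutive matches
#' @keywords internal
#' @noRd
junctionNonEmpty <- function(matches) {
  n <- nrow(matches)
  if (n < 2L) return(logical(0))
  matches$start[-1L] > matches$start[-n] + matches$length[-n]
}

#' Walk forward from match `i` counting merged nonempty gaps; return the
#' first visible match at which the count equals `d` (the decoder's
#' resolution rule), or NA.
#' @keywords internal
#' @noRd
resolveGapTarget <- function(i, d, invisible, jun, n) {
  cnt <- 0L
  prev <- i
  t <- i + 1L
  while (t <= n) {
    if (!(t %in% invisible)) {
      if (any(jun[prev:(t - 1L)])) cnt <- cnt + 1L
      if (cnt == d) return(t)
      if (cnt > d) return(NA_integer_)
      prev <- t
    }
    t <- t + 1L
  }
  NA_integer_
}

#' Gaps-delta encode a final match list
#'
#' Reference starts go to the offsets stream only for matches that are not
#' the correspondence target of an earlier encoded match; every other match
#' (except the last) gets a gaps-delta value: the number of gaps to its
#' closest subsequent corresponding match, merging gaps across matches that
#' correspond to matches preceding the current one, with 0 meaning "no
#' corresponding match". Strand is folded into the offset entries
#' (`refStart * 2 + rc`); derived matches are always forward.
#'
#' @param matches match data.frame with a `link` column (see
#'   [detectCorresponding()]).
#' @param useGapsDelta when `FALSE`, every offset is stored explicitly and
#'   all deltas are 0.
#' @return list with `offsets` (numeric), `deltas` (numeric, one per match
#'   except the last), `explicit` (logical per match) and `target`
#'   (integer per match: resolved link target or NA).
#' @export
gapsDeltaEncode <- function(matches, useGapsDelta = TRUE) {
  n <- nrow(matches)
  deltas <- if (n > 1L) numeric(n - 1L) else numeric(0)
  derivedBy <- rep(NA_integer_, n)
  target <- rep(NA_integer_, n)
  if (useGapsDelta && n > 1L) {
    jun <- junctionNonEmpty(matches)
    for (i in seq_len(n - 1L)) {
      j <- matches$link[i]
      if (is.na(j) || !is.na(derivedBy[j])) next
      inv <- which(!is.na(derivedBy))
      ## count merged gaps from i to j
      visBetween <- setdiff(seq.int(i + 1L, length.out = j - i - 1L), inv)
      seqv <- c(i, visBetween, j)
      d <- 0L
      for (p in seq_len(length(seqv) - 1L))
        if (any(jun[seqv[p]:(seqv[p + 1L] - 1L)])) d <- d + 1L
      if (d < 1L) next
      ## emit only if the decoder's first-hit rule resolves to j
      if (!identical(resolveGapTarget(i, d, inv, jun, n), j)) next
      deltas[i] <- d
      derivedBy[j] <- i
      target[i] <- j
    }
  }
  explicit <- is.na(derivedBy)
  list(offsets = matches$refStart[explicit] * 2 + as.numeric(matches$rc[explicit]),
       deltas = deltas, explicit = explicit, target = target)
}

#' Invert gaps-delta encoding over a contig skeleton
#'
#' Given the decoded contig skeleton (match contig starts and lengths, from
#' which junction emptiness follows), the offsets stream and the gaps-delta
#' stream, reconstructs every match's reference start and strand.
#'
#' @param skeleton data.frame with `start` and `length` per match, in order.
#' @param offsets numeric offset entries (`refStart * 2 + rc`).
#' @param deltas numeric gaps-delta values, one per match except the last.
#' @return data.frame `start`, `refStart`, `length`, `rc`.
#' @export
gapsDeltaDecode <- function(skeleton, offsets, deltas) {
  n <- nrow(skeleton)
  if (n == 0L) {
    if (length(offsets) || length(deltas))
      stop(famecCorrupt("offset/delta streams for an empty match list"))
    return(emptyMatches())
  }
  if (length(deltas) != n - 1L)
    stop(famecCorrupt("gaps-delta stream length does not match the skeleton"))
  jun <- junctionNonEmpty(skeleton)
  dg <- rep(NA_real_, n)     # derived diagonal
  rs <- numeric(n); rc <- logical(n)
  oi <- 0L
  for (m in seq_len(n)) {
    if (!is.na(dg[m])) {
      rs[m] <- dg[m] + skeleton$start[m]
      rc[m] <- FALSE
    } else {
      oi <- oi + 1L
      if (oi > length(offsets))
        stop(famecCorrupt("match offsets stream underrun"))
      v <- offsets[oi]
      rc[m] <- (v %% 2) == 1
      rs[m] <- (v - v %% 2) / 2
    }
    if (m < n && deltas[m] > 0) {
      if (rc[m])
        stop(famecCorrupt("gaps-delta link from a reverse-complement match"))
      inv <- which(!is.na(dg))
      j <- resolveGapTarget(m, as.integer(deltas[m]), inv, jun, n)
      if (is.na(j))
        stop(famecCorrupt("gaps-delta value points past the match list"))
      if (!is.na(dg[j]))
        stop(famecCorrupt("gaps-delta target already derived"))
      dg[j] <- rs[m] - skeleton$start[m]
    }
  }
  if (oi != length(offsets))
    stop(famecCorrupt("match offsets stream not fully consumed"))
  data.frame(start = skeleton$start, refStart = rs,
             length = skeleton$length, rc = rc)
}
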