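## Low-level stream plumbing: LEB128 varints, bit packing, Adler-32,
## and the mutable stream-set container the codec writes into.

#' Encode non-negative integers as unsigned LEB128 varints
#'
#' Values are doubles (exact up to 2^49) so reference offsets are not limited
#' to 32-bit range. Vectorized over values.
#'
#' @param x numeric vector of non-negative integers.
#' @return raw vector.
#' @keywords internal
#' @noRd
varintEncode <- function(x) {
  n <- length(x)
  if (n == 0L) return(raw(0))
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    stop("varintEncode: values must be non-negative integers")
  ## number of 7-bit groups per value
  nb <- pmax(1, ceiling(log2(x + 1) / 7))
  ## guard against log2 rounding at exact powers of 128
  nb <- nb + (x >= 128^nb)
  maxb <- max(nb)
  out <- matrix(0, nrow = maxb, ncol = n)
  keep <- matrix(FALSE, nrow = maxb, ncol = n)
  v <- x
  for (j in seq_len(maxb)) {
    byte <- v %% 128
    v <- (v - byte) / 128
    more <- j < nb
    out[j, ] <- byte + 128 * more
    keep[j, ] <- j <= nb
  }
  as.raw(out[keep])
}

#' Decode a raw vector of unsigned LEB128 varints
#' @param r raw vector containing whole varints.
#' @return numeric vector of decoded values.
#' @keywords internal
#' @noRd
varintDecode <- function(r) {
  if (length(r) == 0L) return(numeric(0))
  b <- as.integer(r)
  cont <- b >= 128L
  if (cont[length(b)])
    stop(famecCorrupt("truncated varint stream"))
  ## group id per byte: 1 + number of completed values before this byte
  ends <- !cont
  grp <- cumsum(c(1L, head(ends, -1L)))
  off <- sequence(tabulate(grp)) - 1L
  vals <- rowsum((b %% 128L) * 128^off, grp)
  as.numeric(vals[, 1L])
}

#' Pack logical flags into raw bytes with a varint bit-count prefix
#' @keywords internal
#' @noRd
packFlags <- function(flags) {
  n <- length(flags)
  pad <- (8L - n %% 8L) %% 8L
  body <- packBits(c(flags, rep(FALSE, pad)), type = "raw")
  c(varintEncode(n), body)
}

#' Inverse of packFlags
#' @keywords internal
#' @noRd
unpackFlags <- function(r) {
  if (length(r) == 0L) return(logical(0))
  ## read varint prefix
  i <- 1L
  while (as.integer(r[i]) >= 128L) i <- i + 1L
  n <- varintDecode(r[seq_len(i)])
  body <- r[-seq_len(i)]
  if (length(body) * 8 < n) stop(famecCorrupt("truncated flags stream"))
  bits <- rawToBits(body)
  as.logical(bits[seq_len(n)])
}

#' Adler-32 checksum of a raw vector
#'
#' Computed in chunks with vectorized cumulative sums; exact in doubles.
#' @param r raw vector.
#' @return double scalar in [0, 2^32).
#' @keywords internal
#' @noRd
adler32 <- function(r) {
  MOD <- 65521
  s1 <- 1
  s2 <- 0
  n <- length(r)
  i <- 1L
  CH <- 3000L
  while (i <= n) {
    j <- min(n, i + CH - 1L)
    b <- as.integer(r[i:j])
    cs <- s1 + cumsum(b)
    s2 <- (s2 + sum(cs)) %% MOD
    s1 <- cs[length(cs)] %% MOD
    i <- j + 1L
  }
  s2 * 65536 + s1
}

## ---------------------------------------------------------------------------
## StreamSet: the eight logical streams. Mutable (environment-backed) because
## encoding appends chunk lists and decoding advances cursors.

STREAM_NAMES <- c("literals", "offsets", "lengths", "gapsDelta",
                  "flags", "truncations", "headers", "fileMeta")

#' Create an empty stream set
#'
#' Holds the logical streams the encoder fills: literals (bytes), match
#' offsets, span lengths, gaps delta, mismatch flags (bits), adjacency
#' truncations, headers and file metadata.
#'
#' @return a `StreamSet` (environment-backed) object.
#' @export
newStreamSet <- function() {
  e <- new.env(parent = emptyenv())
  for (nm in STREAM_NAMES) {
    e[[nm]] <- list()      # chunk accumulator at encode time
  }
  e$finalized <- FALSE
  class(e) <- "StreamSet"
  e
}

#' @export
print.StreamSet <- function(x, ...) {
  s <- streamSizes(x)
  cat("StreamSet:", if (isTRUE(x$finalized)) "(finalized)" else "(building)", "\n")
  for (nm in names(s)) cat(sprintf("  %-12s %d\n", nm, s[[nm]]))
  invisible(x)
}

#' Append a chunk to a stream
#' @keywords internal
#' @noRd
streamPut <- function(ss, name, value) {
  if (length(value)) ss[[name]][[length(ss[[name]]) + 1L]] <- value
  invisible(ss)
}

#' Collapse chunk lists into flat vectors (raw for byte streams, numeric for
#' integer streams, logical for flags)
#' @keywords internal
#' @noRd
streamFinalize <- function(ss) {
  if (isTRUE(ss$finalized)) return(ss)
  rawStreams <- c("literals", "headers", "fileMeta")
  for (nm in STREAM_NAMES) {
    chunks <- ss[[nm]]
    ss[[nm]] <- if (nm %in% rawStreams) {
      if (length(chunks)) do.call(c, chunks) else raw(0)
    } else if (nm == "flags") {
      if (length(chunks)) as.logical(unlist(chunks, use.names = FALSE)) else logical(0)
    } else {
      if (length(chunks)) as.numeric(unlist(chunks, use.names = FALSE)) else numeric(0)
    }
  }
  ss$finalized <- TRUE
  ss
}

#' Element/byte counts per stream
#' @param ss a StreamSet.
#' @return named integer vector.
#' @export
streamSizes <- function(ss) {
  ss <- streamFinalize(ss)
  vapply(STREAM_NAMES, function(nm) length(ss[[nm]]), integer(1))
}

#' Build a cursor-based reader over a finalized stream set
#' @keywords internal
#' @noRd
newStreamReader <- function(ss) {
  ss <- streamFinalize(ss)
  e <- new.env(parent = emptyenv())
  e$ss <- ss
  for (nm in STREAM_NAMES) e[[paste0("pos_", nm)]] <- 0L
  class(e) <- "StreamReader"
  e
}

#' Take `n` elements from a stream, advancing the cursor
#' @keywords internal
#' @noRd
readerTake <- function(rd, name, n) {
  n <- as.integer(n)
  p <- rd[[paste0("pos_", name)]]
  s <- rd$ss[[name]]
  if (p + n > length(s))
    stop(famecCorrupt(sprintf("stream underrun in '%s' at offset %d", name, p)))
  rd[[paste0("pos_", name)]] <- p + n
  if (n == 0L) return(s[0])
  s[(p + 1L):(p + n)]
}

#' Peek at the next element of a stream without consuming it
#' @keywords internal
#' @noRd
readerPeek <- function(rd, name) {
  p <- rd[[paste0("pos_", name)]]
  s <- rd$ss[[name]]
  if (p >= length(s)) return(NULL)
  s[p + 1L]
}

#' Remaining element count of a stream
#' @keywords internal
#' @noRd
readerRemaining <- function(rd, name) {
  length(rd$ss[[name]]) - rd[[paste0("pos_", name)]]
}

## ---------------------------------------------------------------------------
## Typed error conditions

famecCondition <- function(class, msg, ...) {
  structure(
    class = c(class, "famec_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
}

famecCorrupt  <- function(msg, ...) famecCondition("famec_corrupt_error", msg, ...)
famecUsage    <- function(msg, ...) famecCondition("famec_usage_error", msg, ...)
famecNotFound <- function(msg, ...) famecCondition("famec_notfound_error", msg, ...)
famecMalformed <- function(msg, ...) famecCondition(
  c("famec_malformed_error", "famec_usage_error"), msg, ...)
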