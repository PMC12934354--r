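# Independent brute-force MEM oracle: exhaustive equality-matrix enumeration
# of maximal runs on every diagonal, both strands. Deliberately naive; used
# only to validate the k-mer-anchored finder.
bruteMems <- function(ref, contig, minLen) {
  refc <- strsplit(rawToChar(ref), "")[[1]]
  out <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scan1 <- function(qc, rcFlag) {
    nq <- length(qc); nr <- length(refc)
    if (nq == 0 || nr == 0) return(invisible(NULL))
    okq <- qc %in% c("A", "C", "G", "T"); okr <- refc %in% c("A", "C", "G", "T")
    E <- outer(qc, refc, "==") & outer(okq, okr, "&")
    for (d in (-(nq - 1)):(nr - 1)) {
      qi <- max(1, 1 - d):min(nq, nr - d)
      if (length(qi) < minLen) next
      eq <- E[cbind(qi, qi + d)]
      r <- rle(eq)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (j in which(r$values & r$lengths >= minLen)) {
        q0 <- qi[1] + starts[j] - 2                   # 0-based
        out[[length(out) + 1]] <<- data.frame(
          start = if (rcFlag) nq - (q0 + r$lengths[j]) else q0,
          refStart = q0 + d, length = r$lengths[j], rc = rcFlag)
      }
    }
    invisible(NULL)
  }
  qc <- strsplit(rawToChar(contig), "")[[1]]
  scan1(qc, FALSE)
  rcq <- rev(unname(ifelse(qc %in% names(comp), comp[qc], qc)))
  scan1(rcq, TRUE)
  if (!length(out)) {
    return(data.frame(start = integer(0), refStart = integer(0),
                      length = integer(0), rc = logical(0)))
  }
  m <- do.call(rbind, out)
  m <- m[order(m$start, -m$length, m$refStart, m$rc), , drop = FALSE]
  rownames(m) <- NULL
  m
}

normMatches <- function(m) {
  m <- m[, c("start", "refStart", "length", "rc")]
  m$start <- as.integer(m$start); m$refStart <- as.integer(m$refStart)
  m$length <- as.integer(m$length)
  rownames(m) <- NULL
  m
}
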