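## Seeded synthetic genome collections: clonal descendants of one ancestor
## with SNPs, indels, reverse-complemented inversions, translocations and N
## runs — the statistical structure a reference-based codec exploits.

BASES <- charToRaw("ACGT")

#' Generate a random ancestor sequence
#'
#' Bases are i.i.d. with the requested GC content, deterministic for a fixed
#' seed.
#'
#' @param length number of bases.
#' @param gc fraction of G+C in `[0, 1]`.
#' @param seed integer seed.
#' @return raw vector of uppercase residues.
#' @examples
#' rawToChar(makeAncestor(20, gc = 0.5, seed = 1))
#' @export
makeAncestor <- function(length, gc = 0.45, seed = 1L) {
  stopifnot(gc >= 0, gc <= 1, length >= 0)
  if (length == 0) return(raw(0))
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  BASES[sample.int(4L, length, replace = TRUE, prob = p)]
}

## geometric with mean m, >= 1
.rlen <- function(n, m) 1L + stats::rgeom(n, prob = 1 / max(m, 1))

#' Apply the mutation model to a sequence using the ambient RNG
#' @keywords internal
#' @noRd
.mutateSeq <- function(x, model) {
  n <- length(x)
  if (n == 0L) return(x)

  ## segment translocations
  k <- stats::rpois(1L, model@rearrangeRate)
  for (i in seq_len(k)) {
    n <- length(x)
    len <- min(.rlen(1L, model@inversionLen), n - 1L)
    if (len < 1L || n < 3L) next
    from <- sample.int(n - len + 1L, 1L)
    seg <- x[from:(from + len - 1L)]
    x <- x[-(from:(from + len - 1L))]
    to <- sample.int(length(x) + 1L, 1L)
    x <- append(x, seg, after = to - 1L)
  }

  ## reverse-complemented inversions
  k <- stats::rpois(1L, model@inversionRate)
  for (i in seq_len(k)) {
    n <- length(x)
    len <- min(.rlen(1L, model@inversionLen), n)
    if (len < 2L) next
    from <- sample.int(n - len + 1L, 1L)
    x[from:(from + len - 1L)] <- revComp(x[from:(from + len - 1L)])
  }

  ## indels (applied right-to-left so positions stay valid)
  n <- length(x)
  nEv <- stats::rbinom(1L, n, model@indelRate)
  if (nEv > 0L) {
    pos <- sort(sample.int(n, nEv), decreasing = TRUE)
    ins <- stats::runif(nEv) < 0.5
    lens <- .rlen(nEv, model@indelLen)
    for (i in seq_len(nEv)) {
      if (ins[i]) {
        x <- append(x, BASES[sample.int(4L, lens[i], replace = TRUE)],
                    after = pos[i])
      } else {
        del <- pos[i]:min(pos[i] + lens[i] - 1L, length(x))
        x <- x[-del]
      }
    }
  }

  ## substitutions: always to a different base
  n <- length(x)
  nSub <- stats::rbinom(1L, n, model@snpRate)
  if (nSub > 0L) {
    pos <- sample.int(n, nSub)
    cur <- match(x[pos], BASES)
    cur[is.na(cur)] <- 1L                   # non-ACGT: substitute freely
    new <- (cur - 1L + sample.int(3L, nSub, replace = TRUE)) %% 4L + 1L
    x[pos] <- BASES[new]
  }

  ## N runs (overwrite)
  k <- stats::rpois(1L, model@nRunRate)
  for (i in seq_len(k)) {
    n <- length(x)
    len <- min(.rlen(1L, model@nRunLen), n)
    if (len < 1L) next
    from <- sample.int(n - len + 1L, 1L)
    x[from:(from + len - 1L)] <- charToRaw("N")
  }
  x
}

#' Soft-mask random runs of a sequence (lowercase) using the ambient RNG
#' @keywords internal
#' @noRd
.softMask <- function(x) {
  n <- length(x)
  if (n < 10L) return(x)
  k <- stats::rpois(1L, n / 1500)
  for (i in seq_len(k)) {
    len <- min(.rlen(1L, 150), n)
    from <- sample.int(n - len + 1L, 1L)
    idx <- from:(from + len - 1L)
    x[idx] <- .lowerTable[as.integer(x[idx]) + 1L]
  }
  x
}

#' Mutate an ancestor into one descendant genome
#'
#' Applies segment translocations, reverse-complemented inversions, indels,
#' substitutions and N runs per the model, optionally fragments the result
#' into contigs at random breakpoints, and wraps it as a [FastaFile-class].
#' Deterministic for a fixed seed.
#'
#' @param ancestor raw vector (or character) of uppercase residues.
#' @param model a [MutationModel-class].
#' @param name genome name used for the path and headers.
#' @param nContigs number of contigs to fragment into.
#' @param lineWidth sequence line width of the emitted file.
#' @param softMask lowercase random runs to emulate repeat masking.
#' @param seed seed for this genome (defaults to the model seed).
#' @return a [FastaFile-class].
#' @export
mutateGenome <- function(ancestor, model, name = "genome", nContigs = 1L,
                         lineWidth = 70L, softMask = FALSE,
                         seed = model@seed) {
  if (is.character(ancestor)) ancestor <- charToRaw(ancestor)
  if (length(ancestor) == 0L)
    stop(famecUsage("ancestor must be non-empty"))
  set.seed(as.integer(seed))
  x <- .mutateSeq(ancestor, model)
  if (softMask) x <- .softMask(x)
  nContigs <- max(1L, min(as.integer(nContigs), length(x)))
  cuts <- if (nContigs > 1L)
    sort(sample.int(length(x) - 1L, nContigs - 1L)) else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(x))
  residues <- Map(function(s, e) x[s:e], starts, ends)
  headers <- sprintf("%s_contig%02d synthetic", name, seq_len(nContigs))
  canonicalBreaks(
    new("FastaFile", path = paste0(name, ".fa"), headers = headers,
        residues = unname(residues), lineLength = as.integer(lineWidth),
        lineBreaks = rep(list(integer(0)), nContigs),
        crlf = FALSE, trailingNewline = TRUE))
}

#' Generate a synthetic genome collection
#'
#' `nGenomes` independently mutated descendants of a single random ancestor.
#' All randomness flows from `model@seed`; the same model yields the same
#' collection.
#'
#' @param nGenomes number of genomes.
#' @param model a [MutationModel-class].
#' @param ancestorLength ancestor size in bases.
#' @param gc ancestor GC fraction.
#' @param nContigs contigs per genome (scalar or vector, recycled).
#' @param lineWidth sequence line width (scalar or vector, recycled).
#' @param softMask whether to lowercase random runs (scalar or vector).
#' @param baseName prefix for genome names.
#' @return list of [FastaFile-class] objects.
#' @examples
#' coll <- makeCollection(3, MutationModel(seed = 7L), ancestorLength = 2000)
#' vapply(coll, fastaPath, character(1))
#' @export
makeCollection <- function(nGenomes, model, ancestorLength = 20000,
                           gc = 0.45, nContigs = 1L, lineWidth = 70L,
                           softMask = FALSE, baseName = "genome") {
  stopifnot(nGenomes >= 1)
  ancestor <- makeAncestor(ancestorLength, gc, seed = model@seed)
  nContigs <- rep_len(nContigs, nGenomes)
  lineWidth <- rep_len(as.integer(lineWidth), nGenomes)
  softMask <- rep_len(softMask, nGenomes)
  lapply(seq_len(nGenomes), function(i) {
    mutateGenome(ancestor, model,
                 name = sprintf("%s%03d", baseName, i),
                 nContigs = nContigs[i], lineWidth = lineWidth[i],
                 softMask = softMask[i],
                 seed = (model@seed %% 1000000L) * 1000L + i)
  })
}

#' Fix up line-break metadata after synthetic construction
#'
#' Synthetic files carry a uniform line width; their `lineBreaks` slots are
#' placeholders. This regenerates them to the canonical wrap so the object
#' is indistinguishable from one read back from disk.
#' @keywords internal
#' @noRd
canonicalBreaks <- function(f) {
  if (is.na(f@lineLength)) return(f)
  f@lineBreaks <- lapply(f@residues, function(r) {
    len <- length(r)
    if (len == 0L) return(integer(0))
    q <- len %/% f@lineLength; rem <- len %% f@lineLength
    as.integer(c(rep(f@lineLength, q), if (rem) rem))
  })
  f
}
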