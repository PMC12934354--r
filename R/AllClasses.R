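## S4 classes and byte-level sequence utilities shared across modules.

#' @import methods
NULL

## ---------------------------------------------------------------------------
## Byte lookup tables (index = byte value + 1)

.byteTables <- local({
  upper <- as.raw(0:255)
  lo <- as.integer(charToRaw("a")):as.integer(charToRaw("z"))
  upper[lo + 1L] <- as.raw(lo - 32L)

  comp <- as.raw(0:255)
  pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"),
                 c("U", "A"),
                 ## IUPAC ambiguity complements (kept for completeness; such
                 ## bases never participate in matching)
                 c("R", "Y"), c("Y", "R"), c("S", "S"), c("W", "W"),
                 c("K", "M"), c("M", "K"), c("B", "V"), c("V", "B"),
                 c("D", "H"), c("H", "D"), c("N", "N"))
  for (i in seq_len(nrow(pairs))) {
    a <- as.integer(charToRaw(pairs[i, 1L]))
    b <- charToRaw(pairs[i, 2L])
    comp[a + 1L] <- b
  }

  isACGT <- rep(FALSE, 256)
  isACGT[as.integer(charToRaw("ACGT")) + 1L] <- TRUE

  acgtMap <- as.raw(0:255)
  acgtMap[!isACGT] <- charToRaw("A")

  isLower <- rep(FALSE, 256)
  isLower[lo + 1L] <- TRUE

  list(upper = upper, comp = comp, isACGT = isACGT, acgtMap = acgtMap,
       isLower = isLower)
})

#' Uppercase a raw residue vector
#' @keywords internal
#' @noRd
upperBytes <- function(r) .byteTables$upper[as.integer(r) + 1L]

#' Reverse complement of a raw residue vector (byte-level)
#' @keywords internal
#' @noRd
revComp <- function(r) rev(.byteTables$comp[as.integer(r) + 1L])

#' Which bytes are A/C/G/T (uppercase)
#' @keywords internal
#' @noRd
isACGTBytes <- function(r) .byteTables$isACGT[as.integer(r) + 1L]

#' Map non-ACGT bytes to 'A' (reference buffer alphabet)
#' @keywords internal
#' @noRd
acgtMapBytes <- function(r) .byteTables$acgtMap[as.integer(r) + 1L]

#' Which bytes are lowercase letters
#' @keywords internal
#' @noRd
isLowerBytes <- function(r) .byteTables$isLower[as.integer(r) + 1L]

## ---------------------------------------------------------------------------
## MutationModel

#' Mutation model for synthetic genome collections
#'
#' Describes the divergence process applied to a common ancestor when
#' simulating a genome collection: single-nucleotide substitutions, short
#' insertions/deletions, reverse-complemented inversions, segment
#' translocations and runs of `N`. Rates are per base (snpRate, indelRate)
#' or expected events per genome (inversionRate, rearrangeRate, nRunRate).
#'
#' @slot snpRate substitutions per base.
#' @slot indelRate indel events per base.
#' @slot indelLen geometric mean indel length (bases).
#' @slot inversionRate expected inversion events per genome.
#' @slot inversionLen mean inversion length (bases).
#' @slot rearrangeRate expected segment-swap events per genome.
#' @slot nRunRate expected N-run events per genome.
#' @slot nRunLen mean N-run length (bases).
#' @slot seed integer seed for the shared pseudo-random source.
#' @export
setClass("MutationModel", representation(
  snpRate = "numeric", indelRate = "numeric", indelLen = "numeric",
  inversionRate = "numeric", inversionLen = "numeric",
  rearrangeRate = "numeric", nRunRate = "numeric", nRunLen = "numeric",
  seed = "integer"
))

setValidity("MutationModel", function(object) {
  rates <- c(object@snpRate, object@indelRate)
  if (any(rates < 0 | rates > 1)) return("per-base rates must be in [0, 1]")
  if (any(c(object@inversionRate, object@rearrangeRate, object@nRunRate) < 0))
    return("event rates must be non-negative")
  if (object@indelLen < 1 || object@inversionLen < 1 || object@nRunLen < 1)
    return("mean lengths must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' Construct a MutationModel
#'
#' @param snpRate substitutions per base (default 0.01).
#' @param indelRate indel events per base (default 5e-4).
#' @param indelLen geometric mean indel length (default 3).
#' @param inversionRate expected inversions per genome (default 1).
#' @param inversionLen mean inversion length in bases (default 300).
#' @param rearrangeRate expected segment swaps per genome (default 0.5).
#' @param nRunRate expected N-run insertions per genome (default 0.5).
#' @param nRunLen mean N-run length in bases (default 30).
#' @param seed integer seed.
#' @return a [MutationModel-class] object.
#' @examples
#' MutationModel(snpRate = 0.02, seed = 7L)
#' @export
MutationModel <- function(snpRate = 0.01, indelRate = 5e-4, indelLen = 3,
                          inversionRate = 1, inversionLen = 300,
                          rearrangeRate = 0.5, nRunRate = 0.5, nRunLen = 30,
                          seed = 1L) {
  new("MutationModel", snpRate = snpRate, indelRate = indelRate,
      indelLen = indelLen, inversionRate = inversionRate,
      inversionLen = inversionLen, rearrangeRate = rearrangeRate,
      nRunRate = nRunRate, nRunLen = nRunLen, seed = as.integer(seed))
}

setMethod("show", "MutationModel", function(object) {
  cat("MutationModel: snp", object@snpRate, "indel", object@indelRate,
      "(len", object@indelLen, ") inversions", object@inversionRate,
      "rearrange", object@rearrangeRate, "Nruns", object@nRunRate,
      "seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CodecConfig

#' Codec configuration
#'
#' Tunable parameters of the codec plus one boolean switch per
#' approximate-match technique, so each can be disabled independently.
#'
#' @slot k k-mer anchor length for the reference index.
#' @slot minMatchLength minimum MEM length kept (>= k).
#' @slot sampling reference index sampling step (1 = every position).
#' @slot scoreInitial initial mismatch score Y, percent of the threshold.
#' @slot scoreStepX x = maximum run of consecutive mismatches before
#'   adjacent encoding terminates; per-base step is 100/x percent.
#' @slot gapBreaksMax matches shorter than this between mutually
#'   corresponding neighbors are dropped by the gap-breaks filter.
#' @slot corrWindow correspondence window: two matches are linked only if
#'   fewer than this many other matches lie between them.
#' @slot refExtendThreshold contigs whose matched-base fraction is strictly
#'   below this are appended to the reference buffer.
#' @slot refSizeCap hard cap on reference buffer length (bases).
#' @slot useGapsDelta,useGapBreaks,useGapEncoding,useAdjacentEncoding,useMismatchMatrix
#'   ablation switches for the five techniques.
#' @export
setClass("CodecConfig", representation(
  k = "integer", minMatchLength = "integer", sampling = "integer",
  scoreInitial = "numeric", scoreStepX = "integer",
  gapBreaksMax = "integer", corrWindow = "integer",
  refExtendThreshold = "numeric", refSizeCap = "numeric",
  useGapsDelta = "logical", useGapBreaks = "logical",
  useGapEncoding = "logical", useAdjacentEncoding = "logical",
  useMismatchMatrix = "logical"
))

setValidity("CodecConfig", function(object) {
  if (object@k < 8L) return("k must be >= 8")
  if (object@k > 26L) return("k must be <= 26")
  if (object@minMatchLength < object@k) return("minMatchLength must be >= k")
  if (object@sampling < 1L) return("sampling must be >= 1")
  if (object@scoreInitial < 0 || object@scoreInitial > 100)
    return("scoreInitial must be a percentage in [0, 100]")
  if (object@scoreStepX < 1L) return("scoreStepX must be >= 1")
  if (object@gapBreaksMax < 0L) return("gapBreaksMax must be >= 0")
  if (object@corrWindow < 0L) return("corrWindow must be >= 0")
  if (object@refExtendThreshold < 0 || object@refExtendThreshold > 1)
    return("refExtendThreshold must be in [0, 1]")
  TRUE
})

#' Construct a CodecConfig
#'
#' Defaults: Y = 25% initial score, x = 10 (10% per-base step), gap-breaks
#' threshold 256, correspondence window 64; k-mer anchors of 24 with
#' minimum match length 24 and dense (sampling 1) indexing; reference
#' extension below 50% match coverage.
#'
#' @param k,minMatchLength,sampling,scoreInitial,scoreStepX,gapBreaksMax,corrWindow,refExtendThreshold,refSizeCap
#'   see [CodecConfig-class].
#' @param useGapsDelta,useGapBreaks,useGapEncoding,useAdjacentEncoding,useMismatchMatrix
#'   technique switches (all `TRUE` by default).
#' @return a [CodecConfig-class] object.
#' @examples
#' CodecConfig()
#' CodecConfig(useAdjacentEncoding = FALSE)
#' @export
CodecConfig <- function(k = 24L, minMatchLength = 24L, sampling = 1L,
                        scoreInitial = 25, scoreStepX = 10L,
                        gapBreaksMax = 256L, corrWindow = 64L,
                        refExtendThreshold = 0.5, refSizeCap = 2^31 - 1,
                        useGapsDelta = TRUE, useGapBreaks = TRUE,
                        useGapEncoding = TRUE, useAdjacentEncoding = TRUE,
                        useMismatchMatrix = TRUE) {
  new("CodecConfig", k = as.integer(k),
      minMatchLength = as.integer(minMatchLength),
      sampling = as.integer(sampling), scoreInitial = scoreInitial,
      scoreStepX = as.integer(scoreStepX),
      gapBreaksMax = as.integer(gapBreaksMax),
      corrWindow = as.integer(corrWindow),
      refExtendThreshold = refExtendThreshold, refSizeCap = refSizeCap,
      useGapsDelta = useGapsDelta, useGapBreaks = useGapBreaks,
      useGapEncoding = useGapEncoding,
      useAdjacentEncoding = useAdjacentEncoding,
      useMismatchMatrix = useMismatchMatrix)
}

setMethod("show", "CodecConfig", function(object) {
  on <- c(gapsDelta = object@useGapsDelta, gapBreaks = object@useGapBreaks,
          gapEncoding = object@useGapEncoding,
          adjacent = object@useAdjacentEncoding,
          mismatchMatrix = object@useMismatchMatrix)
  cat(sprintf(
    "CodecConfig: k=%d minLen=%d sampling=%d Y=%g%% x=%d gapBreaks<%d window=%d refExt<%g\n",
    object@k, object@minMatchLength, object@sampling, object@scoreInitial,
    object@scoreStepX, object@gapBreaksMax, object@corrWindow,
    object@refExtendThreshold))
  cat("  techniques on:", paste(names(on)[on], collapse = " "),
      if (!all(on)) paste("| off:", paste(names(on)[!on], collapse = " ")) else "",
      "\n")
})

## ---------------------------------------------------------------------------
## FastaFile

#' One FASTA file with full formatting metadata
#'
#' Residues are stored as raw byte vectors (original letter case preserved);
#' per-record line lengths, line-ending style and the trailing-newline flag
#' are captured so the file can be restored byte-for-byte.
#'
#' @slot path relative path of the file within the collection root.
#' @slot headers character vector, one header per record (text after '>').
#' @slot residues list of raw vectors, one per record.
#' @slot lineLength integer: the uniform sequence line width, or `NA` if the
#'   file wraps irregularly.
#' @slot lineBreaks list of integer vectors: per-record sequence line
#'   lengths as found in the file.
#' @slot crlf logical: `TRUE` if lines end with CRLF.
#' @slot trailingNewline logical: `TRUE` if the file ends with a newline.
#' @export
setClass("FastaFile", representation(
  path = "character", headers = "character", residues = "list",
  lineLength = "integer", lineBreaks = "list", crlf = "logical",
  trailingNewline = "logical"
))

setValidity("FastaFile", function(object) {
  if (length(object@headers) != length(object@residues))
    return("headers and residues must have equal length")
  if (length(object@lineBreaks) != length(object@residues))
    return("lineBreaks and residues must have equal length")
  if (any(grepl("[\r\n]", object@headers)))
    return("headers must not contain end-of-line bytes")
  ok <- vapply(object@residues, function(r)
    is.raw(r) && !any(r == as.raw(0x0A) | r == as.raw(0x0D)), logical(1))
  if (!all(ok)) return("residues must be raw vectors without EOL bytes")
  TRUE
})

setMethod("show", "FastaFile", function(object) {
  cat(sprintf("FastaFile '%s': %d record(s), %s line width, %s%s\n",
              object@path, length(object@headers),
              if (is.na(object@lineLength)) "irregular"
              else as.character(object@lineLength),
              if (object@crlf) "CRLF" else "LF",
              if (object@trailingNewline) "" else ", no trailing newline"))
})

#' Number of records in a FastaFile
#' @param x a [FastaFile-class].
#' @return integer.
#' @export
nRecords <- function(x) length(x@headers)

#' Record headers of a FastaFile
#' @param x a [FastaFile-class].
#' @return character vector.
#' @export
recordHeaders <- function(x) x@headers

#' Record residues of a FastaFile as character strings
#' @param x a [FastaFile-class].
#' @return character vector (original letter case).
#' @export
recordSequences <- function(x) vapply(x@residues, rawToChar, character(1))

#' Path of a FastaFile within its collection
#' @param x a [FastaFile-class].
#' @return character scalar.
#' @export
fastaPath <- function(x) x@path

#' Total residue count of a FastaFile
#' @param x a [FastaFile-class].
#' @return numeric scalar (bases).
#' @export
totalBases <- function(x) sum(vapply(x@residues, length, integer(1)))
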