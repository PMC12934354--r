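---
title: "famec: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famec: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famec)
```

## The compression model

famec compresses a collection of FASTA files by *relative compression*:
contigs are encoded against a single reference buffer that grows as the
collection is processed. The first contig enters the buffer essentially
verbatim; each later contig is decomposed into maximal exact matches (MEMs)
against the buffer — on both strands — and the residue between matches is
coded with a handful of complementary techniques. Decompression replays the
records in order, rebuilding the identical buffer, so no side reference is
stored.

### Match finding

The reference buffer indexes one `k`-mer (default `k = 24`) per `sampling`
positions as a sorted vector of packed 2-bit numeric keys. A contig is
scanned by sliding its own `k`-mers over the index (`findInterval` on the
packed keys), extending each seed hit left and right to maximality, and
deduplicating per reference diagonal. Reverse-complement matches are found
by scanning the reverse complement of the contig and mapping coordinates
back. Packed keys are exact in doubles only up to `4^26`, so `k <= 26` is
enforced. The finder is validated against a brute-force MEM oracle in the
test suite.

From the MEM set the encoder keeps a non-overlapping chain (greedy by
length, trimming overlaps) of matches of at least `minMatchLength` bases.

### The coded streams

Each record becomes tokens in eight logical streams (see
`docs/FORMAT.md` for the byte-level grammar):

- **literals** carries raw residue bytes, match marks and per-base codes;
- **lengths** carries match lengths; **offsets** carries reference
  positions the delta coder could not predict;
- **gapsDelta**, **flags** and **truncations** carry the model described
  below; **headers** and **fileMeta** restore the exact file bytes.

### Mismatch encoding matrix

A substituted base can only be one of three bases, so relative to the
aligned reference base it is coded in 2 bits: code 0 for the transition
partner (A↔G, C↔T) — the most frequent substitution class in real data —
then 1 and 2 for the transversions, and 3 as an escape for non-ACGT bytes:

```{r}
mismatchCode("A", "G")   # transition
mismatchCode("T", "G")
rawToChar(mismatchDecode("T", 0:2))
```

### Corresponding matches, gap-breaks and gaps-delta

Two matches are *corresponding* when they lie on the same reference
diagonal (`refStart - start` equal) on the forward strand — i.e. the
contig and the reference differ only by substitutions between them.
`detectCorresponding()` pairs each match with its nearest same-diagonal
successor within a window of 64 matches. The *gap-breaks filter* removes
short matches (≤ 256 bases) strictly inside such a pair: they interrupt a
junction that gap encoding codes more cheaply than two extra match
records. *Gaps-delta coding* then predicts each match offset from
previously emitted same-diagonal candidates, so a predicted match costs a
small integer (its candidate rank) instead of an absolute offset:

```{r}
toy <- data.frame(start    = c(0, 310, 620, 680, 990, 1300, 1610),
                  refStart = c(0, 410, 1520, 780, 1490, 1400, 2110),
                  length   = c(300, 300, 50, 300, 300, 300, 300),
                  rc = FALSE)
filtered <- gapBreaksFilter(detectCorresponding(toy))
gapsDeltaEncode(filtered)$deltas
```

### Encoding in gaps

The junction between two corresponding matches has equal length on both
sides, so it is coded per base: one flag (substituted or not) and, where
flagged, one matrix code. Because the flanking matches are maximal, the
first and last junction base are known mismatches and are coded without
flags. (After overlap trimming a border base can happen to be equal; the
matrix diagonal is the escape code, which carries the raw byte, so the
decoder needs no special case.) Junctions containing non-ACGT bytes are
left to the raw-literal path, where an N run costs almost nothing after
the backend compressor instead of two bytes per base as escapes.

### Score-bounded adjacent encoding

Regions adjacent to a match end start with a known mismatch, and flag
coding is often worth extending beyond it. A score automaton decides how
far: the score starts at 25% (in integer units of `score * x`), each
mismatch adds 100, each match subtracts 100 with a floor at zero, and
coding stops at the mismatch that drives the score to `100 * x` (default
`x = 10`, i.e. a 10% step):

```{r}
# a solid run of mismatches terminates after 8 bases at the defaults
scoreAutomaton(rep(FALSE, 12), scoreInitial = 25, scoreStepX = 10)
```

### Archive backend

Every stream section is stored with the smallest of four encodings: raw,
xz, 2-bit nucleotide packing, and 2-bit packing followed by xz. The
packing matters mainly for the literals stream: the first genome of a
collection is nearly i.i.d. bases, which a general-purpose compressor
cannot reduce to the 2-bits-per-base bound, while packing first and
compressing the packed bytes can.

## Parameters

`CodecConfig()` holds the shipped defaults: initial score 25%, score step
`x = 10`, gap-breaks limit 256 bases, correspondence window 64 matches,
`k = 24`, minimum match length 24, index sampling 1, reference extension
threshold 0.5 (a contig is appended to the buffer only when less than half
of it was already aligned), and five switches (`useGapsDelta`,
`useGapBreaks`, `useGapEncoding`, `useAdjacentEncoding`,
`useMismatchMatrix`) that ablate individual techniques — the archive
stores its configuration, so any combination round-trips.

## The synthetic generator

`makeAncestor()` draws an i.i.d. genome at a given GC content;
`mutateGenome()` applies a seeded `MutationModel` (SNPs, short indels,
inversions, translocations, N runs, optional soft-masking) and formats the
result as a `FastaFile` with configurable contig count and line width;
`makeCollection()` derives a whole collection from one ancestor. All
randomness is seed-derived and reproducible. The generator produces
substitution-dominated divergence between close relatives — the regime the
codec targets — and is *not* a population-genetics simulator: mutation
events are independent and uniformly placed, with no recombination, no
hotspots and no selection.

## Study sizes and design decisions

Numbers quoted here and in the test suite are the package's own choices of
study condition:

- the ratio study uses 10 genomes × 100 kb at 1% SNP-only divergence
  (measured ratio ≈ 26);
- the redundancy study stores 2, 5 and 10 identical copies of a 20 kb
  genome (per-copy growth far below 2% of the genome's bytes);
- the ablation study compares the full configuration against each
  single-technique ablation over 10 seeded trials of 8 genomes × 40 kb at
  3% SNP-only divergence — SNP-only because these techniques act on
  substitution-type divergence, and 3% to maximize junction signal per
  unit runtime. The full configuration won all 10 trials, though margins
  over the no-gap-encoding ablation are small (single-digit bytes): at
  realistic SNP densities the score automaton rarely terminates inside a
  junction, so adjacent encoding captures most of the same information.

Other decisions worth knowing:

- **Appending re-encodes.** `appendToArchive()` decodes, verifies and
  re-compresses the union. The reference buffer depends on record order,
  so true incremental append would freeze a possibly-stale buffer;
  re-encoding keeps one code path and the compression quality of a fresh
  archive.
- **Verification is mandatory.** Every decoded file is checked against a
  stored Adler-32 checksum and byte count; corruption anywhere in the
  payload surfaces as a typed `famec_corrupt_error` rather than silent
  damage.
- **Listing never decodes sequences.** Stream sections are located at
  open time but decompressed lazily, so `listArchive()` touches only the
  metadata sections.

## Limitations

- The whole archive and the reference buffer are held in memory; the
  reference is capped (`refSizeCap`) but inputs are not streamed.
- Selective extraction must still replay all records in archive order to
  rebuild the shared reference; it saves write work, not decode work.
- The codec is byte-oriented FASTA only: FASTQ, alignments and compressed
  inputs are out of scope.
- Compression speed is that of vectorised R; the design favours
  verifiability over raw throughput.
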