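# famec archive format (version 1)

A famec archive is a single binary file restoring a FASTA collection
byte-for-byte. All integers are unsigned LEB128 varints (7 bits per byte,
little-endian groups, high bit = continuation) unless stated otherwise.

## Container layout

```
magic      4 bytes   "FAMC"
version    varint    1
config     10 varints (codec configuration, below)
section[8]           one per logical stream, in fixed order
```

Each section is:

```
backend    1 byte    0 stored | 1 xz | 2 two-bit packed | 3 two-bit packed then xz
size       varint    payload byte count
payload    size bytes
```

The writer tries every applicable backend and keeps the smallest payload.
Backend 2/3 ("two-bit packed") splits the section into alternating runs of
ACGT and non-ACGT bytes and packs ACGT runs four bases per byte
(A=0, C=1, G=2, T=3; the first base occupies the low two bits). Its payload
header is: varint unpacked length, varint first-run-is-ACGT (0/1), varint
run count, then the run lengths as varints, then the concatenated run
payloads (each ACGT run padded to a whole byte).

### Codec configuration (10 varints)

| #  | field               | encoding                      |
|----|---------------------|-------------------------------|
| 1  | k                   | k-mer size (8..26)            |
| 2  | minMatchLength      | bases                         |
| 3  | sampling            | index step                    |
| 4  | scoreInitial        | percent × 1000                |
| 5  | scoreStepX          | x (step = 100/x percent)      |
| 6  | gapBreaksMax        | bases                         |
| 7  | corrWindow          | matches                       |
| 8  | refExtendThreshold  | fraction × 10^6               |
| 9  | refSizeCap          | bases                         |
| 10 | feature flags       | bit 0 gaps-delta, 1 gap-breaks, 2 gap encoding, 3 adjacent encoding, 4 mismatch matrix |

## Logical streams (section order)

1. **literals** — per-record token bytes (grammar below).
2. **offsets** — explicit reference offsets for matches the gaps-delta
   coder could not predict, stored as `2*refStart` for forward matches and
   `2*refStart + 1` for reverse-complement matches.
3. **lengths** — one entry per match: `matchLength - minMatchLength`.
4. **gapsDelta** — one entry per match when gaps-delta coding is on:
   0 = explicit offset follows in `offsets`; d ≥ 1 = the reference
   position is predicted from the d-th candidate among preceding
   same-diagonal corresponding matches.
5. **flags** — per-base mismatch flags for scored regions, serialized
   sparsely: varints (total count, set count, zero-run before each set
   flag).
6. **truncations** — one entry per non-empty post-match region (see
   grammar) plus one per adjacent-encoding block.
7. **headers** — FASTA header lines (without `>`), each terminated by LF.
8. **fileMeta** — per-file metadata blocks (below).

Streams 2–6 are varint sequences; 1, 7, 8 are byte streams.

## Literal-stream grammar

Sentinel bytes never collide with residues; residue bytes equal to a
sentinel are escaped with `LIT_ESCAPE`:

```
SEQ_MARK   0x04   end of record
GAP_MARK   0x05   reserved, unused in version 1
LIT_ESCAPE 0x06   next literal byte is verbatim
MATCH_MARK 0x25   one match (length from the lengths stream, position
                  from gapsDelta/offsets)
```

Per record:

```
record := region? (MATCH_MARK region?)* SEQ_MARK
```

The first region (before any match) and a region whose preceding token is
`SEQ_MARK` are *open* regions without a truncations entry. Every non-empty
region that follows a match consumes one **truncations** entry `e`:

- `e = 0` — open region, no right-adjacent block.
- odd `e` — *gap region* of `L = (e-1)/2` bases (a junction between two
  corresponding matches on the same diagonal). The first and last gap base
  are known mismatches (or matrix-escapes after match trimming) and are
  coded without flags; each of the `L-2` interior bases consumes one flags
  entry, and a code is emitted only where the flag is set. Codes appear in
  the literals stream in order: first base, flagged interior bases, last
  base (when `L ≥ 2`).
- even `e ≥ 2` — open region starting with a *right-adjacent* block of
  `e/2 - 1` scored bases after the known mismatch.

An open region is: optional right-adjacent block, optional left-adjacent
block, then raw residue bytes. Adjacent blocks start with the code of the
known mismatch adjacent to the match (a byte ≤ 0x03, which is how a
left-adjacent block is recognised at the end of a region); scored bases
each consume one flags entry, mismatches one code. Left-adjacent blocks
consume their own truncations entry (scored-base count). A *code* is one
byte 0x00–0x03; 0x03 escapes a non-ACGT base, whose raw byte follows.

Scoring (both adjacent directions): score starts at `scoreInitial`
percent, in integer units of `score × x`; a mismatch adds 100, a match
subtracts 100 with a floor at 0; the block terminates at the mismatch that
drives the score to ≥ 100·x, and that mismatch is the last base consumed.

## fileMeta block (one per file)

```
pathLen varint, path bytes (UTF-8, '/'-separated relative path)
flags   varint   bit 0 CRLF line endings, 1 trailing newline,
                 2 uniform line length
rawSize varint   original file byte count
adler32 varint   checksum of the original bytes
nRec    varint   record count
line wrapping    uniform: one varint (line length)
                 else per record: varint count, then the residue indices
                 after which a line break occurs
case masks       per record: varint run count, varint first-run-is-lower,
                 then the run lengths (alternating case runs)
```

Decompression replays every record in order (the shared reference buffer
is rebuilt exactly as during compression), re-applies wrapping, case, line
endings and trailing-newline state, and verifies `rawSize` and the Adler-32
checksum; any mismatch raises a `famec_corrupt_error`.
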