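---
title: "Rewriting 5' read structures for barcode-expecting tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rewriting 5' read structures for barcode-expecting tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodify)
```

## The procedure

Plate-based single-cell libraries (SMART-seq family, Smart-seq3xpress,
SMART-seq-total, STORM-seq) have one cell per well and no in-read cell
barcode; many carry a 5' UMI, often followed by a fixed
library-construction linker/spacer. Quantifiers built for droplet data
(STARsolo, zUMIs, Alevin) refuse such reads because they expect a cell
barcode at a declared position. `barcodify` makes plate-based reads
consumable by those tools by rewriting the 5' technical region of every
read in one streaming pass.

Every input read is decomposed **positionally**:

* `UMI` — the first `umi_length` bases (`u >= 0`);
* `LINKER` — the next `linker_length` bases (`l >= 0`);
* `INSERT` — everything after.

Qualities partition identically. Given a barcode `B` the output is
`B + UMI + INSERT` (default) or, with `umi_first`, `UMI + B + INSERT`;
linker bases and their qualities are always discarded. The four useful
parameterizations are the cross of `u > 0` and `l > 0`: plain 5'
prepending (`u = 0, l = 0`), UMI preserved at the 5' end with the
barcode inserted after it, prepending with linker removal, and the
combination. For every emitted read

```
nchar(out) = nchar(in) + nchar(B) - l
```

and the quality string has exactly the sequence's length. Records are
never reordered, and headers (id and comment) pass through untouched.

## Assumptions and what they imply

* **The technical region sits at a fixed 5' offset.** The linker is
  identified by length and position, not by sequence matching. This is
  deterministic, alignment-free, and O(n); it is the right model for
  spacers ligated at a fixed position, and the wrong tool for adapters
  at variable positions (use an adapter trimmer for those first).
* **One file per invocation.** The tool is designed for the mate that
  carries the UMI (read 2 in a STORM-seq-style library); the other mate
  is untouched and pairing is the caller's responsibility.
* **Qualities are opaque.** Encoding is assumed Phred+33 but scores are
  never decoded; only sequence/quality length equality is enforced, so
  the transformation works for any encoding.
* **Sequence alphabet is not policed on input.** Any non-whitespace
  characters stream through, so lowercase masking, IUPAC ambiguity
  codes, and unusual base calls survive. (Only the *inserted* barcode is
  validated, against the IUPAC set.)

## Parameters

| parameter | default | meaning |
|---|---|---|
| `barcode` | `"CATATAC"` | sequence to insert; IUPAC, any length; `""` inserts nothing |
| `umi_length` (`u`) | 0 | 5' bases treated as the UMI (bases) |
| `linker_length` (`l`) | 0 | bases after the UMI to remove (bases) |
| `umi_first` | `FALSE` | keep the UMI at the 5' end, barcode after it |
| `fill_quality` | `"I"` | quality character for inserted bases |
| `short_read_policy` | `"fail"` | reads shorter than `u + l`: abort or skip |

The 7-base default barcode gives the geometry a solo-style aligner is
told about for an 8-base-UMI library: cell-barcode start 1 / length 7,
UMI start 8 / length 8 (1-based inclusive coordinates throughout).

`fill_quality = "I"` is Phred 40 in the +33 encoding: synthetic bases
were never sequenced, and the maximal-confidence character guarantees no
downstream quality filter removes the barcode the aligner was promised.
UMI bases keep their original qualities in `umi_first` mode — they are
real sequenced bases and their quality is information.

`short_read_policy = "fail"` is the default because silently truncating
or passing through a read shorter than `u + l` would corrupt the
declared barcode/UMI geometry for every downstream record. `"skip"`
drops such reads and counts them in the run's `transform_result`
(`records_in == records_out + records_skipped`, an invariant the class
itself enforces).

## Numerical and I/O choices

* **Strict 4-line FASTQ.** Wrapped (multi-line) FASTQ is rejected with a
  parse error carrying the absolute line number; modern sequencer output
  is strictly 4-line, and strictness surfaces corrupt files early.
  A repeated title on the `+` separator line is accepted on input and
  always written back as a bare `+`.
* **Compression is detected from content.** The reader peeks at the
  first two bytes and looks for the gzip magic (`1f 8b`), so a
  misnamed file or compressed data on standard input both decompress.
  The peek is explicit rather than delegated to `gzcon()` because
  `gzcon()` mis-handles streams shorter than two bytes (it returns
  garbage for an empty stream), and an empty input must mean zero
  records, not a parse error.
* **Streaming.** Records move through the engine in fixed-size chunks
  (default 10,000 records), so peak memory is bounded by the chunk, not
  the file; 100,000 records round-trip through gzip on both ends in a
  few seconds on one core. One exception: gzip-compressed data arriving
  on standard input is first spooled to a temporary file in fixed-size
  chunks and then decompressed, because R exposes no incremental
  decompressor that can resume a stream whose first bytes were already
  consumed by the content peek. Memory stays bounded; plain-text
  standard input streams directly.
* **Degenerate inputs.** An empty barcode with `u = l = 0` is the exact
  identity (byte-identical output); an empty input file yields an empty
  output and zero counts; a zero-length sequence line is a valid read
  and is shorter than any positive `u + l`.
* **Error taxonomy.** Failures are classed conditions, which the CLI
  maps to exit statuses: 1 usage, 2 I/O or parse, 3 data (bad barcode or
  short read under `fail`). Parse errors report absolute line numbers;
  short-read errors report the read id and its whole-file ordinal, also
  across chunk boundaries.

## The synthetic-read generator

`generate_fixture()` emulates the read-2 structure of a UMI-bearing,
barcode-free plate-based library: a random `u`-base UMI, one fixed
`l`-base linker drawn per batch, and a random insert with length uniform
on `insert_length_range`, plus an optional count of deliberately short
reads (total length uniform on `0 .. u+l-1`). Defaults are `u = 8`,
`l = 6`, inserts 20–80 bases: an 8-base UMI matches the aligner geometry
above, and 6 linker bases make barcode + UMI + linker span 21 bases —
the 5' region an aligner would be told to clip on the barcode mate of a
STORM-seq-style library. (The 6 is arithmetic — 21 − 7 − 8 — i.e. a
modeling choice, not a protocol measurement.) Qualities are uniform over
`#`..`I` to exercise the plausible Phred+33 band.

Every read comes with a ground-truth decomposition row, and identical
parameters plus seed reproduce byte-identical output without disturbing
the caller's RNG state.

What the generator does **not** emulate: sequencing error models, base
composition bias, PCR duplicates, homopolymer artifacts, or real
adapter contamination. Tests passing on these fixtures therefore
demonstrate the *rewrite* is exact — base provenance, length arithmetic,
ordering, conservation — on reads of realistic shape; they say nothing
about biological interpretation of real libraries, which is the
downstream toolchain's job.

## Validation design

The engine is checked against an independently written naive oracle
that explodes each read into character vectors and reassembles the
expected output by slicing and concatenation — sharing no code with the
vectorized `substr`/`paste0` implementation. Equivalence is asserted
byte for byte on 1,000+ seeded reads per mode, alongside property-style
tests (conservation, length arithmetic, header immutability, round-trip
I/O, gzip/plain/stdin equivalence) and an error matrix for every
documented failure path. Problem sizes in the suite (hundreds to tens of
thousands of reads) were chosen so the whole suite completes in seconds
while still exercising chunk boundaries.

## Known limitations

* Only the 5' technical region is rewritten; 3'-end insertion is not
  supported.
* Linker removal is positional; sequence-match (adapter-style) trimming
  with mismatches is out of scope.
* No paired-file synchronized mode, barcode whitelists, demultiplexing,
  UMI deduplication, or quality trimming — the tool does one rewrite,
  upstream of tools that do those jobs.
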