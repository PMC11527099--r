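---
title: "Scoring motif conservation in multiple alignment (MAF) files"
author: "mafconserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring motif conservation in multiple alignment (MAF) files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(mafconserve))
```

## The problem

Whole-genome alignments — typically distributed in the Multiple Alignment
Format (MAF) — record how the genomes of related species line up block by
block, with insertions and deletions represented as `-` gap columns. A
recurring comparative-genomics question is whether a short functional
element (a transcription-factor binding site, a restriction site, any
motif of interest) found in one genome is *conserved* in the aligned
genomes: conserved instances are more likely to be functional.

`mafconserve` answers that question in two steps:

1. **Scan**: locate every instance of a motif set in the ungapped
   sequence of a chosen row of each alignment block. Motifs can be
   literal k-mers, regular expressions, or position weight matrices
   (PWMs) in JASPAR format.
2. **Score**: for each instance, walk the alignment columns it spans and
   compare the searched row with every other genome row, producing a
   binary *similarity vector* (one entry per motif base), a
   *conservation percentage*, and a per-instance *block average* over
   the compared genomes.

## Coordinate systems

MAF `s` lines carry a 0-based, strand-relative `start`, the count of
non-gap bases (`size`), and the gapped alignment text. The package keeps
three coordinate frames and converts between them explicitly:

* **ungapped offsets** — 0-based positions in the row's gap-free
  sequence; this is the frame motif engines operate in, so a motif
  interrupted by an alignment gap is still found;
* **gapped columns** — 0-based column indices in the block, computed
  through a `GapIndexMap` (`buildGapMap()`); the hit's column span is
  what conservation scoring slices out of every other row;
* **source coordinates** — `start + offset` with *inclusive* end
  `start + offset + len - 1`, matching the convention in which a 4-base
  motif starting at position 1,000 ends at 1,003. Reported coordinates
  stay in the strand-relative frame of the `s` line; no strand
  conversion is applied because none is defined for this report format.

## The similarity vector

For one hit and one compared row, both rows are sliced at the hit's
gapped column span. Columns gapped in **both** rows are skipped — they
carry no signal for either genome. Every other column is scored 1 when
the two characters are identical (an `N` never scores; an unknown base
cannot attest conservation) and 0 otherwise, and the emitted entries are
truncated to the motif length. The conservation percentage is
`100 * matches / motif length`, and the block-level value for a hit is
the unweighted mean over the compared genomes.

Worked through the canonical two cases with motif `ATCG`:

```{r}
similarityVector("A-TCG", "A-TCG", 4)   # identical rows -> 100%
similarityVector("A-TCG", "AT-CG", 4)   # shifted gap    -> 50%
```

The second case shows the subtle point of the default rule
(`mode = "truncating"`): the column where the reference has a gap but
the compared row has a base **is** scored (as a mismatch), and because
the emitted entries are then cut to the motif length, the final matching
column falls off the end — `[1,0,0,1]`, 50%. A stricter alternative that
scores only columns where the reference row has a base is available as
`mode = "refbase"`:

```{r}
similarityVector("A-TCG", "AT-CG", 4, mode = "refbase")  # -> 75%
```

Both rules are deliberate, documented choices: the truncating column
walk is the package default; the reference-base rule is the natural
per-motif-base reading and is exposed through
`conservationMode = "refbase"` in `mafMotifScan()`. Compared rows whose
slice is entirely gaps still contribute an all-zero vector by default —
dropping them silently would bias block averages upward — and can be
excluded with `dropAllGapRows = TRUE`.

## Motif classes and engines

**k-mers** are located with an Aho-Corasick multi-pattern automaton
(compiled code, `src/aho_corasick.cpp`): all patterns are matched in a
single pass over the text, and overlapping and nested occurrences are
all reported. Reverse-strand search simply adds each k-mer's reverse
complement to the automaton and tags its matches with strand `-`; the
reported `matchedSeq` is always the forward-frame text.

**Regular expressions** cannot be reverse-complemented symbolically, so
reverse-strand search scans the reverse complement of the *sequence* and
reflects match coordinates back into the original frame
(`start' = len - end - 1`). Overlapping matches are enumerated by
restarting one position after each match start, for parity with the
k-mer engine.

**PWMs** are converted to log-odds matrices
`score[b, i] = log2(p[b, i] / bg[b])` against a background nucleotide
model (uniform unless specified). Scores are in bits; any fixed base
would do since thresholds are calibrated in the same units. A
pseudocount of 0.01 is added to each probability cell (columns then
renormalized) before taking logs, so a JASPAR matrix containing an exact
zero — as the worked four-column example does — cannot produce `-Inf`
scores; the value is configurable. The reverse-complement matrix
(positions reversed, nucleotide rows complemented — an involution) is
scanned for the reverse strand against the same threshold. Windows
containing `N` are skipped.

### Threshold calibration

There is no closed-form null distribution for an arbitrary PWM, so the
score cutoff for a target p-value (default `1e-4`) is calibrated by
Monte Carlo: draw `nSamples = 100000` i.i.d. sequences of the motif
length from the background model, score them, and take the empirical
`(1 - p)` quantile. The calibration is deterministic given its seed
(default 42) and warns when `nSamples < 1/p`, where the tail cannot be
resolved. Each hit's empirical p-value is the tail fraction of the
calibration sample at or above its score (resolution `1/nSamples`,
floored at `1/(nSamples + 1)` so no hit reports p = 0). Tests verify the
calibration against exhaustive enumeration of all `4^L` sequences for
small L, allowing three binomial standard errors plus the quantization
atom `0.25^L` of the discrete score distribution. The paper-style
per-hit "false discovery rate" is computed as Benjamini–Hochberg
q-values over all PWM hits of a run — the standard, order-deterministic
choice where no procedure is prescribed.

## Parallelism and determinism

`chunkBlocks()` splits the MAF file into block-aligned byte ranges, so a
worker can `seek` and parse its chunk independently and no block is ever
split. Results are merged with a stable sort on
`(blockIndex, sourceStart, motifId)`; consequently JSON and CSV outputs
are byte-identical for any number of processes, which the test suite
checks for 1–8 workers on a 50-block synthetic file. Per-block search is
a deliberate boundary: a motif spanning two consecutive blocks is not
detectable, as block junctions are alignment discontinuities.

## The synthetic-alignment generator

`generateMaf()` builds test alignments with known ground truth: a random
reference row with motifs planted at fixed offsets (reverse-strand
plants insert the reverse complement), derived rows mutated by i.i.d.
substitution at a chosen rate, and structural events at a gap rate —
deletions (a `-` run of length 1–3 replacing bases of one row) and
insertions (a new column with a base in one row and `-` elsewhere, which
is what creates reference-gap columns). Column padding keeps the block
rectangular, so every generated file satisfies the MAF invariants by
construction and re-parses cleanly.

The generator emulates *alignment structure*, not evolution: there is no
phylogenetic tree, no transition/transversion bias, no realistic indel
length distribution, and mutations are independent across positions and
genomes. Passing tests on generated data therefore demonstrate the
correctness of parsing, scanning, coordinate mapping and scoring — not
that the conservation percentage is a calibrated evolutionary statistic
on real alignments. Default rates (5% substitution, 2% gap events) are
in the range typical of closely related vertebrate alignments and are
only defaults; every test fixes its own rates explicitly.

Problem sizes used in the shipped tests are desk-scale by design — the
worked examples are 5–7 columns; property checks use 50–200 blocks of
30–120 columns and sequences up to 500 bases, with 100,000-draw
calibrations against exhaustive enumeration at motif length ≤ 6. These
sizes give stable statistics while keeping the whole suite fast.

## Numerical and degenerate-input choices

* Threshold comparison is inclusive (`score >= threshold`), and at
  `pValue = 1` the threshold is pinned to the matrix minimum so every
  window passes.
* A window whose score ties the threshold exactly can fall on either
  side of it at one-ulp level depending on summation order; the test
  oracles exclude that measure-zero boundary rather than pretending it
  is determined.
* An empty similarity vector (no scored columns) yields 0% with a
  warning; a hit with no compared genomes yields an `NA` block average
  with a warning rather than being dropped.
* `i`/`e`/`q` MAF lines are tolerated and skipped; sequence text is
  uppercased on load; a stated `size` that disagrees with the non-gap
  count, or unequal row lengths within a block, is a structural error
  naming the block.
* Genome identifiers are matched by the `src` prefix before the first
  `.` (`hg38.chr1` → `hg38`), both for `searchIn` targeting and for
  `genomeIds` restriction; unmatched requested IDs produce a warning
  listing them.

## Known limitations

Approximate or IUPAC-degenerate k-mer matching, dinucleotide or
higher-order background models, exact DP p-values for PWMs,
phylogeny-weighted conservation (phastCons-style) and cross-block motif
detection are all out of scope. Conservation here is a descriptive
per-instance statistic, not a test against a neutral model.

## A complete run

```{r}
maf <- system.file("extdata", "example.maf", package = "mafconserve")
kmers <- system.file("extdata", "example_kmers.txt", package = "mafconserve")
res <- mafMotifScan(maf, kmerFile = kmers, reverseComplement = TRUE)
scanHits(res)[, c("motifId", "src", "sourceStart", "sourceEnd", "strand")]
conservationTable(res)[, c("motifId", "comparedSrc", "similarityVector",
                           "conservationPct", "blockAvgPct")]
```

The same pipeline is exposed as a shell command in
`exec/mafconserve` (flags `--maf_file`, `--kmer_file`, `--jaspar_file`,
`--regexes`, `--search_in`, `--genome_ids`, `--reverse_complement`,
`--processes`, `--background_frequencies`, plus the extensions
`--p_value`, `--seed`, `--conservation_mode`, `--output_prefix`).
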