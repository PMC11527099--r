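# mafconserve

Motif detection and conservation scoring in Multiple Alignment Format
(MAF) files.

Whole-genome alignments in MAF format record, block by block, how the
genomes of related species line up, with indels written as `-` gap
columns. `mafconserve` finds instances of short DNA motifs — literal
k-mers, regular expressions, or JASPAR position weight matrices (PWMs)
— in a chosen genome row of each block, and quantifies how well each
instance is conserved in every other aligned genome. It is intended for
comparative genomicists who want to ask, directly of an alignment,
"is this binding site / element / pattern conserved, and where?"

## Method

For a motif instance found in the ungapped sequence of the searched row,
the instance's span is mapped to alignment columns and compared with
each other genome row column by column:

* columns gapped in **both** rows are skipped;
* every other column scores **1** if the two characters are identical
  (`N` never scores) and **0** otherwise;
* the emitted entries are truncated to the motif length *L*, giving the
  binary **similarity vector** `v`;
* the **conservation percentage** is `100 · Σv / L`, and the block-level
  value of an instance is the unweighted mean over compared genomes.

So for motif `ATCG` with searched row `A-TCG`: an identical compared row
gives `[1,1,1,1]` (100%), while `AT-CG` gives `[1,0,0,1]` (50%) — the
ref-gap column scores as a mismatch and the trailing match is truncated
away. An alternative rule that scores only reference-base columns
(`[1,0,1,1]`, 75% in that case) is available via
`conservationMode = "refbase"`.

Engines: k-mers are matched with an Aho-Corasick multi-pattern automaton
(single pass, overlaps reported); regexes are scanned forward and, for
the reverse strand, against the reverse-complemented sequence with
coordinates reflected back; PWMs are scored as log-odds (bits) against a
background nucleotide model with the score threshold calibrated by Monte
Carlo sampling at a target p-value (default `1e-4`), the reverse strand
scanned with the reverse-complement matrix, and per-hit empirical
p-values plus Benjamini–Hochberg q-values reported. Source coordinates
follow the MAF convention (0-based strand-relative start, inclusive
end): a 4-base motif starting at 1000 is reported as 1000–1003.

## Worked example

```r
library(mafconserve)
maf   <- system.file("extdata", "example.maf", package = "mafconserve")
kmers <- system.file("extdata", "example_kmers.txt", package = "mafconserve")
res <- mafMotifScan(maf, kmerFile = kmers, reverseComplement = TRUE)
#> scanned 1 chunk(s): 3 hit(s), mean block conservation 86.11%

scanHits(res)[, c("motifId", "src", "sourceStart", "sourceEnd",
                  "strand", "matchedSeq")]
#>   motifId       src sourceStart sourceEnd strand matchedSeq
#> 1    ATCG hg38.chr1        1000      1003      +       ATCG
#> 2    ATCG hg38.chr1           1         4      +       ATCG
#> 3     CCG hg38.chr1           3         5      -        CGG

conservationTable(res)[, c("motifId", "comparedSrc", "similarityVector",
                           "conservationPct", "blockAvgPct")]
#>   motifId  comparedSrc similarityVector conservationPct blockAvgPct
#> 1    ATCG    mm39.chr4             1001        50.00000    75.00000
#> 2    ATCG panTro6.chr1             1111       100.00000    75.00000
#> 3    ATCG    mm39.chr4             1111       100.00000   100.00000
#> 4    ATCG panTro6.chr1             1111       100.00000   100.00000
#> 5     CCG    mm39.chr4              110        66.66667    83.33333
#> 6     CCG panTro6.chr1              111       100.00000    83.33333
```

Reading the output: `ATCG` in block 0 sits at hg38 positions 1000–1003;
the chimp row is identical (vector `1111`, 100%) while the mouse row's
shifted gap yields `1001` = 50%, so the instance's block average is 75%.
In block 1 the k-mer `CCG` is found on the reverse strand (the forward
text `CGG` at positions 3–5); mouse has lost its middle base to a
deletion, scoring `110` ≈ 66.7%.

`writeHitsJson()` / `writeHitsCsv()` (or the `outputPrefix` argument)
serialize these tables: JSON keyed by
`"<src>:<start>-<end>:<motifId>:<strand>"`, CSV with one row per hit ×
compared genome. The same pipeline is available from a shell:

```sh
Rscript <library>/mafconserve/exec/mafconserve \
    --maf_file aln.maf --kmer_file motifs.txt \
    --reverse_complement yes --processes 4 --output_prefix out
```

Output is byte-identical for any `--processes` value. Synthetic test
alignments with planted motifs and known ground truth can be produced
with `generateMaf()`.

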