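# qualcrunch

Reference-free lossy compression of per-base quality values in
coordinate-sorted SAM/BAM alignment files.

Quality values are the bulk of a compressed alignment file, and most of
them never influence downstream variant calling.  `qualcrunch` rewrites the
quality string of every read so that the quality budget is spent only where
it matters, for anyone (sequencing cores, archives, population-scale
projects) who needs to keep alignments around at a fraction of the cost
without silently breaking later re-calling.

## The method in brief

A fast, deliberately **pessimistic diploid consensus caller** runs on every
pileup column over the five-letter alphabet {A, C, G, T, \*} (\* marks a
deletion).  All 15 unordered genotypes are enumerated in exact log space
under a flat prior; an entry with base *b* contributes via its effective
error rate *e* = 10^(−min(q, MAPQ, cap)/10):

* homozygous {g,g}: P(b) = 1−e if b = g, else e/4
* heterozygous {g1,g2}: P(b) = (1−e)/2 + e/8 if b ∈ {g1,g2}, else e/4

The Phred-scaled posterior of the winner (capped at 99) is then reduced by
Σ min(q, MAPQ) over every entry that contradicts the genotype — a caller
designed to be uncertain whenever *any* caller might be.

Given the calls, each base is rewritten: **agrees** with a confident call →
constant `qual_high` (40); **disagrees** (or is soft-clipped/inserted) →
constant low, 8-level Illumina-style quantization, or kept, per
`disagree_mode`; lies in the **retention mask** → kept verbatim (optionally
P-block smoothed within ±p).  The mask is the union of six heuristics —
concordant soft clips, excessive depth, low MAPQ (with whole-read
retention), more than two supported alleles, low-confidence calls,
proximity to short tandem repeats — each padded with surrounding context.
Sequence, CIGAR, positions, flags and tags are preserved byte for byte, and
a windowed run is byte-identical to a monolithic one.

See `vignettes/quality-crunching.Rmd` for the full model, the preset
design, and what the built-in simulator does and does not establish.

## Worked example

```r
library(qualcrunch)
sim <- simulate_alignments(ref_len = 50000, depth = 30, err_rate = 0.005,
                           seed = 1)
res <- compress_records(sim$records, preset = qc_preset(9, pblock_p = 8))
res
#> qualcrunch result: 15000 records
#> retention mask: 533 interval(s) covering 42709 bp, 0 whole read(s)
#>   reasons: str=509 lowconf=354
compression_summary(sim$records$qual, res$records$qual)
#>   stream n_symbols distinct_symbols entropy_bits gzip_bytes
#> 1  input   1500000               32     3.639519     786044
#> 2 output   1500000               29     2.473454      72602
```

On this 50 kb, 30× simulation the aggressive preset shrinks the gzipped
quality stream 10.8-fold.  The mask report says *why* bases were retained:
`str` intervals surround short tandem repeats (dense in any realistic
sequence — a 3-base homopolymer qualifies), `lowconf` marks loci whose
pessimistic consensus fails the confidence bar (shallow window edges,
heterozygous sites, error pile-ups).  Re-calling the compressed records
reproduces the confident genotype calls everywhere outside the mask.

The same pipeline from the shell:

```sh
exec/qualcrunch simulate --ref-len 20000 --seed 7 demo.sam
exec/qualcrunch -l 9 -p 8 demo.sam demo.out.sam
#> quality stream: 293591 -> 27089 gzip bytes (10.8x), 20 -> 15 distinct symbols
exec/qualcrunch stats demo.out.sam
```

`-l 0` is the lossless escape hatch (output qualities byte-identical),
`--tuned` the hand-tuned aggressive bundle; `--drop-names`/`--drop-aux`
shed read identifiers and auxiliary tags for maximum shrinkage.

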