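---
title: "How qualcrunch decides which quality values matter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How qualcrunch decides which quality values matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualcrunch)
```

## The problem

Per-base quality values dominate the size of compressed alignment files, yet
most of them never influence a variant call: at a locus where every read
agrees and the consensus is overwhelming, a caller reaches the same decision
with or without the qualities.  qualcrunch spends its "quality budget"
selectively.  It rewrites the quality string of every read in a
coordinate-sorted SAM/BAM file so that

* bases that **agree** with a confident diploid consensus call take one
  constant high value (`qual_high`, default 40);
* bases that **disagree** with a confident call — plus soft-clipped and
  inserted bases, which support no consensus column — are set to a constant
  low value, heavily quantized, or left intact (`disagree_mode`);
* bases in regions where *any* caller might be confidently wrong are kept
  **verbatim**, optionally smoothed by a P-block pass.

Every other record field (sequence, CIGAR, positions, flags, tags) is
preserved byte for byte.  No reference genome is used anywhere: the aligner
already consulted one, and injecting it again would add reference bias.

## The pessimistic diploid caller

Each window of reads is stacked into pileup columns over a five-letter
alphabet {A, C, G, T, \*}, where \* is the "fifth base" marking a deletion.
A deleted base has no stored quality, so its \* entry carries the floor of
the mean of the two flanking base qualities of the same read — a deletion's
evidence cannot be stronger than its neighbours.  `N` bases count toward
depth but carry no information.

For every column the caller enumerates all 15 unordered diploid genotypes
over the five letters, in exact log space under a flat prior.  An entry with
base $b$ contributes through its *effective* error rate
$e = 10^{-\min(q,\,m,\,c)/10}$, where $q$ is the base quality, $m$ the
mapping quality (255 "unavailable" is replaced by `mapq_floor`, default 30)
and $c$ = `max_phred_cap` (default 40) a ceiling that stops a single read
from dominating:

* homozygous $\{g,g\}$: $P(b) = 1-e$ if $b = g$, else $e/4$;
* heterozygous $\{g_1,g_2\}$: $P(b) = (1-e)/2 + e/8$ if
  $b \in \{g_1,g_2\}$, else $e/4$.

Both rows sum to 1 over the alphabet; the heterozygote emission is the
standard samtools-style diploid model extended to five letters.  The raw
confidence is the Phred-scaled posterior of the winning genotype, capped at
99.  Ties are broken deterministically: homozygotes first, then alleles in
A<C<G<T<\* order.  (The C++ accumulates the two allele terms before the
shared mismatch mass so that structurally symmetric genotypes tie
*bit-exactly* and the rule actually fires.)

The caller is then made deliberately pessimistic:

$$\mathrm{conf} = \max\bigl(0,\ \mathrm{raw} - \textstyle\sum_{b \notin G}
\min(q_b, m_b)\bigr),$$

i.e. every entry that contradicts the chosen genotype subtracts its full
evidence.  The goal is not a good caller but a cautious gatekeeper: a column
is only "confident" (and hence rewritable) when `conf >= conf_threshold`,
boundary inclusive.  Note that confidence grows only ~3 Phred per clean
base (the nearest competitor is always a heterozygote containing the called
allele), so ten agreeing Q30 bases sit near 24 Phred — shallow regions are
*not* confident at the default threshold of 30, by design.

## The retention heuristics

Six detectors flag loci (half-open intervals, merged with reason tags) or
whole reads whose qualities are kept verbatim:

| tag        | trigger | default thresholds |
|------------|---------|--------------------|
| `softclip` | ≥ `clip_min_count` reads and ≥ `clip_min_fraction` of spanning reads soft-clip at one site (large novel insertion / contamination) | 3 reads, 30% |
| `depth`    | column depth > `depth_max` (collapsed repeat, contamination) | 100 |
| `mapq`     | read MAPQ < `mapq_low` (whole-read retention); locus where ≥ `low_mapq_fraction` of entries are low-MAPQ; optionally whole high-MAPQ reads colocated there | 10, 25%, on |
| `alleles`  | more than `max_alleles` alleles each supported by ≥ 2 reads *and* ≥ 10% of depth | 2 |
| `lowconf`  | pessimistic confidence below `conf_threshold` | 30 |
| `str`      | tandem tract, unit ≤ `str_unit_max`, ≥ `str_min_copies` exact copies, on the *consensus* string | 4, 3 |

Each flagged run is padded by `pad` bases (default 10) of sequence context
on both sides — alignment wobble around a bad site extends beyond the site
itself.  A single flagged locus therefore becomes a `2*pad + 1`-wide
interval.  Soft-clip sites are point events and use `[site - pad,
site + pad)`.  STR tracts are additionally extended to cover any
overlapping read's indel span before padding, because indels inside repeats
are exactly where pileup columns go wrong.  The allele detector's support
floor (2 reads, 10% of depth) exists because raw "more than two alleles"
would fire on scattered sequencing errors at any depth; the floor targets
systematic mispileup.

The STR scan runs on the computed consensus (first allele per locus,
deletions breaking tracts) rather than a reference, keeping the tool
reference-free.  Note that *any* realistic sequence contains qualifying
tracts — a 3-base homopolymer is one — so STR retention is dense; that is
intentional and matches the behaviour of the tool this package re-derives.

## Rewriting, quantization, P-block

Reads retained whole come back verbatim.  Otherwise, per base: inside a
mask interval → keep; aligned and agreeing with a confident call →
`qual_high`; everything else (disagreeing, unconfident-and-unmasked,
soft-clipped, inserted) → `disagree_mode`.  Soft-clip bases are projected
through the alignment (left clips count backwards from `pos`) when testing
mask membership.  The default quantizer is the familiar 8-level
Illumina-style binning {0–1, 2–9, 10–19, 20–24, 25–29, 30–34, 35–39, 40+}
→ {0, 6, 15, 22, 27, 33, 37, 40}.

Kept stretches may be P-block smoothed: a greedy left-to-right pass extends
the current block while max−min of the block's original values stays ≤ 2p,
then replaces the block with ⌊(max+min)/2⌋, guaranteeing every output value
within p of its input.  `p = 0` is the identity.  P-block matters most for
legacy data with 40+ distinct quality levels.

Two degenerate modes are worth naming.  `qc_preset(0)` sets
`conf_threshold = Inf` and `disagree_mode = "keep"`: nothing is ever
confident, so every quality survives byte-identically — the lossless escape
hatch.  And with `conf_threshold = Inf` the low-confidence detector alone
covers every covered locus, which is why that detector is part of the
method's contract rather than an optional extra.

## Presets

The preset table is this package's own design (the upstream tool never
published its per-level bundles): levels 1–9 interpolate
`conf_threshold` 75→35, `mapq_low` 25→5, `depth_max` 400→100, with
`disagree_mode` keep (1–3) / low (4–6) / quantize (7–9).  Level 1 retains
generously and keeps disagreeing values; level 9 quantizes them.
`qc_preset(tuned = TRUE)` is level 9 + P-block 8 with
`conf_threshold = 60`, `mapq_low = 30`, `depth_max = 100` — one fixed
interpretation of the upstream tuned profile, whose exact flag semantics
were never specified.

## The simulator and what a green test establishes

`simulate_alignments()` emulates: a random reference window; a diploid pair
of haplotypes with SNPs and 1–4 bp indels at `var_density` (90/5/5), het
variants on haplotype 2 only; uniformly placed fixed-length reads; base
qualities `clamp(round(Normal(37, 3)), 2, 41)` with errors injected per
base at exactly `10^(-q/10)`; and planted anomalies (novel-insertion soft
clips split mid-read, a depth-doubled tract, a MAPQ-0 tract, an (AC)-type
STR).  When a target `err_rate` is requested the Normal mean is
re-calibrated by root finding so the *expected* error of the discretised
distribution equals the target — naively setting mean = −10·log10(err)
biases the realised rate upward because E[10^(−Q/10)] > 10^(−E[Q]/10).

The simulator does **not** emulate: GC bias, indel-rich long repeats,
mate-pair structure, chimeric reads, reference mismatch, or any real
base-caller's error correlations.  A green suite therefore establishes that
the machinery implements its stated rules exactly and preserves calls on
idealised data; it says nothing about variant-calling accuracy on a real
genome, which the upstream work measured against external truth sets that
are out of scope here.

Fixture edge effects are real effects: read starts are uniform over
`[0, ref_len − read_len]`, so coverage ramps down at the window edges and
the low-confidence detector rightly retains them.  "Clean control" checks
are therefore asserted on the uniformly covered interior.

## Numerical and design notes

* Exact log-space likelihoods, no streaming approximations; columns are
  small and correctness wins.  Q0 entries (`e = 1`) produce −Inf terms that
  IEEE arithmetic handles correctly (a homozygote contradicted by certainty
  is impossible, not merely unlikely).
* Windowing: each read is *owned* by the window containing its start and
  rewritten exactly once; detectors see `overlap` (default 1000 bp) of
  context each side.  Windowed and monolithic runs are byte-identical as
  long as no retention signal spans more than the overlap, which holds for
  short-read data by a wide margin.  Window geometry is deliberately left
  out of the recorded `@PG` command line so it can never change the output
  bytes.
* Mate-pair retention is not propagated (retaining a read does not retain
  its mate); the upstream description leaves this open and the simpler rule
  is easier to reason about.
* Order-0 entropy of the output stream is *not* guaranteed below the
  input's at intermediate presets: the output is a mixture of kept,
  constant and quantized components, and entropy is concave in the mixture
  weights.  At the aggressive preset the reduction is large and the
  package asserts it there.
* `'*'`-involving confident calls are retention-neutral: a deletion "base"
  has no stored quality to rewrite, and reads with a real base at such a
  locus are treated by the ordinary agree/disagree rules.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_alignments(ref_len = 50000, depth = 30, err_rate = 0.005,
                           seed = 1)
res <- compress_records(sim$records, preset = qc_preset(9, pblock_p = 8))
res$mask
compression_summary(sim$records$qual, res$records$qual)
```

On this 50 kb, 30× simulation the gzip size of the concatenated quality
stream drops about tenfold (the README shows the exact numbers printed by
the released code), while re-calling the compressed records reproduces the
confident genotype calls away from the retention mask.
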