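---
title: "Impact scoring for structural variants: model, parameters and design"
author: "SVImpact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impact scoring for structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SVImpact)
```

## The problem and the model

Predicting the functional impact of structural variants (SVs) is harder
than for SNPs: SVs span kilobases, their consequences depend on variant
type (a deletion across a gene is not an inversion with the same
coordinates), and short-read callers report breakpoints with positional
uncertainty. SVImpact turns an existing per-base SNP pathogenicity track
(CADD-style phred-scaled scores) into per-variant impact scores by
aggregating the per-base scores over intervals chosen by variant type:

* **LEFT / RIGHT** — the confidence interval (CI) around each breakpoint,
  for every variant type. When the caller provides a per-base breakpoint
  probability distribution (`PRPOS`/`PREND`, as emitted by LUMPY), those
  probabilities weight the bases of the CI: bases in the tails of the
  distribution are less likely to be the true breakpoint and should count
  less.
* **SPAN** — the interval between the most likely breakpoints, for
  copy-number-changing types only (DEL, DUP, CNV). The affected bases of
  a balanced inversion are only its junctions, so INV has no SPAN.
* **LTRUNC / RTRUNC** — for DEL, INV, MEI and INS variants whose
  breakpoint falls strictly inside a transcript, the portion of the
  transcript downstream of the break in transcription order
  (`[pos, txEnd]` on `+`, `[txStart, pos]` on `-`), one interval per
  (breakend, transcript) pair. A truncating event disrupts everything
  downstream of the break, so scoring that remainder measures what is
  lost. MEI denotes mobile-element insertions present in the reference;
  INS denotes insertions in the sequenced sample.

Each interval is summarised by one or more operations — maximum, sum,
weighted mean, and weighted mean of the top *N* bases (default *N* = 10
and 100) — and the **maximum over a variant's interval scores** is
reported as the variant score for that operation, written into the VCF
INFO column as `SVSCOREMAX`, `SVSCORESUM`, `SVSCOREMEAN`,
`SVSCORETOP10`, `SVSCORETOP100`.

## Numerical and coordinate conventions

* All internal intervals are 1-based inclusive; `[a,b]` and `[c,d]`
  overlap iff `a <= d` and `c <= b`. refGene/BED12 half-open inputs are
  converted once, at load time.
* `CIPOS`/`CIEND` are signed inclusive offsets (VCF 4.2); an absent CI
  defaults to `(0,0)`, a point breakpoint.
* Positions absent from the score track are *skipped*, not imputed as
  zero — phred-like scores have no natural zero.
* Positions with several track rows (one per alternate allele) reduce to
  the **maximum** across alleles: a conservative upper bound on per-base
  deleteriousness.
* Weighted top-*N*: bases are selected by raw score (ties broken by
  ascending genomic position, for determinism), then averaged with their
  weights renormalised over the subset. Selection precedes weighting
  because the operation is a mean *of the top N bases*.
* SPAN and truncation intervals are never probability-weighted: their
  defining endpoints are the point estimates, and breakpoint
  probabilities only have meaning inside a CI.
* Sums and means accumulate in double precision via R's long-double
  `sum()`; INFO values are serialised with one decimal (configurable).
* A variant with no scorable base in any interval is flagged and written
  with the `-1` sentinel plus an `SVSCORE_MISSING` flag — clearly out of
  range for phred-like non-negative scores.

## Design choices where the design was open

* **Truncation trigger.** A transcript is truncated when the *most
  likely* breakpoint position lies strictly inside its span
  (`txStart < pos < txEnd`), not when the CI merely brushes it: a wide
  CI can dwarf a small transcript and would otherwise flood the
  truncation set. An optional mode
  (`exonRestrictedTruncation = TRUE`) clips truncation intervals to the
  transcript's exonic bases; the default scores the full downstream
  span, since intronic disruption of a truncated transcript is part of
  what is lost.
* **Point-event insertions.** For INS/MEI without an END, both breakends
  sit at the insertion site and contribute a single truncation interval
  per transcript (not a duplicated LTRUNC/RTRUNC pair).
* **BND handling.** Reciprocal mates (linked by `MATEID`) merge into one
  variant — left breakend is the positionally first — and both VCF lines
  receive identical scores. Unmated breakends are scored on their single
  CI. BND variants get LEFT/RIGHT only: no SPAN is defined for an
  unclassified junction, and length-based reasoning does not apply.
* **Multi-allelic SV records are rejected** with advice to pre-split:
  interval semantics per ALT are ambiguous.
* **Percentile definition.** "At or above the 90th percentile" needs an
  estimator; we use the nearest-rank empirical quantile (the value at
  rank `ceil(p*n)`), which is reproducible and keeps boundary ties
  pathogenic. On the scores 1..100 this yields exactly 11 pathogenic and
  49 benign variants. Fewer than 10 usable values is an error —
  percentiles of tiny samples are unstable.
* **Odds ratio.** The evaluation uses the sample odds ratio
  `(a*d)/(b*c)` on the rare/common x pathogenic/benign table
  (intermediates excluded), the two-sided Fisher exact p-value, and a
  95% CI from the log-OR normal approximation; zero cells get a 0.5
  continuity correction and are flagged.

## What the synthetic generator emulates — and what it does not

Real SV callsets with population allele frequencies are large and not
redistributable, so the package ships a deterministic generator that
produces the three inputs at desk scale: two contigs (chrT1 = 50 kb,
chrT2 = 30 kb), a complete per-base CADD-dialect track (gamma(2, 3)
background, phred-like mean 6), a refGene-style annotation
(non-overlapping transcripts, 2–10 exons, both strands), and a VCF 4.2
callset with CIs, breakpoint probability vectors and AF.

The generator plants *spike regions* (~14% of the genome) whose scores
are elevated by +20, and couples allele frequency to them: with
probability `enrichment` (default 0.9) a spike-overlapping variant is
forced to rare AF (< 0.01); otherwise — and for every other variant — the
AF class is drawn from a background mixture (25% rare, 15% intermediate,
60% common). With `enrichment = 0` the assignment ignores spike overlap
entirely, making it an exact null for the AF–score association. This
gives the evaluation module a known ground truth: under purifying
selection high-impact variants are depleted of common alleles, and the
pipeline should recover an odds ratio above 1 exactly when the coupling
is present.

What the fixtures do **not** emulate: real CADD score distributions and
their correlation structure, realistic human AF spectra, overlapping
transcript models, sequence context, or caller-specific CI shapes beyond
uniform/triangular. Passing the test suite therefore demonstrates the
correctness of the interval rules, the aggregation arithmetic, the VCF
round-trip and the statistical machinery — not calibration on real
genomes. In particular, the length- and exon-overlap-based alternative
classifiers carry no signal in the synthetic design (AF is coupled to
spike overlap, not to variant length or exon content), so their odds
ratios hover around 1 on fixtures; on real data they are meaningful
baselines.

## Problem sizes used by the checks

The test suite runs the aggregation oracle on 500 random intervals, the
interval-rule conformance check on 1,000 generated variants, the Fisher
oracle on every 2x2 table with total at most 40, and the end-to-end
signal-recovery experiment on 20 replicates of 1,000 variants (plus 200
null replicates against a fixed score landscape, regenerating the
callset each time). These sizes keep a full run at desk scale while
leaving each property with enough randomisation to be informative.

## Limitations

Like any approach built on per-base SNP scores, the method underweights
mechanisms that are not per-base losses: gain-of-function fusions, novel
regulatory adjacencies, and dosage effects of whole-gene duplications
are addressed only indirectly. Genotype (FORMAT) fields are passed
through untouched; there is no liftover, no CDS/UTR modelling, and no
canonical-transcript selection.

## A minimal session

```{r example, eval = FALSE}
fx <- generateFixtures(fixtureSpec(seed = 1), tempdir())
track <- scoreTrack(fx$track)
genes <- loadGeneAnnotation(fx$annotation)
res <- scoreCallset(fx$vcf, track, genes, "annotated.vcf")
ev <- evaluateScoredVcf("annotated.vcf", scoreKey = "SVSCORETOP10")
ev$or$or   # rare-vs-common odds ratio
```
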