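# SVImpact

Impact scoring for structural variants (SVs) from per-base SNP
pathogenicity tracks.

Calling 5,000–10,000 SVs per deeply sequenced human genome is routine;
deciding which of them matter is not. SVImpact produces a quantitative
pathogenicity score per SV by aggregating an existing per-base SNP score
track (e.g. CADD phred scores, tabix-indexed) over intervals chosen by
variant type, and writes the scores back into the VCF INFO column. It is
aimed at WGS studies — rare-variant association and rare-disease work —
that need to prioritise deletions, duplications, inversions, insertions
and unclassified breakends on one scale.

## Method

For an SV with breakends at positions $p_L, p_R$ and confidence
intervals $CI_L, CI_R$:

* **LEFT**, **RIGHT** = the breakpoint CIs (every type). With caller
  probabilities $w_i$ over the CI (`PRPOS`/`PREND`), weighted operations
  use $\sum_i w_i s_i / \sum_i w_i$.
* **SPAN** = $[p_L, p_R]$ for copy-number-changing types (DEL/DUP/CNV).
* **LTRUNC/RTRUNC** = for DEL/INV/MEI/INS with a breakend strictly
  inside a transcript, the downstream remainder of that transcript in
  transcription order, per transcript.

Each interval's per-base scores $s_1..s_m$ are summarised with
`max`, `sum`, weighted `mean`, and weighted mean of the top-$N$ bases
($N = 10, 100$); the **maximum over intervals** is the variant's score
per operation (INFO keys `SVSCOREMAX`, `SVSCORESUM`, `SVSCOREMEAN`,
`SVSCORETOP10`, `SVSCORETOP100`).

Evaluation uses population allele frequency as a proxy for
pathogenicity: under purifying selection, truly deleterious variants are
rare. Variants at or above the 90th score percentile are "pathogenic",
below the 50th "benign"; AF < 0.01 is "rare", AF ≥ 0.05 "common"; the
association is measured by the odds ratio
$OR = (a d)/(b c)$ on the 2×2 rare/common × pathogenic/benign table with
Fisher's exact test. Alternative classifiers (SV length percentile;
exon overlap of LEFT/RIGHT/SPAN) are provided for comparison.

## Worked example

Everything runs offline on the package's deterministic synthetic
fixtures (two toy contigs, a complete per-base score track, a
refGene-style annotation, and a VCF with CIs, breakpoint probabilities
and AF):

```r
library(SVImpact)
fx    <- generateFixtures(fixtureSpec(seed = 1, nVariants = 1000), tempdir())
track <- scoreTrack(fx$track)                 # tabix-indexed CADD dialect
genes <- loadGeneAnnotation(fx$annotation)    # refGene flat table
out   <- file.path(tempdir(), "annotated.vcf")

res <- scoreCallset(fx$vcf, track, genes, out)
res$summary
#> $n_records   [1] 1115
#> $n_variants  [1] 1000
#> $n_scored    [1] 1000
#> $n_missing   [1] 0
#> $n_skipped   [1] 0

ev <- evaluateScoredVcf(out, scoreKey = "SVSCORETOP10")
ev$contingency
#> rarePathogenic commonPathogenic    rareBenign   commonBenign
#>             78               24           123           293
round(ev$or$or, 2); signif(ev$or$p, 3)
#> [1] 7.74
#> [1] 9.86e-18
```

An annotated record looks like (probability vectors elided):

```
chrT1  30722  SV00001  N  <DEL>  .  PASS  SVTYPE=DEL;END=30785;SVLEN=63;CIPOS=-8,9;CIEND=-5,8;PRPOS=...;PREND=...;AF=0.0837;SVSCOREMAX=30.2;SVSCORESUM=9296.3;SVSCOREMEAN=6.9;SVSCORETOP10=24.7;SVSCORETOP100=17.3
```

The contingency table says: of the variants in the top score decile, 78
are rare and 24 common, against 123/293 among benign variants — an odds
ratio of 7.7 (Fisher p ≈ 1e-17), i.e. high-scoring variants are strongly
skewed toward low allele frequency, which is the designed-in signal of
the fixture generator (score-spiked regions force rare AF with
probability 0.9). With that coupling disabled the same pipeline returns
log-odds centred on zero.

A command-line wrapper covers the same surface:

```sh
Rscript inst/scripts/svimpact.R fixtures make --seed 1 --out fx/
Rscript inst/scripts/svimpact.R score --vcf fx/variants.vcf \
    --score-track fx/scores.tsv.bgz --annotation fx/genes.refgene.txt \
    --ops max,sum,mean,top10,top100 --output annotated.vcf
Rscript inst/scripts/svimpact.R evaluate --vcf annotated.vcf --out-prefix eval
```

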