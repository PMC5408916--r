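Package: SVImpact
Title: Impact Scoring for Structural Variants from Per-Base SNP
    Pathogenicity Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Aggregates per-base SNP pathogenicity scores (CADD-style,
    tabix-indexed) over variant-type-aware genomic intervals to produce
    impact scores for structural variants: breakpoint confidence intervals
    with optional per-base probability weighting, SPAN intervals for
    copy-number-changing variants, and transcript-truncation intervals.
    Annotates SV VCFs with the resulting scores in the INFO column, and
    provides allele-frequency-based evaluation statistics (percentile
    pathogenicity classes, rare/common odds ratios with Fisher's exact
    test, and alternative length- and exon-overlap-based classifiers).
    Includes a deterministic synthetic fixture generator (score tracks,
    gene annotations, SV callsets) so the full pipeline runs offline at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralVariation, VariantAnnotation, Software
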