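---
title: "BSA-seq QTL mapping with bsascan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BSA-seq QTL mapping with bsascan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The experimental design the package models

`bsascan` analyses a four-pool bulked segregant design: two inbred parents
fixed for alternate alleles, and two bulks of phenotypically extreme F2
individuals pooled before sequencing. The motivating trait is a trimodal
leaf-colour phenotype under a single incompletely dominant locus, so the F2
segregates Green : Purple-green : Purple at 1:2:1 and the bulks are drawn
from the two homozygous classes. The package consumes finished variant
calls (VCF with per-sample allele depths); upstream read QC, alignment and
variant calling are out of scope.

## Per-site statistics

For a pool with `ref` and `alt` read counts, the SNP-index is
`alt / (ref + alt)`. The association statistics between the green (LS) and
purple (ZS) bulks are

- ΔSNP-index = SNP-index(green) − SNP-index(purple), in that fixed order.
  The sign depends on which parent carries the ALT allele at a locus, so
  all thresholding uses |Δ| while reports keep the sign.
- ED = sqrt(Δf_alt² + Δf_ref²), the Euclidean distance between the bulks'
  allele-frequency vectors over both alleles; for biallelic sites
  ED = √2·|Δf_alt|, and ED⁴ = 4·(ΔSNP-index)⁴ with maximum 4.

The two-allele form of ED is used deliberately: it is the only form whose
fourth power spans the observed 0–4 range at biallelic sites (a
single-difference fourth power is bounded by 1), and the identity
ED⁴ = 4Δ⁴ is enforced by a property test at 1e-12 relative tolerance.

Sites with zero depth in either bulk are *undefined*, propagate `NA`, and
are excluded from scans. No pseudocounts are added: imputation would
distort the fixation identities (Δ = ±1, ED⁴ = 4) that carry the mapping
signal, and the depth filters upstream make zero-depth sites rare.

## Site filtering

Hard GATK-style site filters retain a variant iff DP ∈ [60, 1000],
QUAL ≥ 50, MQ ≥ 50, QD ≥ 2, FS ≤ 40, AN ≥ 5 and SOR ≤ 5 (all inclusive).
DP is interpreted as the *combined* site depth over the four pools — the
60–1000 bracket is consistent with 4 × ~45× per-pool coverage — rather than
per-sample depth. A missing metric fails its rule: a site without recorded
evidence of quality is not treated as reliable. Each removed record is
attributed to the first violated rule in the order above, giving an
additive filter ledger. Multiallelic sites are dropped, not decomposed,
because the ED⁴/Δ identities assume biallelic sites.

Parent-informative SNPs are those where each parent is effectively
homozygous (minor-allele read fraction ≤ 0.05) for opposite alleles, with
parental depth ≥ 10. No published rule exists for "parentally segregated";
both knobs are exposed (`tolerance`, `min_parent_depth`) and the defaults
reflect typical pooled-parent depths, where one or two stray reads should
not disqualify a fixed site.

## Genome scan

Windows of 1 Mb step by 500 kb, anchored at position 1 of each chromosome;
terminal windows are truncated, not dropped. Windows holding fewer than
`min_snps_per_window = 10` defined SNPs carry undefined means and never
contribute to thresholds or intervals. Window means are arithmetic means
over contained SNPs.

Smoothing is per-chromosome LOESS (degree 1, tricube weights,
`surface = "direct"` so fits are exact and deterministic), with default
span 0.1 of the chromosome's SNPs. The span is floored so each local fit
sees at least 10 points; with fewer than 10 defined SNPs a chromosome is
skipped with a warning. Degree 1 reproduces linear trends exactly, which
the tests verify to 1e-8.

Two significance rules:

- **ED⁴**: the genome-wide top 1% of *raw per-SNP* ED⁴ values (empirical
  quantile, linear interpolation between order statistics) thresholds the
  LOESS-fitted ED⁴ track. This rule presumes the QTL footprint is a small
  fraction of the genome; on a single-chromosome dataset the threshold
  lands inside the QTL cluster itself and `top_fraction` should be raised.
- **ΔSNP-index**: a Monte-Carlo null. Under the null each bulk's true
  allele frequency is the mean of `bulk_size` F2 dosages (0, ½, 1 with
  probabilities ¼, ½, ¼ — equivalently Binomial(2·bulk_size, ½)/2·bulk_size
  alleles), and read counts are Binomial(depth, f). Upper quantiles of |Δ|
  at 95% and 99% are tabulated on a depth grid (5× resolution) and matched
  to each window's mean bulk depth. No analytic form is assumed; the
  bulk-size-1, infinite-depth case is checked against the exact enumeration
  {0: 0.375, 0.5: 0.5, 1: 0.125}.

A window is flagged per method when the fitted value at its midpoint
exceeds the method's bound; the null CI is applied to the *fitted* Δ track
(the raw window means are also emitted). Because smoothing shrinks noise,
comparing the fitted track against a per-SNP null quantile is conservative,
which suits a consensus caller whose false positives multiply across
methods.

## Interval calling

Runs of flagged windows are merged per method, bridging unflagged gaps up
to `max_gap` = one step (500 kb) so a single sparse window does not split a
QTL. Merged runs are then snapped to the first and last raw SNP above the
method's per-SNP threshold inside the run — this is how SNP-coordinate QTL
boundaries arise — and both the snapped and window-edge bounds are kept.
The ΔSNP-index and ED⁴ interval sets are intersected pairwise per
chromosome into the consensus QTL. Interval width is reported as
`(end − start)/1e6` Mb: the convention for a physical interval quoted by
its flanking SNP coordinates.

## Annotation

Gene models come from GFF3 + FASTA; one canonical transcript per gene (the
longest total CDS) is used, and genes failing validation (CDS not a
multiple of 3, CDS outside exons, exons outside the gene span, or no CDS)
are skipped with a log. Each candidate SNP receives exactly one category:
coding (synonymous / non-synonymous via strand-aware codon substitution and
the standard nuclear code), UTR (5′/3′ by strand), intron, upstream /
downstream within a 5 kb flank (no published distance; exposed as `flank`),
or intergenic. A SNP hitting several genes keeps the most severe category,
nearest gene breaking ties. The candidate table is restricted to the
consensus interval and sorted by descending |Δ| then descending ED⁴;
the absolute value makes the ordering independent of which parent
contributed the ALT allele.

## The synthetic generator

`simulate_bsa_experiment()` emulates the target experiment at a tractable
scale: 12 chromosomes of 5 Mb / 50 cM, 40 SNPs/Mb, n = 646 F2 individuals,
bulks of 30 + 30 from the two homozygous classes, mean pooled depth 45×,
base error 1%, a single incompletely dominant causal locus. Population
size, bulk sizes and depth mirror the motivating experiment; chromosome
count matches a typical solanaceous karyotype, and the 5 Mb / 50 cM scaling
keeps 100 simulated experiments within a few minutes while preserving
realistic marker-to-marker linkage (0.25 cM spacing).

Meiosis is Haldane (no interference). Rather than drawing Poisson crossover
counts and uniform breakpoints explicitly, transmitted parental origin is
simulated as a Markov chain along the ordered markers with switch
probability c = (1 − exp(−2d))/2 per adjacent interval of d Morgans; for a
no-interference Poisson crossover process the two formulations are
identical in distribution at the marker loci, and the Markov form
vectorises over gametes. The Haldane map function is verified empirically
from dosage correlations (corr = 1 − 2c for F2 dosages).

Phenotype misclassification is modelled as adjacent-class flips with
default rate 0 (clean trimodal classes); sequencing error is folded into
the allele frequency as f(1−e) + (1−f)e rather than per-read simulation,
which is adequate for count-level statistics. All randomness flows from
one master seed through fixed per-stage offsets (population +101,
phenotypes +202, bulks +303, reads +404), so any stage reproduces in
isolation. Simulated INFO fields are emitted at clean pass-filter values so
the quality filters are exercisable but not stressed.

What the generator does *not* emulate: alignment artefacts and mapping-bias
in allele depths, depth heterogeneity beyond Poisson, linked selection or
segregation distortion, crossover interference, structural variants, and
multi-locus or incompletely penetrant traits. Passing the recovery tests
therefore demonstrates correctness of the statistics and calling logic
under the stated model, not robustness to real-data artefacts.

## Verified properties and problem sizes

The test suite (all generated in code, fixed seeds) verifies among others:

- worked values: χ² = 3.40 (p = 0.18) for counts (177, 325, 144) vs 1:2:1;
  ED⁴ = 3.69 at Δf = 0.98; width 17.49 Mb for bounds
  59,315,357–76,806,837; Δ = 1 exactly at opposite fixation;
- the ED⁴ = 4Δ⁴ identity on 10,000 random count configurations (1e-12
  relative tolerance) and antisymmetry under pool swap;
- the null-CI enumeration at bulk size 1 (100,000 replicates);
- causal-locus recovery: over 50 seeded synthetic experiments at the
  default scale the consensus interval contains the true locus in ≥ 90%
  of runs and the peak chromosome is correct in ≥ 95%; over 50 no-QTL
  experiments a consensus interval appears in ≤ 10%;
- byte-identical pipeline outputs for identical config + seed.

## Known limitations

- The ED⁴ top-percentile threshold is relative; it cannot certify the
  *absence* of a QTL (some top 1% always exists) — absence is judged by
  the consensus requirement with the simulated Δ null.
- The Δ null assumes an F2 design; backcross or RIL designs would need
  their own genotype-dosage null (the `population_type` argument errors on
  anything but `"F2"`).
- Depth matching of the null uses each window's mean bulk depth; strong
  within-window depth heterogeneity is not modelled.
- Coordinates are 1-based inclusive throughout; only BED exports are
  0-based half-open.
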