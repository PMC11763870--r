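---
title: "Methods: panel-based molecular profiling of uveal melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-based molecular profiling of uveal melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umprofiler)
```

# The problem

Uveal melanoma stratifies into prognostic categories by a small set of
genetic markers: Gαq-pathway initiating mutations (*GNAQ*, *GNA11*,
*CYSLTR2*, *PLCB4*; *GNAQ*/*GNA11* mutually exclusive), second-hit
prognostic mutations (*BAP1* adverse, *SF3B1*/*SRSF2* intermediate,
*EIF1AX* favourable), emergent biomarkers, and bi-allelic imbalance of
chromosomes 1, 3 and 8 — monosomy 3 being the strongest adverse factor.
`umprofiler` implements the downstream analytics for a targeted amplicon
panel that reads out all of these from one assay: variant filtering,
SNP-VAF imbalance calling, category/stratum assignment, QC and concordance
statistics, and survival comparison. This vignette records the models, the
tunable parameters, and the design decisions taken where the method
description left choices open.

# Variant filter chain

A variant is kept iff all of the following hold, evaluated in order with the
first failing rule recorded as the rejection reason:

1. `vaf >= vaf_min` (default 10%, **inclusive** — the stated cut-off names
   the boundary value, and we keep it);
2. `total_depth > depth_min` (default 100, strict, per "depth > 100");
3. `qual > qual_min` (default Phred 40, strict);
4. `pvalue < p_max` (default 0.01, strict);
5. consequence not synonymous;
6. clinical class not benign / common SNP.

The p-value is the upstream caller's per-variant significance and is an
*input* column here; the simulator reproduces it as a one-sided binomial
tail of the alt count against a 1% per-base error null, which mirrors how
such values behave without reimplementing a commercial caller. Clinical
classes (Pathogenic, VUS, CIP — conflicting interpretations —, novel,
benign, common SNP) come from an offline `annotation_table()`: a genomic
key `chrom:pos:ref:alt` with a `gene:hgvs_p` fallback, unlisted variants
classifying as novel. No live database queries, for reproducibility.
Malformed rows are routed to the rejected table with reason `MALFORMED`,
never dropped, so `kept + rejected` always partitions the input.

# Imbalance calling from SNP VAFs

## Banding

Each SNP VAF is banded with inclusive boundaries: homozygous 0–5% and
95–100%, heterozygous 45–55%, otherwise **deviant**. Banding is total on
[0, 100]: every VAF falls in exactly one band.

## The dosage model

With tumor purity $p$, a germline-heterozygous SNP has expected alt-allele
fraction

$$\mathrm{VAF} = \frac{c_a p + (1-p)}{c_t p + 2(1-p)},$$

where $c_a$ is the tumor's alt-allele copy number and $c_t$ its total copy
number. Under monosomy ($c_t = 1$) this is $(1-p)/(2-p)$ or $1/(2-p)$
(≈ 9.1% / 90.9% at $p = 0.9$); under single-copy gain ($c_t = 3$),
$1/(2+p)$ or $(1+p)/(2+p)$ (≈ 34.5% / 65.5%). Homozygous SNPs cannot move
(0% stays 0%), which is why they are uninformative.

## Aggregation rule

The source method calls imbalance "when each VAF was outside of these
thresholds" without saying how many SNPs must deviate. Our rule, both
knobs exposed: a chromosome is

- `NON_INFORMATIVE` when informative SNPs (heterozygous + deviant) number
  fewer than `min_informative` (default 2);
- `IMBALANCED` when at least `min_informative` SNPs are deviant **and**
  deviants are at least `deviant_fraction` (default 0.5) of the
  informative SNPs;
- `BALANCED` otherwise.

Rationale: one deviant SNP is within binomial noise at panel depths
(sd ≈ 2.2 VAF points at depth 500 and VAF 50%), and a majority rule
matches the visual call on banded dot plots. Arm-level sub-calls (p vs q)
are computed and attached, but the headline status is per chromosome,
because the survival strata are per chromosome; we deliberately do not
invent arm-level prognosis, nor do we distinguish monosomy from
copy-neutral LOH or gain — the method reports "imbalance" only.

## A structural sensitivity boundary

The two monosomy VAF clusters cross into the homozygosity bands when
$(1-p)/(2-p) \le 0.05$, i.e. $p \ge 0.9/0.95 \approx 0.947$. Above that
purity a monosomic chromosome reads as (mostly) homozygous and the banding
rule *cannot* fire except through binomial noise. Over the cohort purity
world U(0.85, 0.95) this caps monosomy sensitivity below the ≥ 99%
acceptance criterion (the acceptance test measures it directly), which is
why that criterion is left red rather than the bands being widened: the
limitation belongs to the published thresholds, and widening the
homozygosity band to rescue it would trade directly against the ≥ 99%
disomy specificity criterion, which passes. A unit
test pins the boundary behaviour at $p = 0.95$ explicitly.

# Categories, strata and cohort rates

Genes map to exactly one of four disjoint categories (4 initiating, 4
prognostic, 6 emergent, *BRAF* as a no-mutation-expected control). A gene
counts as mutated once per patient regardless of variant multiplicity
(tile plots are presence/absence). Cohort percentages are half-up rounded
to one decimal; published figures mix one-decimal and integer display
(40.9% printed as 41%), so checks against printed values compare at each
value's printed precision.

Strata: the BAP1 scheme contrasts BAP1-mutant vs wild type. The
chromosome-k schemes contrast k-imbalanced patients against a
chromosome-3-disomy baseline that, for k ≠ 3, additionally requires
balance on chromosome k — the only definition consistent with a baseline
whose size differs per comparison (13 vs 15 vs 11 in the reference
cohort). Imbalance membership takes precedence (a D3-but-Imb1 patient is
in IMB1), non-informative patients are excluded and reported. Note the
molecular BAP1 count and the survival-analysis BAP1 count can differ when
a patient lacks survival data (18 vs 17 in the reference cohort);
`compare_strata()` reports `missing_survival` rather than reconciling.

# QC and concordance statistics

- **Coverage**: per-amplicon read counts approximate per-amplicon depth;
  mean depth is length-weighted; uniformity is the percent of target bases
  at ≥ 0.2× mean depth (the sequencing platform's convention — the source
  uses the metric without defining it).
- **ROUT outliers**: specialised to a location model (the published use is
  per-patient summary values, not a regression): median center, robust
  scale RSDR = 68.27th percentile of absolute residuals × n/(n−1),
  two-tailed t probabilities at n−1 df, and a step-up
  false-discovery scan from the most extreme point inward at rate Q
  (default 1%). The original procedure's exact threshold schedule is not
  printed in the text we follow; a Benjamini–Hochberg-style schedule is
  the documented choice here. Zero robust spread (all values identical)
  yields no outliers by convention.
- **Cohen's κ** on 2×2 method tables, with sensitivity/specificity in both
  reference directions (the published table prints both); κ bands weak
  < 0.4 / moderate 0.4–0.8 / strong > 0.8; an empty reference class gives
  `NA`, never 0; degenerate perfect agreement (p_e = 1) reports κ = 1.
- **Bland–Altman**: mean difference ± 1.96 × sample SD (n−1).
- **validation_concordance** exposes both display conventions: half-up
  rounding (10/11 → 91) and truncation (103/104 = 99.0385 → 99.03, the
  convention under which the published GIAB overlap prints).

# Survival

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (`survfit`/`survdiff`) behind a plain-table API; the
test suite cross-checks both against independent brute-force
implementations (explicit product-limit loop; per-event-time 2×2
summation). The source names only the estimator, not its two-group test;
the log-rank test is the standard companion and is our documented choice.
No Cox modelling or competing risks — none appear in the method.

# The synthetic-data generator

`simulate_cohort()` states a world rather than exposing dials:

| Parameter | Default | Why |
|---|---|---|
| purity | U(0.85, 0.95) | stated tumor cellularity of the specimens |
| amplicon depth | NB(mean 500, size 11.1) | CV ≈ 0.3, realistic amplicon overdispersion |
| driver CCF | 1.0 | GNAQ/GNA11/BAP1 are truncal in UM |
| gene frequencies | published cohort rates (GNAQ 0.591, GNA11 0.296, BAP1 0.41, …) | GNAQ/GNA11 exclusivity enforced by a single categorical draw |
| imbalance frequencies | chr1 0.50, chr3 0.66, chr8 0.568 | published cohort rates |
| copy states | chr1 loss, chr3 monosomy, chr8 gain | the field's typical aberrations (1p loss, monosomy 3, 8q gain) |
| SNP heterozygosity | 0.5 | loci were chosen to be highly polymorphic |
| survival | exponential, median 100 months; HR 2.5 (BAP1), 3.0 (Imb3); censoring U(24, 150) | univariate stratum-linked hazards mirror the univariate comparisons |

Noise variants (synonymous, low-VAF artifacts, benign/common germline) are
injected so the filter chain does real work; ground truth labels them and
is never consumed by the pipeline under test. What the generator does
*not* emulate: FFPE artefact spectra, subclonal structure, mapping error,
primer dropout, matched-normal contamination. A green ground-truth
recovery test therefore establishes that the pipeline's logic is correct
under the stated noise model, not that the assay performs at these levels
on archival tissue.

# Numerical and degenerate-input conventions

Zero total depth is an error (VAF undefined), not a 0. Empty SNP input
yields `NON_INFORMATIVE` with zero counts. Band edges are inclusive on
every stated interval. Percent rounding is half-up (base `round()` is
banker's). The bundled panel file is a *synthetic reconstruction* —
approximate hg19 gene intervals, invented rs-numbered SNP loci with the
correct counts and arm coverage — because the original appendix
coordinates are not available to this implementation; downstream code
depends on the structure, not the identities. Coordinates are 1-based
inclusive internally; BED input is shifted at ingestion; `chr` prefixes
are stripped.

# Known limitations

- Monosomy at purity above ≈ 94.7% is structurally undetectable under the
  published bands (see above).
- Copy-number calls for *BAP1*/*CDKN2A* deletions are out of scope, as is
  distinguishing gain from loss from copy-neutral LOH.
- The amplicon-count metadata (418) is carried, not derived: primer design
  and in-silico coverage prediction are external to this package.
```{r session}
sessionInfo()
```
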