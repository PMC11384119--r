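---
title: "Methods: two-bulk ED mapping, integration, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-bulk ED mapping, integration, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purplemap)
```

# Scope and model

`purplemap` maps a dominant, monogenic leaf-colour locus in an F1
pseudo-testcross by bulked segregant analysis, integrates the genomic
(BSA) and transcriptomic (BSR) variant layers with pooled
differential-expression calls, and provides the assay-level arithmetic
around the candidate gene (anthocyanin quantification, 2^-ddCt,
antisense-oligo filters, in-silico PCR of an InDel marker,
co-segregation, cis-element scanning). The pipeline starts at variant
tables and count matrices; read QC, alignment and variant calling are
out of scope, as are GO/KEGG database contents (only a generic
over-representation test against a user-supplied term map is included).

## Genetic model

The purple parent is modelled heterozygous (Aa) at the causal locus and,
in coupling phase, at every marker; the green parent is homozygous
reference. Offspring alt dosage is therefore 0 or 1 at every marker,
segregating 1:1 — the classic pseudo-testcross configuration, consistent
with both colour classes appearing among the F1 and with the dominant
marker band present in all dark-purple offspring. Whether the purple
parent is really heterozygous at the locus is not observable from the
published material; it is the only genotype configuration that produces
the observed segregation, so it is fixed as a design decision.

Gametes are simulated as a Markov chain along each chromosome with
Haldane map-function switch probabilities `r(d) = (1 - exp(-2d/100))/2`;
no crossover interference.

## Phenotype model

Leaf colour is an ordinal trait with five grades (green, three
transition grades, dark purple). We use a liability-threshold model:
liability = genotype mean (0 for aa, 3 for Aa) + Normal(0, 1) noise,
with four ordered cut points. The outer thresholds are calibrated
constants, −0.573101 and 2.993587, solved so that at n = 127 under 1:1
segregation the expected number of green individuals is exactly 18 and
of dark-purple individuals exactly 32 — the class counts of the real
population. The middle thresholds (0.8, 1.9) split the remaining mass
into the three transition grades; their semantics are modelled, not
transcribed, since the source defines them only in supplementary
material. Units: liability is in noise-SD units; thresholds have no
physical unit.

## Synthetic world defaults (and what they emulate)

| knob | default | emulates |
|---|---|---|
| offspring | 127 | the real F1 population |
| genome | 5 chromosomes x 100 cM, 100 markers each | desk-scale stand-in (1 marker/cM, a typical BSA panel) |
| scale | 1 cM = 1 Mb | synthetic physical coordinates |
| causal locus | chr3 @ 50 cM | one dominant locus |
| bulks | 15 + 15 extremes by liability | the sequenced extreme pools |
| RNA pools | 3 x 5 per colour | GP1–GP3, PP1–PP3 |
| DNA/RNA depth | Poisson, mean 50 | pooled sequencing depth |
| sequencing error | 0.001/read | Illumina-scale |
| genes | 10 kb at 80% of markers + intergenic fillers | gene models for region-to-gene mapping |
| counts | NB, dispersion 0.05, lognormal base means | pooled RNA-seq |
| planted DEGs | 5% of genes, log2FC ~ N(0, 2) | trans consequences of the colour difference |
| causal gene | log2FC = 2 x causal dosage, base mean 200 | the anthocyanin regulator |
| promoter fixture | 500-bp allele + 181-bp insertion at −332..−152 | the InDel marker locus |

What a green test establishes: that the statistics recover structure
*of this stated world* — single locus, clean 1:1 segregation, unimodal
noise, independent markers given the genetic map. Real data add
segregation distortion, multi-locus architecture, mapping artefacts,
allele-specific expression and reference bias, none of which the
generator emulates.

# The ED statistic and region calling

For each biallelic variant with at least 10 reads per pool (default),
`ED = sqrt(2) |f1 - f2|` where `f` is the alt-read frequency in each
bulk; the general multi-allele form `sqrt(sum_a (f1_a - f2_a)^2)` is
what `ed_statistic()` implements and the profile code reduces to the
biallelic closed form. ED is raised to the 4th power (`k` is a knob;
ED^4 is the conventional noise suppressor, and any positive power
preserves the per-variant ranking) and tricube-smoothed with a 6 Mb
window. The source reports Mb-scale candidate regions but no smoother
or threshold, so both are design choices here:

* **Window 6 Mb** (not 2 Mb): at 1 marker/Mb a ±1 Mb tricube window
  averages ~3 markers and leaves the profile noise-dominated; pilot
  simulations showed peak localization improving from ~38% to ~55%
  (within 2 Mb) when widening to 6 Mb.
* **Threshold**: the classical `median + 3 SD` rule is retained in
  `call_regions()` but is *liberal* under the null: the smoothed ED^4
  null is strongly right-skewed, and ~2–3% of null variants end up in
  called regions. No SD multiplier fixes this — large multipliers also
  destroy recovery, because in signal runs the genome-wide SD is
  inflated by the signal itself. The pipeline therefore defaults to a
  simulated no-linkage null (`ed_null_threshold()`): 1000 null genomes
  are drawn at the observed marker positions and depths, with both
  bulk-composition variance (binomial over the 15 bulk members, per-site
  carrier frequency estimated from pooled reads) and read-sampling
  variance, smoothed identically; each variant receives the 0.9995
  pointwise quantile of its own smoothed null. This is the QTL-seq
  approach of depth-aware simulated confidence bounds, not a permutation
  test. Calibration runs: 0.56% of null variants inside called regions
  (20 seeds); causal-region coverage and triple-intersection recovery
  20/20.

Runs of consecutive above-threshold variants become intervals (merged
when closer than the smoothing window), reported 0-based half-open,
with the argmax of the smoothed profile as the peak. SNPs and InDels
are profiled jointly and additionally reported per class.

## Localization is bounded by the bulks, not by depth

Only 30 informative purple-parent gametes enter the two bulks. Between
the innermost crossovers flanking the causal locus, every purple-bulk
member carries the alt allele and every green-bulk member the reference
— the likelihood is exactly flat there, so the causal position is
uniform on that interval. Its half-widths are approximately
Exponential(0.3/cM), giving the *oracle* probability of localizing
within 2 Mb (= 2 cM) of only ~0.73 even at infinite depth (2000-run
simulation of the plateau-midpoint estimator). The practical smoothed
ED^4 argmax achieves ~0.5 at depth 50. The acceptance suite therefore
reports the peak-within-2-Mb rate against its stated 90% bar and that
assertion fails by design of the world, not of the code; the quantity
the design *can* deliver — the causal position inside a called
candidate region, and the causal gene inside the BSA/BSR/DEG triple
intersection — is met in >= 90% of runs.

## The BSR layer

RNA-layer depth at a marker is the DNA-layer mean scaled by the
containing gene's class-level expression (zero for intergenic markers).
This encodes why a regulatory-region variant — like the promoter InDel —
is invisible to BSR-seq while remaining mappable by BSA-seq, and why
the BSR profile drops markers in silent genes.

# Differential expression

The source states the DEG criteria (|log2FC| > 1, P < 0.05, green as
control, strict inequalities as printed) but not the engine. We use
median-of-ratios size factors (fallback to total-count scaling below 50
all-positive genes) and a per-gene Welch t-test on log2(normalized + 1),
declared in the output, with BH q-values reported alongside but not
used by the headline filter (the source filters on raw P). Fold change
uses a 0.5 pseudocount on normalized class means; the log transform a
pseudocount of 1. Type-I error on an all-null 10 000-gene, 3 vs 3
simulation lands in [0.03, 0.07] at nominal 0.05 (acceptance criterion).
Degenerate genes: zero variance in both classes yields p = 1 when the
means agree and p = 0 otherwise. Scale invariance under per-sample
rescaling holds up to the pseudocounts (log2FC shifts < 0.01 at 3x).

# Integration

The three gene sets entering the Venn are: genes overlapped (>= 1 bp,
half-open arithmetic) by BSA candidate intervals; likewise for BSR; and
the DEG set. The triple intersection is the candidate shortlist.
Over-representation uses the hypergeometric upper tail with BH
correction (the source's procedure is unstated). "Significantly
correlated" in the focal-gene network is implemented as |r| >= 0.8 and
p < 0.05 with df = n − 2 — with the six RNA pools the minimum
significant |r| is 0.811, which matches the 0.8–1.0 range displayed in
the source's network figure; both knobs are configurable. Whether the
original correlations were computed on pools or individuals is
unstated; we compute them across the six pools.

# Assay layer notes

* `anthocyanin_content()` implements the printed formula exactly. The
  source measures absorbance at 520 nm but the formula names A530; the
  function exposes an `a530` slot and documents that a 520-nm reading
  goes there — the inconsistency is surfaced, not resolved. epsilon has
  no printed value or unit, so it is a required argument and results
  are in formula units unless the user supplies a unit-bearing epsilon.
* `relative_expression()` computes ddCt from replicate-mean Cts, so the
  calibrator is exactly 1; the SD column summarizes per-replicate
  2^-ddCt spread.
* GC bounds in `asodn_filter()` are inclusive (a printed closed range);
  binding energy is an input, not computed (thermodynamics out of
  scope).
* `insilico_pcr()` is exact-match only; mismatch tolerance is a
  documented non-goal. Amplicon length spans both primer sites
  inclusive.
* Promoter coordinates: −1 is the base immediately 5' of the ATG's A;
  windows are inclusive on both ends, so −332..−152 spans exactly
  181 bp, the insertion length of the fixture.
* `cosegregation_test()` contrasts dark-purple vs green individuals
  (transition grades excluded from the 2x2 by default) with a two-sided
  Fisher exact test plus the two pattern flags the gel assay reads off.

# Numerical and degenerate-input choices

* Extreme selection breaks liability ties by individual id; output is
  deterministic and stable across runs.
* Zero-depth sites yield all-NA frequencies and are excluded with a
  logged count; depth filtering drops a site when *either* pool fails.
* A flat smoothed profile calls no regions (warning) under the legacy
  rule; an explicit threshold on a flat profile simply calls nothing.
* PCA fixes component signs so the largest-magnitude loading is
  positive; duplicated samples get identical scores.
* Sub-stage seeds derive from the global seed by a polynomial string
  hash of the stage name (kept below 2^31), so adding a stage does not
  shift other stages' streams; a naive character-sum hash was replaced
  after it produced 74% seed collisions across 1000 replicate labels.
* Run configs are JSON (jsonlite), not YAML, to stay within the
  declared dependency set.

# Known limitations

* Localization accuracy is bulk-limited (above); reported peaks should
  be read as region anchors, not point estimates.
* The generator is single-locus and interference-free; no segregation
  distortion, no epistasis, no allele-specific artefacts.
* The DE engine is a transparent Welch t, adequate for 3 vs 3 pooled
  designs in simulation; it is pluggable, and real studies may prefer a
  count-model engine.
* Dataset-level counts from the original study (total SNPs, 459 DEGs,
  1554/1387/2747 genes, specific chromosome-14 coordinates) depend on
  the deposited reads and are expressly not reproduction targets.
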