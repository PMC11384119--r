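# purplemap

Bulked-segregant mapping of a dominant leaf-colour locus in tea, as a
reusable, fully synthetic-testable R pipeline.

## The problem

Purple-leaf tea accumulates anthocyanins under the control of a dominant
locus. Given an F1 pseudo-testcross population (heterozygous purple
parent x homozygous green parent) one can map the locus by sequencing
two pools of phenotypically extreme individuals (15 dark purple, 15
green) and looking for variants whose allele frequencies diverge between
the pools. `purplemap` implements that analysis for both a genomic
variant layer (BSA-seq) and an RNA-seq variant layer (BSR-seq), plus the
downstream integration used to nominate a causal gene:

* **ED mapping** — per variant, the Euclidean distance between the
  bulks' allele-frequency vectors,
  `ED = sqrt(sum_a (f1_a - f2_a)^2)`, raised to the 4th power to
  suppress noise, tricube-smoothed along each chromosome, and
  thresholded against a simulated no-linkage null (bulk-composition +
  read-sampling variance, QTL-seq style) to call candidate regions and
  the genes they cover.
* **Differential expression** — median-of-ratios normalization, Welch's
  t on log2(normalized + 1), DEGs at `|log2FC| > 1` and `P < 0.05`
  (green pools as control), PCA ordination, qPCR concordance.
* **Integration** — 7-region Venn partition of the BSA, BSR and DEG
  gene sets (the triple intersection holds the prime candidates),
  pathway filtering, hypergeometric over-representation with BH
  correction, and a focal-gene Pearson correlation network
  (`|r| >= 0.8`, `p < 0.05`).
* **Assay mathematics** — spectrophotometric anthocyanin content
  `(A x V x n x 465.2) / (eps x m)` with
  `A = (A530 - A620) - 0.1 (A650 - A620)`; relative expression by
  2^-ddCt; antisense-oligo selection (40–60% GC, binding energy
  <= -8 kcal/mol); exact-match in-silico PCR for the 181-bp promoter
  InDel marker; Fisher-exact co-segregation testing; IUPAC cis-element
  scanning of promoter sequences.
* **Synthetic data** — a seeded generator for the whole stated world:
  127 F1 offspring by Haldane-model recombination, a liability-threshold
  colour model calibrated so a population of 127 carries on average 18
  totally green and 32 dark-purple individuals, 15+15 extreme bulks,
  six 5-plant RNA pools, Poisson/binomial pooled read depths, negative
  binomial counts with planted DEGs, and a promoter-allele fixture with
  a 181-bp insertion at -332..-152.

Everything runs from code; no external data are downloaded.

## Worked example

```r
library(purplemap)

res <- run_full(seed = 7)

res$bsa$intervals
#>   chrom    start      end peak_pos peak_smoothed n_variants
#> 1  chr3  9999999 13000000 12000000    0.04968915          4
#> 2  chr3 20999999 76000000 55000000    0.43786870         56
#> 3  chr3 81999999 85000000 83000000    0.06511711          4

res$sim$truth$causal_gene
#> [1] "GENE0450"
res$venn
#> venn_partition of BSA/BSR/DEG - union 139 genes
#> A_only B_only C_only     AB     AC     BC    ABC
#>     40      7     19     70      2      0      1
res$recovery$causal_in_triple
#> [1] TRUE
```

The major interval sits on chr3 around the planted causal locus at
50 Mb (synthetic scale, 1 cM = 1 Mb; the smaller flanking intervals are
shoulders of the same linkage signal), and the planted causal gene is
the single member of the BSA ∩ BSR ∩ DEG triple intersection — the package's
analogue of nominating the anthocyanin-pathway candidate. The assay
layer works standalone:

```r
fx <- make_promoter_fixture(seed = 1)
insilico_pcr(fx$long, fx$fwd, fx$rev) -
  insilico_pcr(fx$short, fx$fwd, fx$rev)
#> [1] 181
```

A thin CLI wraps the stages (`inst/cli/purplemap`):

```sh
purplemap simulate --out sim/ --seed 7
purplemap bsa --vcf sim/bsa_pools.vcf --gff sim/genes.gff3 --out bsa/
purplemap de --counts sim/counts.tsv --classes classes.csv --out de/
purplemap run-all --out results/ --seed 7
```

## Known limitation

With 15+15 bulks only 30 informative gametes reach the pools, so the
causal position is only bounded by the innermost crossovers (half-widths
~Exp(0.3/cM)). Even a perfect estimator localizes the peak within 2 Mb
in only ~73% of simulations; the smoothed-ED⁴ argmax achieves ~50%.
Candidate *regions*, by contrast, cover the locus essentially always
(20/20 in calibration runs). See the methods vignette.
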