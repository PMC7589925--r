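---
title: "Inferring antagonistic miRNA-mRNA modules from sRNA, transcriptome and degradome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring antagonistic miRNA-mRNA modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomirnet)
```

## The inference problem

Plant miRNAs guide the cleavage of near-perfectly complementary mRNA
targets. A genuine regulatory interaction therefore shows up three
times in a multi-omics experiment: the miRNA is present in the small-RNA
libraries, the target is present in the transcriptome libraries, and the
degradome (PARE) libraries carry a pile-up of 5' ends at the predicted
cleavage position. When the interaction responds to a condition —
drought or heat during grain fill, or a genotype difference — the two
members additionally move in *opposite* directions: silencing increases
when the miRNA rises and relaxes when it falls.

`triomirnet` turns this reasoning into a three-step filter over a
factorial design of genotype (TG tolerant / SG sensitive), treatment
(CG control, WS water deficit, HS heat, WH combined) and developmental
time (5-45 days post anthesis, DPA):

1. **Validated pair universe.** A (miRNA, gene) pair enters the universe
   only if the miRNA is expressed, the gene is expressed, and at least
   one complementarity-predicted site on the gene is supported by
   degradome tags (category 0-4).
2. **Joint significance.** Both members must be differentially expressed
   at `p < alpha` (default 0.05, raw p) in the *same* contrast.
3. **Antagonism.** The fold-changes must have opposite signs; the
   direction (`mirna_up_mrna_down` / `mirna_down_mrna_up`) is recorded.

Each contrast is evaluated independently, so one pair can be reported
under several stress contrasts — stress-responsive module lists are
per-treatment, and genotype contrasts (TG vs SG within a treatment,
with "up" meaning higher in the tolerant genotype) form a parallel
family.

## Statistical components

### Differential expression

Counts are normalized to reads per million (sRNA) or FPKM (mRNA) and
tested feature by feature: a two-sided Welch *t*-test for two groups, a
classic one-way ANOVA for more. Tests run on `log2(x + 1)` by default —
on overdispersed abundance data the log transform brings the group
distributions close enough to normal that the Welch test holds its
nominal size even at a few replicates (the acceptance suite verifies a
false-positive rate within three binomial standard errors of 5% on 2000
null features). Fold-changes are computed on the original scale as
`log2((mean1 + 1)/(mean2 + 1))`; the pseudocount keeps them finite for
features with zeros. All-zero features get `p = 1`, `log2fc = 0` by
convention. Raw p-values drive the module filters (the convention for
this analysis style); BH q-values are always reported alongside for
transparency. For ANOVA over more than two groups no single fold-change
is defined and `log2fc` is `NA`; antagonism is therefore always assessed
on two-group contrasts.

Stress contrasts pool the five time-points of a (genotype, treatment)
cell against the genotype's control libraries. Pooling is valid here
because baseline means are condition-independent in the generator; on
real data with strong developmental trends one would instead test per
time-point (the functions accept any grouping factor).

### Target-site scoring

Duplexes are scored gaplessly with the de facto plant rule set: each
miRNA position contributes 0 for a Watson-Crick pair, 0.5 for a G:U
wobble, 1 for a mismatch, and penalties are doubled across positions
2-13 (the seed-to-central region whose pairing determines cleavage
competence). Sites score at most 4.5 by default. Gapless alignment is a
deliberate restriction: it matches the dominant geometry of plant
cleavage sites, makes the scan exactly checkable against a brute-force
oracle, and keeps coordinates unambiguous. The cleavage position is the
transcript nucleotide opposite miRNA position 10, the 5' side of the
10-11 duplex center where slicing occurs. The sliding-window scan is
implemented in C++ (Rcpp) and is verified window-by-window against the
pure-R `score_duplex()` on 2 kb transcripts.

### Degradome categories

A predicted site is classified against the transcript's t-plot (the
per-position tag-count vector) with the standard five classes: with `c`
the count at the site, `M` the transcript maximum and `med` the median
over *tagged* positions — category 4 if `c == 1`; category 0 if
`c > 1` and `c` is the unique maximum; category 1 for a tied maximum;
category 2 for `med < c < M`; category 3 for `1 < c <= med`; no category
if the site is untagged. The median is taken over tagged positions only:
including the structural zeros of a long transcript would drive the
median to 0 and make category 2 nearly unattainable, which is not how
established degradome tools behave. Categories are computed per library
from raw integer tag counts (they are evidence classes, not abundance
measures); differential degradation across conditions is tested
separately on per-million-normalized site counts. A site's summary is
its best (lowest) category across libraries, with the library recorded.

### Enrichment

Term enrichment is the one-sided hypergeometric (equivalently one-sided
Fisher) test, reported with the rich factor `k / n_term` — the fraction
of a term's genes recovered in the study set — as the effect size. The
population universe defaults to all annotated genes; supplying the
measured-gene universe instead is supported and changes p-values, so the
choice is explicit. There is no GO-graph propagation: the annotation is
taken as given.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested
against a known truth. It emulates:

* mature miRNAs of 21-24 nt and transcripts of 300 nt over {A,C,G,U};
* planted target sites: exact reverse complements of their miRNA
  (optionally degraded by prescribed mismatch/G:U edits), placed on
  fixed non-overlapping slots at least 30 nt apart so recovered
  coordinates are unambiguous;
* negative-binomial counts over the full 2 x 4 x 5 design: per-feature
  log-normal baseline means (median 200 counts, log-sd 1), per-library
  log-normal depth factors (log-sd 0.1), one dispersion (default 0.1, a
  typical biological-replicate value for sequencing counts);
* planted antagonism: each antagonistic pair multiplies the miRNA mean
  by `2^(+-2)` in one (genotype, treatment) cell and the target mean by
  the opposite factor. Antagonistic pairs use dedicated miRNAs, while
  the remaining planted sites share the rest of the catalog (one miRNA,
  several targets — as in real regulomes); this keeps the truth table
  free of half-planted pairs;
* degradome libraries, one per (genotype, treatment) cell as in a
  typical 8-library PARE experiment: each planted site gets a Poisson
  peak with expectation `0.25 x` the guiding miRNA's mean count in the
  matching cell (linear abundance-to-cleavage coupling, the simplest
  model that yields category-0 signatures at expressed sites), over a
  sparse uniform background of 0.005 tags/nt/library (degradome noise
  concentrates at decay hotspots, so per-position background is low).

Every stage derives a fixed sub-seed from the plan seed and is
byte-identical on re-run.

The reference scenario — the plan defaults — uses 100 miRNAs, 500
transcripts, 500 planted sites of which 50 antagonistic, effect
`log2fc = 2`, dispersion 0.1, 3 replicates per cell. On it the
three-step integration recovers the planted modules with recall ~1.0
and precision ~0.9 (the residual false positives are the chance
`alpha^2/2` passes expected among 450 null pairs across six contrasts).

**What passing these tests does and does not show.** The generator's
counts are exchangeable within cells: no developmental trends in the
baseline, no batch structure, no correlation between features beyond the
planted coupling, no isoforms, no sequencing-error or mapping artifacts,
and degradome background is uniform rather than hotspot-structured.
Recovery on this simulation therefore validates the *logic and
calibration* of the pipeline — not its robustness to the full mess of
real grain libraries, where normalization choices, uneven replication
and pleiotropic miRNAs will bite first.

## Numerical and design choices

* **Pseudocount 1.0** in logs and fold-changes (configurable).
* **Zero-variance groups** in the Welch test: equal means give `p = 1`,
  unequal constant groups `p = 0` — degenerate cases that only arise on
  tiny integer counts.
* **Presence threshold 0**: any positive normalized abundance counts as
  expressed; raise it to emulate detection floors.
* **Temporal classes** require monotone profiles with at least a 2-fold
  end-to-end change for ascending/descending; interior-peak classes
  require a unique maximum. Flat profiles are `other`. The rule is
  scale-invariant.
* **Ties in site de-duplication** (same miRNA, same gene, same category)
  resolve to the 5'-most site.
* **Category cutoff** for "validated" defaults to 4 (any degradome
  evidence); tighten via `max_category` when precision matters more than
  sensitivity.
* **Zero fold-change with significant p** (possible under ANOVA or
  exact ties) has no direction and is excluded from antagonism, with a
  message.
* **Differential degradation as a fourth filter** is available
  (`test_differential_degradation`) but not wired into the default
  module definition: requiring it would conflate evidence of *pairing*
  with evidence of *regulatory change*, and the two are reported
  separately.

## Problem sizes

The shipped tests and the acceptance script are sized for a laptop-class
single core: oracle sweeps use 1000 random cases, null calibration 2000
features, and the reference recovery scenario 600 features x 120
libraries (about ten seconds end to end). All sizes scale linearly; the
same code runs unchanged on full-size catalogs (hundreds of miRNAs,
tens of thousands of genes), with the all-vs-all site scan dominating
runtime.

## Known limitations

* Gapless duplexes only: bulged sites and target mimics are out of
  scope, as is thermodynamic (free-energy) scoring.
* Translational repression leaves no degradome footprint and is
  invisible to this pipeline by design.
* The integration treats contrasts marginally; it does not model the
  full factorial structure jointly (no interaction tests).
* Transcript-to-gene collapsing is an explicit input map; there is no
  isoform-level quantification.
* Enrichment ignores term-term redundancy and the GO DAG.
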