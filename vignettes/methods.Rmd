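---
title: "Methods: clonal-evolution inference from multi-region tumor and spheroid sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal-evolution inference from multi-region tumor and spheroid sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherophylo)
```

## The problem

High-grade serous ovarian cancer typically presents with malignant ascites:
peritoneal fluid carrying multicellular tumor spheroids, the vehicles of
transcoelomic metastasis. Whether the spheroids are a genetic mirror of the
primary tumor or an independently evolving lineage is a question about clonal
phylogeny: sequence multiple regions of the primary tumor and multiple
individual spheroids, genotype their somatic alterations, and reconstruct the
tree relating them.

`spherophylo` implements that inference chain end to end:

1. **Copy-number profiling** from low-depth whole-genome sequencing by
   variable-size binning with Lowess GC normalization, and hierarchical
   clustering of the per-sample profiles into genetic subgroups.
2. **Somatic SNV consensus** from high-depth whole-exome call sets of three
   variant callers, with a two-stage artifact filter and an allele-count
   rescue test.
3. **VAF-based cellular composition**: tumor purity per sample, detection of
   subclonal structure, and a clonality index for sample pairs.
4. **Phylogenetics**: joint multi-sample segmentation, trinary CNA and binary
   SNV event matrices, and maximum-parsimony trees rooted at the normal.

Because spheroid cohorts of this kind are not publicly deposited, the package
ships a **synthetic-data generator** that produces the same observable layers
(binned read counts, pileups, three caller call sets) from a known clone tree,
so every stage is testable against ground truth at desk scale.

## The synthetic cohort generator

`simulate_clone_tree()` draws a rooted clone tree: the root is the normal
genotype, the first clone is the ancestral tumor clone and later clones attach
to uniformly chosen existing clones (or to an explicit `parents` topology).
Somatic events are distributed over branches with three guarantees:

* every branch carries at least one event (a clone indistinguishable from its
  parent is not a clone);
* when the budget allows, every branch carries at least one SNV *and* one CNA,
  so trees built from either data type alone can resolve every branch, as both
  trees did in the motivating study;
* CNA segments are mutually non-overlapping. Clone-defining lesions are
  modelled as distinct regions; overlapping events on different branches would
  cancel (a gain over a loss) or saturate (nested losses both read as "loss"
  in a trinary code), destroying branch signal in a way the method does not
  claim to handle. Subclonal mixtures and nested rearrangements are out of the
  generator's scope.

SNV loci are uniform over the genome; CNA lengths are log-uniform between 30%
and 90% of the host chromosome. The fractions are chosen so that, at the
desk-scale bin counts used throughout (hundreds of bins), each CNA spans
several-to-tens of bins — the same segment-to-bin ratio as arm-level tumor
CNAs seen at a 15,000-bin genome-wide resolution. A sub-bin CNA is an artifact
of scaling the genome down, not a regime the binned method addresses.

Per sample (`sample_specs()`: group, clone, purity, mean depth):

* **Binned WGS counts** — expected count of bin $b$ is
  $\mu_b = d\,[\,p\,c_b/2 + (1-p)\,]\,g(\mathrm{GC}_b)$ with $d$ the mean
  reads per bin, $p$ the purity, $c_b$ the clone's copy number (diploid
  baseline, ±1 per event) and $g$ a monotone GC-efficiency curve rescaled to
  mean 1; counts are Poisson.
* **WES pileups** — per-locus depth is negative-binomial with mean 134 and
  size 55, matching the modest overdispersion of a 134 ± 21 exome; alt reads
  at a clonal heterozygous locus are $\mathrm{Binomial}(\mathrm{depth}, p/2)$.
* **Three caller call sets** — true loci with at least `min_alt` (2) alt reads,
  thinned by a false-negative rate, plus two distinct error modes:
  *caller-private* NGS false positives (each invented by exactly one caller,
  with no allelic support in the pileup) and *sample-private* amplification
  (WGA) artifacts, which look allelic (VAF 0.15–0.5 in the pileup) and are
  seen by at least two callers of that sample — but by no other sample.
  Error rates are expressed per true somatic locus; the study gives no
  quantitative WGA error rate, so the defaults (0.05) are free parameters
  chosen to make the filters' work visible without dominating the data.
* Optional **germline heterozygous loci** (VAF 0.5 in every sample including
  the matched normal) exercise the germline-removal step.

All randomness flows from one root seed through named substreams
(`substream_seed()`), so adding a sample never changes another sample's draws
and every run is reproducible.

## Copy-number profiling

`build_variable_bins()` implements variable-size binning: bin boundaries are
placed so each bin contains an equal number of uniquely-mappable reference
positions, making the expected read count uniform across bins for a diploid
genome and absorbing mappability variation into bin width. The bin quota is
apportioned per chromosome by largest remainder, so bins never straddle
chromosomes; the equal-count guarantee is exact to ±1 within a chromosome.
Coordinates are 0-based half-open (BED) throughout; variant positions are
1-based (VCF convention).

`lowess_gc_normalize()` divides counts by a Lowess trend of count versus GC
(span 0.3, one robustifying iteration — the method names Lowess but no span)
and rescales to preserve the genome-wide median. Copy-number signal is local
in genome position but spread across GC, so the smooth trend captures
amplification/sequencing efficiency, not biology. A second pass changes the
output only within smoothing noise (about 0.2% on Poisson counts; exactly zero
on trend-free data) — a genuine smoother re-fits its own noise, so exact
idempotence is not attainable or claimed.

`estimate_copy_ratio()` divides a sample's normalized depths by the median
normalized depth of the reference (matched normal) DNA, putting
diploid-neutral at 1.0; the mixture algebra gives an expected ratio
$p\,c/2 + (1-p)$ for copy number $c$ at purity $p$. This presumes samples
sequenced to comparable depth, as the simulator (and the study) provide.
`depth_distribution_qc()` summarizes the ratio distribution (variance, moment
skewness, flag at |skew| > 1): uneven whole-genome amplification shows up as
heavy-tailed, skewed profiles. `cluster_profiles()` performs agglomerative
clustering (Euclidean, Ward linkage) with the cluster number chosen by mean
silhouette over $k \in [2, \min(6, n-1)]$ — the study names only
"hierarchical clustering", so distance, linkage and $k$-selection are package
choices, recorded here.

## SNV consensus

The filter chain, with defaults `consensus_config(min_callers = 2,
min_samples = 2, fisher_alpha = 1e-3)`:

1. **Intra-sample double-calling** — keep loci reported by at least two of the
   sample's three callers. Caller-private NGS errors do not replicate across
   callers.
2. **Germline removal** — drop loci called in the matched normal. (Applied
   after double-calling, following the order the method describes; the two
   commute for the final set.)
3. **Confident sites** — keep loci double-called in at least two samples.
   Each sample is amplified in its own WGA reaction, so amplification
   artifacts are sample-private and do not recur across samples.
4. **Fisher rescue** — at every confident site, in every sample, the variant
   is accepted if at least one caller reported it there *and* its allele
   count significantly exceeds that of the other non-reference bases:
   one-sided Fisher's exact test on
   $[[\mathrm{alt}, D-\mathrm{alt}], [\mathrm{other}, D-\mathrm{other}]]$
   with $p < 10^{-3}$, where "other" is the **larger** of the two remaining
   non-reference base counts (the conservative comparator). The method does
   not state the table layout or sidedness; comparing the alt fraction
   against the worst competing base, one-sided, is the most defensible
   reading and both are configurable. Samples where the site was
   double-called are present outright; rescue recovers allele dropout in
   single-called samples without ever adding loci.

Locus identity is (chrom, pos, alt): the same position with a different
alternate allele is a different variant. Final loci are categorized
`common` (present in ≥1 primary and ≥1 ascites sample), `primary_only`, or
`ascites_only`; `summarize_categories()` turns counts into the percentages
the report prints.

The filter trades sensitivity for specificity in one documented way: a true
variant private to a *single sample* cannot become a confident site. In the
motivating design every clone is carried by several samples (multiple regions,
multiple spheroids), so clone-level recall is unaffected; the recall tests
reproduce exactly that condition.

## VAF, purity, clonality

With diploid heterozygous clonal variants, VAF concentrates at purity/2, so
`estimate_purity()` returns $\min(1, 2\,\mathrm{median\ VAF})$ over
common-category loci and flags samples below 0.3 purity for exclusion from
phylogenetics — the threshold reflects the clear bimodality between
tumor-cell-rich and normal-cell-dominated spheroids and is configurable.
`compare_common_vs_private()` is a one-sided Mann–Whitney U test
(common > group-private, α = 0.01): in a sample containing subclones, trunk
mutations ride on every tumor cell while group-private ones ride on a subset.
The study reports only "p < 0.01" with no test named; Mann–Whitney is the
package's choice. The generator does not simulate within-sample subclones
(each sample is one clone plus normal cells), so on synthetic cohorts this
test is expectedly negative; its power is validated on constructed mixtures.

`clonality_index()` quantifies whether two samples share a clonal origin.
The study cites earlier clonality work without reproducing a formula, so the
package implements a likelihood-ratio index *as an interpretation*: each
shared mutation contributes $1/p_i$ (under independence both samples must hit
the same locus of background probability $p_i$, default $10^{-4}$); each
discordant mutation contributes a penalty factor (default 0.1, the relative
likelihood of a private mutation under a clonal versus independent origin);
the index is $\mathrm{CI} = \mathrm{LR}/(1+\mathrm{LR}) \in [0,1]$, defined
as exactly 0 when nothing is shared. Identical 20-mutation profiles at
$p_i = 10^{-4}$ give CI = 1.0 at one-decimal precision; the index is
symmetric in its arguments.

## Phylogenetics

`joint_segmentation()` finds chromosome-wise breakpoints **shared across
samples** by exact dynamic programming on the penalized least-squares
objective $\sum_s \sum_b (y_{sb} - \bar y_{s,\mathrm{seg}})^2 + \gamma K$,
the objective family of multi-sample piecewise-constant fitting, with
γ = 50 as in the study. Each sample is first standardized by a robust noise
scale (median absolute first difference / √2), so γ penalizes breakpoints in
per-bin noise units and is comparable across depths; means are reported on
the ratio scale. The DP is exact per chromosome (verified against exhaustive
breakpoint search), not a reimplementation of any particular package's
internals.

`trinary_matrix()` codes each (sample, segment) cell on the **ploidy scale**
(2 × ratio, so one copy = 1 unit): gain (+1) above mean ploidy + 0.7, loss
(−1) below − 0.7, neutral (0) within ± 0.5, and **missing** in the ambiguous
0.5–0.7 band — the literal thresholding rule of the method, including its
deliberate gap. "Mean ploidy" is the segment-length-weighted mean of the
sample, as the method leaves it undefined. The thresholds are on the ploidy
scale because a one-copy event moves ploidy by 1.0 (straddling 0.7), whereas
on the raw ratio scale a one-copy loss (−0.5) could never reach an 0.7
threshold. `binary_snv_matrix()` is per-sample presence (1/0) over the final
consensus loci. Both matrices always append an all-neutral/all-zero `normal`
pseudo-sample — the outgroup that roots the trees.

`parsimony_score()` is unit-cost Sankoff (Fitch-equivalent for binary data)
over the tree, vectorized across characters; missing values admit every state
at no cost, so an all-missing character scores 0. `search_max_parsimony()`
enumerates **all** unrooted topologies for up to 8 taxa (guaranteed optimum;
identical character patterns are collapsed with weights first) and returns
every co-optimal tree plus their strict consensus; above 8 taxa it
hill-climbs by nearest-neighbor interchange from a neighbor-joining start
with random restarts. The strict consensus matters: samples carrying the same
clone, or attached at an ancestral clone, admit several equally parsimonious
resolutions, and the consensus collapses exactly those arbitrary edges.
`compare_trees()` is the standard unrooted Robinson–Foulds distance.

## Problem sizes, defaults, and what the tests show

The default desk-scale configuration (`default_config()`) uses a 24-chromosome
genome scaled to ~36 Mb, 600 bins from 200,000 reference positions (the
binning contract itself is exercised at 15,000 bins from 5 million positions),
150 somatic SNVs, 18 CNAs and 30 germline SNPs on a three-clone tree
(ancestral → primary clone + ascites clone), 11 samples (5 primary regions at
purity 0.60–0.70, 3 spheroids at 0.75–0.80, 2 spheroids at 0.10, one normal),
WGS at 570 reads per bin and WES at depth 134. These mirror the study design:
its three CNA clusters (primary, tumor-like spheroids, normal-like spheroids),
its low-purity exclusions, and its early-divergence topology. Tree-recovery
properties are checked over 20 no-noise replicates of six-clone trees (60
SNVs, 12 CNAs, one sample per clone), where both the SNV and the CNA tree
must match the truth (RF = 0) in at least 90% of replicates.

Passing these tests shows the chain is correct under its own model:
Poisson/negative-binomial counting noise, binomial allele sampling, diploid
±1 CNAs, caller- and sample-private artifacts. It does not demonstrate
robustness to features real cohorts add on top — subclonal mixtures within a
spheroid, allele-specific and high-amplitude copy number, mappability and
FFPE artifacts, indels, caller-specific biases — and the clonality index is
an interpretation of an uncited formula, not a reproduction.

## Numerical and degenerate-input choices

* All-equal GC: no trend is fittable; counts are returned unchanged with a
  warning. Fewer than 10 bins is an error.
* Zero-depth pileup records are dropped from VAF computation with a warning;
  a missing pileup at a confident site makes that sample's status absent,
  with a warning.
* Identical profiles: silhouette is undefined; clustering returns k = 2 with
  silhouette 0 and a warning.
* Single-bin chromosomes segment trivially; γ → ∞ yields one segment.
* Equally parsimonious trees are all returned (≤ 8 taxa) and summarized by
  strict consensus; the heuristic path reports the single best tree found.
* Purity is undefined without common-category loci; such samples are flagged
  low-purity (and excluded), never silently imputed.
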