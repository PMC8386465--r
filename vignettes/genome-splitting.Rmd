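---
title: "Splitting genomes and lumping species: methods behind rrnsplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting genomes and lumping species: methods behind rrnsplit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Bacterial genomes carry between 1 and 19 copies of the rrn operon, and the
16S rRNA genes in those copies are frequently not identical.  An amplicon
sequence variant (ASV) is, by definition, a cluster of *exactly identical*
sequences, so a genome with divergent operon copies is represented by
several ASVs — the genome is *split*.  Distance-based OTUs at a threshold
*t* reunite copies that differ by at most *t*, but a broad *t* also risks
*lumping* sequences from different species into one OTU.  `rrnsplit`
quantifies both sides of that trade-off on a catalog of genomes with known
species labels, and ships a synthetic community generator so the whole
pipeline is exercised without downloading a reference database.

The pipeline is: **catalog** (genomes + copies + one species label each) →
**region extraction** (trim every aligned copy to a hypervariable region)
→ **dereplication** (ASVs) → **pairwise distances** (sparse neighbor set)
→ **clustering** (OTUs at each threshold on a grid) → **statistics**
(fraction of genomes intact per copy-number class; fraction of ASVs/OTUs
containing several species), all under a species-controlled randomization
that samples one genome per species.

## The clustering objective

OTUs are formed de novo by an iterative maximizer of the Matthews
correlation coefficient (MCC) over sequence pairs, in the style of the
OptiClust family of algorithms.  Truth for a pair is "distance ≤ t"
(inclusive — a pair at exactly the threshold is within it); a call is
"placed in the same OTU".  With TP/TN/FP/FN counted over all pairs,

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

Conventions: a partition with `FP = FN = 0` is perfect (MCC 1); otherwise a
zero denominator factor yields MCC 0.

`opticlust_partition()` starts from all singletons and visits items in a
seeded random order, moving each to the existing or new cluster that most
improves the objective; ties keep the current assignment, then prefer the
smallest cluster id, with a fresh singleton considered last.  A pass with
no moves (or total gain below 1e-10, or 100 passes) ends a run;
`restarts` independent seeded runs can be taken with the best kept.
Confusion counts are maintained incrementally and re-derived from scratch
in the tests.

Two numerical details matter:

* **Plateau regularization.**  Moves are ranked not by the exact MCC but by
  the MCC of counts shifted by 1e-9.  On tiny instances whole regions of
  the search space have a zero-denominator MCC (for example every state
  with `TN = 0` when all pairs are within the threshold), and the exact
  coefficient is flat at 0 there; the shifted form orders those states so
  the hill-climb can cross them, while agreeing with the exact MCC to
  ~1e-9 elsewhere.  Reported MCC values are always the exact form.
* **Inclusive thresholds with tolerance.**  All "distance ≤ t" comparisons
  carry a 1e-12 absolute tolerance so that distances that are exact
  rationals (k substitutions over m columns) are not dropped by floating
  rounding.

Two oracles guard the implementation: `complete_linkage_partition()`
(furthest-neighbor agglomeration via `stats::hclust` + `cutree`, whose
partitions are provably nested across thresholds) and
`brute_force_optimal()` (exhaustive enumeration of set partitions, capped
at 10 items).  The iterative clusterer matches the exhaustive optimum on
≥95% of random 6-item instances with 10 restarts, and can only fall below
it, never above.

## Distances and gap policies

Distances are computed between aligned ASV representatives (any member is
exact, since ASV members are identical strings) by a small C++ engine.
Columns where both sequences have gaps are never counted.  Three modes are
exposed because the reference tooling's settings are a known unknown in
this kind of analysis:

* `gap-run-single-difference` (default): a maximal run of gaps in one
  sequence is one difference and one compared unit — the default of the
  widely used `dist.seqs` calculator;
* `each-gap-a-difference`: every gap-vs-base column counts separately;
* `ignore-gap-columns`: only columns where both sequences carry a base are
  compared.

`count_terminal_gaps = FALSE` first trims columns before the first and
after the last position where both sequences have a base.  A pair with no
comparable units is assigned distance 1.0.  The sparse `neighbor_pairs()`
set keeps every pair at distance ≤ `d_max` (default 0.10, the top of the
threshold sweep); the clusterer only ever needs those.

## Regions

Region coordinates are 1-based inclusive positions on the unaligned
E. coli K-12 MG1655 (NC_000913) 16S gene: V1-V9 (28–1491), V3-V4
(358–786), V4 (534–786), V4-V5 (534–908).  `map_reference_coordinates()`
converts them to alignment columns through the gapped reference;
`extract_region()` trims and degaps every copy.  A copy with a gap at
either boundary column is dropped by default (a primer could not land
there); the alternative `keep` policy trims regardless, since whether
partially covering sequences were retained upstream is not documented for
this kind of analysis.  Copy-number classes are therefore computed per
region from the *surviving* copies.

## The species-controlled randomization

Uneven sampling of genomes per species would otherwise let heavily
sequenced species dominate: each replicate draws one genome per resolved
species uniformly (`sample_one_genome_per_species()`), the pooled ASV set
of the subset is clustered at every grid threshold, and medians with
linear-interpolation (type 7) interquartile ranges are reported across
replicates.  Defaults follow the study design: thresholds 0.0025–0.1000
in steps of 0.0025, 95% confidence for the collapse threshold, 100
randomizations, and copy-number classes kept only when present in more
than 100 species.  Every replicate's seed is derived deterministically
from the master seed, so runs are byte-reproducible.

The *collapse threshold* of a copy-number class is the smallest grid
threshold at which at least 95% of the class's genomes have all their
ASVs in a single OTU; a class that never reaches that on the grid is
reported as `NA` ("> 10%"), not extrapolated.  Clustering is performed on
the pooled subset, not per genome, so between-genome sequences may bridge
or absorb a genome's ASVs — that is the quantity of interest, since real
databases are clustered as a whole.  Species labels come from organism
names with strain designations discarded (first two tokens, three for
*Candidatus*; `sp.`/single-token/unclassified names are excluded from the
resampling but kept in per-genome statistics).

Because the headline "variants per gene copy" average has several
reasonable readings, `variants_per_copy_summary()` reports all three: the
unweighted mean over genomes (the default headline), the mean over species
of per-species means, and the pooled ratio of total ASVs to total copies.
Likewise the species-accumulation ratio divides a species' distinct
variants by its *median* copies per genome (robust to assembly outliers;
switchable to the mean).

## What the synthetic generator emulates — and what it does not

`generate_community()` builds species templates by mutating a common
ancestor (rejection-sampled to keep templates at least `interspecies_subs`
apart), genome templates by adding `intergenomic_subs` substitutions, and
copies 2..k by adding per-copy substitution counts at positions never
reused within a genome — so substitution counts map *exactly* to Hamming
distances and every ground-truth quantity is analytic.  Defaults, chosen
once as desk-scale analogues of a curated genome database: 50 species;
genomes per species geometric with mean 3.4 (the genome-to-species ratio
of a large curated collection); copies per genome geometric with mean 4,
truncated to 1–19 (the observed range); 1500-bp genes; per-copy
substitution counts geometric with mean 1 (so roughly half the copies are
identical to their genome template and variants-per-copy lands near the
0.5–0.7 regime real genomes show); species templates ≥75 substitutions
(5%) apart.  `inject_shared_variant()` overwrites one copy of one genome
with an exact copy of another species' sequence, creating the cross-species
identical variants real databases contain; the `well_separated` check
guarantees that *only* injected variants can be shared, which is what
makes the expected multi-species ASV count exactly the number of links.

Deliberate simplifications: no PCR or sequencing error (the analysis
concerns ideal sequences from assemblies); no chimeras; no indels by
default (the alignment is columnar; an optional indel mode inserts
gap-bearing columns to exercise the gap policies, with insertion patterns
shared within a species so ground-truth distances are untouched);
substitutions are uniform over positions, so there are no hypervariable
hot spots — region-level contrasts in the synthetic data come only from
fragment length.  Between-species divergence is also far more regular than
real taxonomy: passing tests therefore demonstrate the *machinery*
(recovery of constructed distances, exact multi-species counts,
determinism), not the field values a real database would produce, which
depend on its taxonomic composition.

## Problem sizes

The shipped analyses and checks run at sizes a laptop CPU handles in
minutes: the simulated study community has 50 species (~175 genomes, ~730
copies) with 10 randomizations over the full 40-point threshold grid; the
copy-class-7 analysis uses 150 single-genome species with 7 copies each
and 5 randomizations; clusterer-vs-oracle comparisons use 200 random
6-item instances.  All of these are configuration, not code: `stat_config()`
and `synth_config()` scale every dimension, and the full-scale design
(100 randomizations, a real catalog of ~20,000 genomes) is reached by
changing only those parameters and supplying the real files to
`run_pipeline()`.

## Known limitations

* The MCC maximizer is a stochastic local search; on adversarial instances
  it can return a slightly sub-optimal partition (always detectably ≤ the
  exhaustive optimum on small cases).
* Multiple alignment is out of scope: inputs are consumed pre-aligned, and
  coordinate mapping trusts the provided reference record.
* Taxonomy is taken from metadata; no classifier is run, so species labels
  are only as good as the organism names.
* The multi-species fractions of the synthetic community reflect its
  constructed separation and injected links, not the dense species space
  of a real database.
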