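---
title: "Methods: catchment-structured phylogeography with 2ISP-aware distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catchment-structured phylogeography with 2ISP-aware distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylocatch implements a multilocus phylogeographic analysis for species
whose populations are structured by river catchments, together with the
palaeodistribution post-processing used to ask whether glacial-age range
contraction could have reinforced watershed barriers. This vignette is the
package's own account of the models and the design choices behind them.

## The data model: IUPAC state-sets and 2ISPs

Direct-PCR sequences of multi-copy nuclear regions (ITS, and to a lesser
degree low-copy loci such as ncpGS) routinely show two or more superimposed
bases at a site: intra-individual site polymorphisms (2ISPs). These are not
base-calling uncertainty — they record real within-individual copy
variation — so the package treats the extended IUPAC symbols as *state
sets*: `Y` is `{C,T}`, `V` is `{A,C,G}`, and so on. `N` and `?` are missing
data and never contribute information; `-` is an alignment gap. A site
where a gap is superimposed on a base has no IUPAC symbol, so such sites
carry an opaque per-pattern code (digits in the FASTA input).

Alignment gaps are recoded by simple indel coding: every maximal gap run
shared (with identical start and end) by at least one sequence becomes one
binary presence/absence character; a sequence whose longer gap covers the
run scores missing for that character. Gap runs immediately flanked by a
mononucleotide repeat of four or more identical bases (configurable) are
assumed to be polymerase slippage and are not coded. Columns inside coded
runs are removed from site-wise distance computation so an indel is never
counted twice.

## Polymorphism p-distances

The per-site kernel between two standard state-sets is the Jaccard
distance `1 - |A∩B| / |A∪B|`, which grades 2ISP information instead of
discarding it: `Y` vs `Y` is 0, `Y` vs `C` is 0.5, `Y` vs `R` is 1.
Pairwise distances average this kernel over comparable sites (pairwise
deletion of missing and gap sites) and add mismatches of shared indel
characters to the numerator and the shared-character count to the
denominator. The plain uncorrected p-distance used for chloroplast data is
the singleton special case of the same kernel, and the two agree exactly
on 2ISP-free data (a tested invariant). The kernel is a true metric —
symmetry, identity of indiscernibles and the triangle inequality hold over
all state pairs, exhaustively tested — so distance-based tree building is
well behaved.

Two conventions are our own where the companion distance literature is
silent: haplotypes are equivalence classes under *exact* state-set
identity (a `{C,T}` individual is a different haplotype from a `{C}`
individual — with 68 ribotypes among 75 ITS samples the 2ISP patterns are
clearly doing the distinguishing), and nucleotide diversity is the mean of
the pairwise kernel distances, 2ISP sites included.

## Isolation by distance

Mantel tests correlate genetic with great-circle geographic distance
(haversine, Earth radius 6371 km). The statistic is Spearman's rank
correlation over the upper-triangle pairs; significance comes from jointly
permuting rows and columns of one matrix, with
`p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)` and 10,000 permutations by
default. The tail is one-sided (greater) because isolation by distance
predicts a positive correlation. The permutation scheme is implemented
in-package so that every draw is controlled by an explicit seed; a unit
test cross-checks the observed statistic against vegan's Spearman Mantel,
and the type-I error rate is verified against binomial bounds under an
independent-matrix null (500 replicates of 999 permutations).

## Genealogical sorting

The genealogical sorting index quantifies how exclusively a predefined
group clusters on a rooted genealogy, from 0 (complete lack of divergence)
to 1 (monophyly). Let `U` be the internal nodes of the minimal subtree
connecting the group's tips through their MRCA, `n_min = |group| - 1`, and
`deg(u)` the node degree in the whole tree. Then

    gs     = n_min / sum_{u in U} (deg(u) - 2)
    gs_min = n_min / sum_{all internal u} (deg(u) - 2)
    gsi    = (gs - gs_min) / (1 - gs_min), clamped to [0, 1].

A degree-2 root contributes zero to both sums, which keeps the endpoints
exact: a monophyletic group scores exactly 1 and a maximally dispersed
group (uniting every internal node) exactly 0. The implementation is
validated against an independent brute-force computation of `U` (unions of
tip-to-MRCA node paths) over *every* labelled rooted binary topology with
up to seven tips.

Two boundary behaviours follow from the formula and are worth knowing.
First, a group of `n-1` tips on a fully resolved tree has `gs_min = 1`,
so the normalisation is undefined and `gsi()` raises an error (as it does
for a group containing all tips). Second, because the root contributes
zero, a group whose uniting path spans the root while covering one whole
root side can also score 1 without strict monophyly; monophyly is
sufficient, not necessary, for a score of 1.

Ensembles: trees come from bootstrap resampling of alignment columns and
indel characters jointly, with a neighbour-joining tree per replicate
(1,000 replicates by default). Parsimony and likelihood bootstrap
ensembles are out of scope, so ensemble means here are NJ-only. Each
ensemble tree is rooted with the configured outgroup when present,
otherwise at the midpoint, before scoring; the ensemble gsi reports the
mean and sample standard deviation against a sorting threshold of 0.6.
Per-tree significance uses uniform permutation of group labels over tips.

## Divergence-time bracketing

Bayesian dating is out of scope; instead the package builds a UPGMA
chronogram (average-linkage, deterministic, ultrametric by construction,
exact on ultrametric inputs) and divides node heights by two bracketing
substitution rates for non-coding chloroplast DNA: a slow 1.0e-9 and a
fast 31e-9 substitutions/site/year. Node ages are reported under both
rates — their ratio is exactly 1/31 by construction — together with a flag
for ages beyond the Pliocene-Pleistocene boundary (2.6 Ma). This is a
point-estimate bracket, not a posterior: no credible intervals are
produced, and the conclusion it supports is of the form "even under the
extreme rates, divergence falls within period X".

## Palaeodistribution post-processing

The package consumes continuous habitat-suitability grids (real or
synthetic); it does not fit distribution models. Continuous surfaces are
binarised at the equal sensitivity-plus-specificity threshold: scanning
the union of observed presence and absence scores, the cutoff minimising
`|sensitivity - specificity|` (ties broken by larger sensitivity +
specificity, then by the lower threshold). Ensembles of binary maps are
stacked into a cellwise agreement fraction. Within each catchment mask,
presence cells are grouped into 8-connected patches and summarised by
count, area, and the patch cohesion index

    PC = 100 * [1 - sum(p_i) / sum(p_i * sqrt(a_i))] * [1 - 1/sqrt(Z)]^-1

with perimeters `p_i` in 4-neighbour cell-edge units, areas `a_i` in
cells, and `Z` the catchment cell count (the 8-connected/4-edge convention
of the standard landscape-metrics tools). The mask boundary counts toward
perimeter, so habitat at the catchment edge is treated as bounded. A mask
fully covered by one patch scores exactly 100 and a single isolated cell
exactly 0 (both hand-verified in the tests); values are clamped to
[0, 100] against floating-point overshoot. `Z` is taken from the
catchment mask, not the full landscape, matching the per-catchment framing
of the question. Scenario comparison reports per-catchment area and
cohesion changes and flags fragmentation when the LGM surface is both
less cohesive and split into more patches.

## The synthetic-data generator

The simulator produces data with the statistical structure the analysis
assumes, so that the whole pipeline can be validated by parameter
recovery. Its components:

* **Demography.** K catchment populations under the n-coalescent
  (pairwise rate `1/(2Ne)` per generation), merging west-to-east at
  configured split times; optional symmetric migration. Defaults describe
  three deeply split catchments: `Ne = 5000`, generation time 10 years
  (a slow-maturing perennial shrub), splits at 0.8 and 1.5 Ma — deep
  enough (more than 10 Ne generations) that lineage sorting is expected.
* **Sequences.** Infinite-sites mutations (Poisson per branch, unique
  positions) on each locus's own genealogy. Defaults: a 1,948 bp
  chloroplast locus at the slow literature rate 1e-9, a fast 666 bp
  multi-copy nuclear locus (8e-9, four copies per individual), and a slow
  1,089 bp low-copy locus (1e-9, two copies) — chosen to reproduce the
  qualitative diversity ordering high-copy >> chloroplast > low-copy.
* **2ISPs.** Each individual's copies are independent tips in the same
  genealogy; collapsing them to the per-site IUPAC union creates 2ISPs
  whose abundance grows with copy divergence. Optional contact-zone
  swaps replace one nuclear copy of a boundary individual with a
  neighbour-catchment draw, emulating pollen-mediated introgression.
* **Geography.** Localities are drawn uniformly in disjoint west-to-east
  catchment boxes with a 10 km minimum spacing (rejection sampling).
* **Suitability grids.** The current surface is one Gaussian kernel per
  catchment plus noise; the LGM surface replaces each kernel with two
  smaller, weaker sub-kernels, so the LGM range contracts *and* fragments
  within every catchment by construction. A configurable pseudo-ensemble
  (216 members by default) jitters kernel centres and widths, each member
  binarised at its own equal-SS threshold.

What the generator does *not* emulate: recombination, selection, rate
heterogeneity across sites, concerted evolution of ribosomal copies,
realistic dispersal kernels or climate surfaces. Passing the recovery
suite therefore shows the pipeline is correct and well calibrated on data
satisfying its own assumptions; it does not certify behaviour on real
data violating them (e.g. intragenomic recombination between divergent
ITS copies).

## Numerical and procedural choices

* Tie-breaks are deterministic throughout (lowest index / lowest
  threshold first); every stochastic step takes an explicit seed, and
  fixture generation is byte-identical under a fixed seed.
* Negative NJ branch lengths are clamped to zero.
* Bootstrap replicates in which some pair has no comparable site are
  redrawn (at most ten times) rather than propagated.
* Pairs with no comparable sites at all raise an error naming the pair;
  groups of fewer than four samples skip the Mantel test rather than
  report an unstable statistic.
* Watershed reassignments and contact-zone exclusions are explicit,
  config-driven sample lists (with provenance recorded in the sample
  table), not computed from watershed polygons; the 5 km proximity figure
  is documentation of the criterion.
* Test and validation problem sizes (e.g. 5 samples per catchment in the
  pipeline fixtures, 100-tree ensembles in the recovery suite, a
  24 x 36 grid) are chosen as the smallest sizes at which the tested
  signal is unambiguous; the analysis defaults remain the full 1,000
  bootstrap replicates and 10,000 permutations.

## Known limitations

* NJ-only ensembles mean ensemble gsi values are comparable to published
  multi-method ensembles only approximately.
* The UPGMA chronogram assumes clock-like evolution; rate variation
  among lineages biases its relative node heights.
* The gsi normalisation is an operational reconstruction from the
  endpoint definitions (0 = fully dispersed, 1 = monophyly); parity with
  other implementations beyond those endpoints has not been established.
* Patch cohesion depends on the raster resolution; comparisons are only
  meaningful between grids of identical cell size.
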