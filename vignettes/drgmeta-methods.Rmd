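---
title: "Methods: cross-study integration of rodent DRG injury transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study integration of rodent DRG injury transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgmeta)
```

## The problem

Peripheral nerve injury (PNI) triggers a transcriptional program in dorsal
root ganglion (DRG) neurons — regeneration-associated genes such as Atf3,
Gap43 and Sprr1a rise, ion-channel and neuronal-maintenance genes fall.
Dozens of public RNA-seq studies profile this response, but they differ in
species (mouse, rat), injury model (spared/SNI, sciatic/ScNI, spinal/SpNI
nerve injury), timepoint (hours to months), tissue (bulk DRG vs sorted
neurons), sex composition and replicate structure. Any single study's DEG
list mixes the injury program with these idiosyncrasies. `drgmeta`
integrates per-comparison differential-expression tables across studies
and asks what survives the heterogeneity.

The unit of analysis is the *comparison*: one injury-vs-control contrast
with per-gene log2 fold-change (LFC), adjusted p-value (absent for
datasets without biological replicates), and optional mean normalized
expression. A catalog assigns each comparison to a species × model group;
the full rodent design has four (mouse SNI and ScNI, rat ScNI and SpNI).

## Ranking: the π-value

Within a comparison, genes are ranked by

$$\pi = -\log_{10}\!\big(\max(p_{adj},\, 10^{-20})\big) \times \mathrm{LFC}.$$

The product rewards genes that are both significant and strongly changed;
the cap at $10^{-20}$ bounds the contribution of underflowed p-values
(differential-expression software reports 0 when the test statistic
saturates double precision, and an uncapped $-\log_{10}$ would be
infinite). π is odd in LFC and monotone non-increasing in $p_{adj}$ for
up-regulated genes; both properties are asserted by tests. Comparisons
without replicates have no p-values and rank by LFC alone. Ranking is
restricted to genes passing the DEG thresholds, runs separately for up-
and down-regulation, and breaks ties by larger |LFC| then lexicographic
gene id so results are deterministic. Top-15 occurrence frequencies across
a group's comparisons summarize which genes recur; the denominator is the
group's full comparison count, not the count where the gene was detected,
so a gene absent from half the annotations cannot look spuriously
recurrent.

## Robust and conserved genes

A gene is a DEG in a comparison when $p_{adj} \le 0.05$ and
$|\mathrm{LFC}| \ge \log_2 1.5$ (fold-change criterion alone in
no-replicate mode, symmetrically for both directions). Only comparisons in
which Atf3 itself is called up — evidence the library really captures an
injured state at that timepoint — enter group analyses; the gate is
evaluated per comparison, and a missing Atf3 record fails it with a
warning rather than passing silently.

Within a group of $N$ comparisons each gene receives weight $x_{ij} = +1$
(up), $-1$ (down) or $0$ (neither, or not measured), and
$score_i = \sum_{j=1}^{N} x_{ij}$. Genes with $|score| \ge 0.5\,N$
(inclusive) are robust. $N$ stays fixed at the group size: a gene missing
from a comparison contributes 0 but still competes against the full
denominator, which penalizes genes measurable in only a few annotations —
deliberately, since the aim is cross-study reproducibility. Intersecting
robust sets across groups yields the conserved injury program; pairwise
overlap counts and percentages are emitted alongside for UpSet-style
reporting.

The vote threshold has a simple sensitivity model worth keeping in mind:
if a true effect gene is called in a given comparison with probability
$q$, its chance of reaching the threshold in one group is
$1 - F_{\mathrm{Binom}(N,q)}(\lceil N/2 \rceil - 1)$, and recovery of the
cross-group intersection is the product over groups. At the synthetic
defaults ($q = 0.8$ under 20% dropout; groups of 8/20/7/5) this product is
about 0.90 — the vote rule trades some sensitivity for an essentially
zero false-positive rate (observed precision 1.0), and small groups with
odd $N$ (7, 5) dominate the loss. Analysts wanting more recall should
lower `robust_fraction` knowingly rather than expect the default to be
lossless.

## Orthology and species preference

Comparing mouse and rat robust sets requires knowing which genes
correspond. Upstream protein clustering (e.g. OrthoFinder on longest
isoforms) supplies pairwise similarity; `drgmeta` consumes it as a
3-column table and forms connected components of the bipartite graph
thresholded at `min_score`, augmented with identical-symbol edges — the
rodent nomenclature convention names one-to-one orthologs identically, so
same-symbol genes are linked even without a similarity entry. Components
are classed single-copy (1+1), multi-copy (both species, > 2 genes) or
species-specific (one side empty); genes with no surviving edge become
species-specific singletons. Connected components are a deliberate
simplification of MCL-style clustering: the downstream logic consumes only
membership and copy class, not cluster granularity. The implementation is
checked against a brute-force union-find oracle on random bipartite
graphs.

Robustness lifts to clusters by the any-member rule (a cluster is
robust-up in a species if any member gene is), matching cluster-level
reporting of multi-copy DEGs. A cluster is a *mouse-preference* candidate
when it is robust-up in mouse while the rat side is quiet: rat up-vote
ratio below `other_species_max_ratio` (default 0.2 — under 20% of the
rat group's comparisons call it up) *and* either a small rat change
(median |LFC| below the fold-change cutoff) or low rat injury-side
expression (below `low_expr`, default 1.0 on the normalized RPKM/FPKM
scale). Rat-preference is symmetric; robust in both species is conserved.
Missing expression columns degrade gracefully: the call proceeds on votes
and fold-changes with the expression flag set to `unknown`. These two
defaults operationalize "low expression or small change" and are the most
judgment-laden constants in the package; both are configurable, and the
per-cluster support columns are returned so a reviewer can re-screen
candidates manually — published preference lists were manually curated,
and this rule is the automatable approximation, not a replacement for
that curation.

## Temporal clustering

Time-series datasets (at least three injured timepoints; the synthetic
default covers 9 h, 1 d, 3 d, 7 d) are clustered on profile shape: each
gene row is centred and scaled to unit population standard deviation
(zero-variance rows dropped), then soft-clustered by classical fuzzy
c-means — alternating centre/membership updates minimizing
$\sum_{i,k} u_{ik}^m d_{ik}^2$ with $\sum_k u_{ik} = 1$. Choices that
matter:

* **Fuzzifier** `m = 2`, the classical default; Mfuzz-style estimators on
  expression data typically choose 1.1–1.3, which gives crisper
  memberships. Configurable.
* **Cluster count** defaults to 8 for real DEG sets; the bundled drivers
  cluster the synthetic data at its four planted archetypes.
* **Initialization** seeds centres from `c` distinct genes via the seeded
  RNG; 5 restarts are run and the fit with the lowest objective kept,
  because a single alternating-update run occasionally merges two close
  archetypes (a local optimum). Given `seed`, the result is
  deterministic.
* **Convergence**: largest centre displacement < `tol` ($10^{-6}$) or 300
  iterations; the per-iteration objective is recorded and non-increasing,
  which tests assert.
* **Hard assignment** is argmax membership with ties to the lowest
  cluster index, for determinism.

Cluster numbering is arbitrary, so clusters are matched across datasets by
shared-gene counts between hard clusters, keeping edges with ≥ 10 shared
genes (`correspondence_min`); the output is invariant to label
permutations.

## Sex analysis

Four Y-chromosome genes expressed in DRG — Uty, Eif2s3y, Kdm5d, Ddx3y
(rat annotation: Ddx3) — are male-specific. A sample is male when ≥ 3 of 4
markers exceed the expression threshold (default 1.0 normalized units),
female when ≥ 3 fall at or below it, ambiguous otherwise; the 3-of-4 rule
tolerates one annotation dropout, and unmeasured markers count as below
threshold with a warning. Batch inference flags datasets whose replicates
receive conflicting calls — the failure mode where injury and control
groups differ in sex and injury DEGs absorb sex DEGs.

The four-comparison design crosses sex and treatment. Over genes DE in at
least one comparison: *injury-only* requires DE in the same direction in
both sexes' injury comparisons and no DE in either sex comparison
(direction-conflicting injury responses are *mixed*, not injury-only);
*sex-only* is DE in a sex comparison and neither injury comparison;
*mixed* spans both categories; everything else (e.g. DE in a single
injury comparison only) is *none*. The labels are mutually exclusive and
exhaustive, which a test asserts by enumeration. "Not DE" reuses the
global DEG thresholds — the package makes that assumption explicit rather
than introducing a second, looser criterion. Injury-only LFCs are
correlated between sexes (Pearson, two-sided t-test p); sex-biased
responses are split into eight regions of the (female LFC, male LFC)
plane cut at ±log₂ 1.5 per axis — four diagonal regions where both sexes
exceed the cutoff and four axis regions where only one does, with the
centre square excluded.

## The synthetic-data generator

The generator exists so every stage has a ground truth. Its defaults
mirror the full rodent integration: four groups with 8/20/7/5
comparisons, 53 conserved-up genes (Atf3 among them) and one
conserved-down gene (Vstm2b), 34 mouse-preference and 42 rat-preference
genes among 2000 total; planted |LFC| = 2 with Gaussian observation noise
(sd 0.3); adjusted p-values drawn log-uniformly in $[10^{-20}, 10^{-4}]$
for true effects and uniformly on $[0,1]$ for nulls; a 20% per-comparison
chance that an effect gene behaves as a null (dropout); one no-replicate
comparison in the rat ScNI group; Atf3 never dropped so the injury gate
stays exercised. Preference genes are lowly expressed in their
non-responding species so the expression filters fire. Time-series data
follow four archetypes — early-up by 1 d (Atf3-like), late-up by 3 d
(Gap43-like), monotone decline (ion-channel-like), and an immune-like
rise at 3–7 d — as template × lognormal amplitude under multiplicative
lognormal noise (sdlog 0.2), regenerated over the same gene ids in ≥ 2
datasets for correspondence testing. The sexed design plants a shared
injury program (per-gene |LFC| uniform in [0.8, 3], between-sex noise sd
0.1), sex-only genes, and the four Y markers at LFC 6 with underflowed
p-values — Y genes are absent in females, so their tests saturate. Marker
expression sheets draw male samples lognormal around 50 and female
samples zero-inflated near 0.

P-values are drawn, not computed from simulated counts: the pipeline
consumes DE tables, so emulating count-level inference would add
complexity without adding test power. Consequently the generator does
*not* emulate count overdispersion, correlated genes, batch effects,
annotation mismatches between studies, or p-value/effect-size coupling —
passing tests demonstrate the integration logic is correct under the
stated noise model, not that any biological conclusion transfers to real
archives. All generators are bit-reproducible given their seed.

## Numerical and degenerate-input choices

Adjusted p of exactly 0 is accepted on input (underflow) and only capped
at π-computation time. Squared distances in fuzzy c-means are floored at
$10^{-300}$ so a gene exactly on a centre gets membership 1 without
0/0. `c = 1` forces all memberships to 1; `c` exceeding the gene count is
an error. Harmonization collisions (two synonyms mapping to one canonical
symbol) keep the row with larger |LFC| and report the drop; identifier
matching is case-insensitive against the alias map, absorbing Atf3/ATF3
drift, and case-sensitive thereafter. Timepoints are stored uniformly in
hours (1 d = 24 h, 1 m = 720 h). Empty alias maps, empty groups, catalogs
with unknown species/model tokens, and missing schema slots in the
four-comparison design all fail fast with named errors.

## Problem sizes

The bundled drivers and the test suite run the full synthetic design
(40 comparisons × 2000 genes), 20-seed Monte-Carlo recovery for the
conserved set, 240-gene time-series with 4 clusters, and exhaustive
$3^8$ vote-vector enumeration — sizes chosen so the whole suite completes
in well under a minute per module on a laptop while still exercising
every rule at realistic scale.

## Known limitations

* Read-level processing (QC, alignment, quantification, DE estimation) is
  out of scope; the package starts from DE tables.
* The connected-components orthology stand-in cannot reproduce
  MCL-granularity cluster counts from real proteomes.
* Species-preference calling approximates, but does not replace, manual
  curation of candidate lists.
* The vote rule's sensitivity drops for small odd groups, as quantified
  above; conclusions about marginal genes in 5–7-comparison groups should
  be read with that in mind.
* Sex inference assumes Y-marker expression is quantified at all; sorted
  single-sex datasets with zero marker coverage return ambiguous calls by
  design.
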