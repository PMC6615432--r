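---
title: "Community phenotype profiling of B-vitamin auxotrophy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community phenotype profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosig)
```

# The model

`phenosig` estimates the prototrophic and auxotrophic fractions of a
microbial community, per B vitamin, from three ingredients: a phylotype
abundance table with best-match identities, a reference collection of
genomes with binary biosynthesis phenotypes (the BPM), and the mapping
rules that connect them.

## Phylotype mapping and weights

A phylotype's best-match percent identity sets its mapping rank:
strictly above 98% it is treated as a species-level hit, between 95 and
98% as genus-level, between 90 and 95% as family-level, and below the
family floor it is excluded from phenotype prediction. The species and
genus bands follow the standard 16S interpretation of those identity
ranges; the 90% family floor is a conventional choice, since no sharp
published cutoff exists at that rank. All three thresholds are
configurable (`mappingThresholds()`). A consequence of the open species
band is that an identity of exactly 98 maps at genus rank.

The phylogenetic neighborhood of a phylotype is the set of reference
genomes at its rank, weighted hierarchically with equal weights at each
taxonomic level:

* species rank: each strain genome of the species gets weight $1/n$;
* genus rank: each of the $S$ species in the genus gets $1/S$, split
  equally over its $n_s$ genomes, so genome weights are $1/(S n_s)$;
* family rank: equal per genus, then per species, then per genome.

This "equal per child, then recurse" rule, rather than a flat equal
weight per genome, prevents heavily sequenced species from dominating a
genus- or family-level average. Weights of a mapped phylotype always
sum to 1.

A phylotype whose name is absent from the collection at its assigned
rank is downgraded one rank at a time (species to genus to family)
with a warning, rather than discarded: this preserves abundance
coverage while recording the loss of precision. A name absent at every
rank is unmapped. Name matching is exact after normalization (trimming,
bracket conventions such as `[Eubacterium]`, whitespace, case); no
fuzzy matching is attempted, and since matching is exact, ties between
two equally matching reference species cannot arise.

## Phenotype indices and community signatures

Genome phenotypes are strictly binary (1 = prototroph). Each mapped
phylotype gets a per-vitamin prototrophy index
$p_{i,v} = \sum_m w_{i,m}\, p_{m,v}$, a convex combination of binaries
and hence a value in $[0,1]$ interpretable as the probability that a
cell of this phylotype carries the complete pathway. Fractional values
(0.25, 0.67, ...) arise only from strain or within-taxon heterogeneity;
they are never stored in the BPM.

The per-sample signature is then

$$\mathrm{CPI}_v \;=\; 100 \sum_i A_i \sum_m w_{i,m} p_{m,v},
\qquad
\mathrm{aux}_v \;=\; 100 \sum_i A_i (1 - p_{i,v}),$$

with $A_i$ the relative abundances (fractions). The two totals conserve
the mapped abundance: $\mathrm{CPI}_v + \mathrm{aux}_v = 100 \cdot
\text{mapped fraction}$, an invariant the test suite checks to 1e-9.
Unmapped abundance contributes to neither side. Whether published
community percentages renormalize by the mapped fraction is usually
unstated, so both conventions are emitted (`*_pct` and
`*_renorm_pct` columns) and the mapped fraction is always reported.

Replicate groups are aggregated as arithmetic mean and sample standard
deviation (the $n-1$ estimator; plain "STDEV" reports do not
distinguish the estimators, and the sample version is the conservative
choice at $n = 5$–$6$). Groups of one replicate report SD 0 and are
flagged by `n = 1`.

## Copy-number renormalization

16S read fractions overestimate taxa with many rRNA operon copies.
Optionally, each phylotype's abundance is divided by its mean 16S gene
copy number — looked up species first, then genus, then family, then a
table-wide default (the unweighted mean of all entries, since no
standard fallback exists) — and the sample is rescaled to sum to 1.
The stage is off by default: copy-number catalogs are incomplete and
imprecise, and read-based results are conventionally shown without it.
Because mapping weights are abundance-independent, renormalizing before
or after mapping yields identical CPIs (a tested invariant).

## Classification and group comparison

Per vitamin, an index at or below `auxThreshold` (default 0) is called
auxotrophic and at or above `protoThreshold` (default 1) prototrophic;
anything between is ambiguous. Under these strict defaults only fully
binary index vectors are classified — matching analyses restricted to
taxa with unambiguous auxotrophy — and relaxed thresholds (e.g.
0.2/0.8) are available for exploratory use. Classes: omni-prototroph
(all vitamins prototrophic), mono-auxotroph (exactly one auxotrophy),
multi-auxotroph (at least `multiMin = 3`), and a residual ambiguous
class that also holds two-vitamin auxotrophs, so the classes always
partition the mapped taxa.

`compareGroups()` compares per-species abundances between two
aggregated sample sides (e.g. vitamin-deficient diets AD/4D4N/7D1N vs
excess diets AE/4E4N/7E1N). Species are tested only when their mean
abundance reaches 0.01% on at least one side. The default test is the
exact two-sided Mann-Whitney U — a nonparametric default suited to
compositional percent data at 15 or so samples per side, switching to
the normal approximation above 20 per side or under ties — with
Welch's t as the parametric alternative. Raw p-values are reported by
default (Benjamini-Hochberg optionally), since headline reports of
this kind typically quote unadjusted values. Fold changes are reported
E over D together with both means and their difference.

# The synthetic-study generator

`studyDesign()` / `generateStudy()` emulate a multi-replicate
diet-variation study: seven groups named by the diet codes (AD, AN, AE,
4D4N, 4E4N, 7D1N, 7E1N) with five replicates each, mirroring the in
vivo layout (six replicates are used where a validation scenario calls
for the in vitro layout). The generative model is:

1. a reference collection of 20 species with 1–7 genomes each,
   per-vitamin prototroph probabilities reflecting typical gut
   communities (0.7–0.95 for most vitamins, 0.5 for B12, i.e. 20–30%
   and ~50% auxotrophy by species), and a strain-heterogeneity rate of
   0.1 under which a prototroph species carries a mixed strain set
   (yielding fractional indices such as 0.25, as in real collections
   where e.g. 1 of 4 *A. muciniphila* genomes encodes the B12
   pathway);
2. one base composition per study drawn from a symmetric Dirichlet
   with concentration 0.5 — heavy-tailed, like real gut profiles;
3. optional injected effects multiplying target species' expected
   abundance in chosen groups before renormalization (ground truth is
   ledgered);
4. per replicate, a composition drawn from a Dirichlet centered on the
   group composition with concentration 500 (replicates seeded from a
   homogenized inoculum are highly reproducible; this is the standard
   overdispersed Dirichlet-multinomial model for 16S replicates), then
   multinomial counts at depth $10^5$ reads, a typical V3–V4 per-sample
   yield.

Setting the concentration to `Inf` removes replicate-level biological
noise (replicates become multinomial draws from the group composition)
and setting the depth to `Inf` gives the noise-free expectation path,
on which profiling output equals the truth ledger to 1e-9 (tested).
Parameter-recovery validation uses `designBaseComposition()` to build
communities whose true auxotrophy fraction for one vitamin is exact,
with `concentration = Inf`, so that recovery error isolates sequencing
noise at the stated depth; exact calibration requires binary species
indices, hence heterogeneity 0 in those designs.

What the generator does *not* emulate: real taxonomic name structure
(names are synthetic), unmapped or family-level phylotypes (all
simulated phylotypes are exact species hits), chimeras and sequencing
error, copy-number variation, and any ecological interaction between
species. Passing tests on synthetic studies therefore validate the
estimator and its calibration, not the upstream 16S processing.

# Worked-example fixtures

`tableFixture("table2")` / `tableFixture("table3")` encode the two
printed 20-species index tables (a humanized gnotobiotic mouse
community and an anaerobic fecal subculture) as full reference
collections plus profiles. Printed fractional indices are expanded
into per-genome binaries deterministically, prototrophs-first: a
species row with $n$ genomes and index $p$ gets $k = \mathrm{round}(p
n)$ prototroph genomes (any ordering gives the same mean, which is all
downstream arithmetic uses). Genus-level rows become genera of
single-genome member species where a flat expansion reproduces the
printed values; two genus rows admit no flat expansion at 2-decimal
precision (no $k/23$ rounds to 0.75, no $k/3$ to 0.5), so their genera
are built from a small species partition — including the table's own
same-genus species rows — with per-vitamin prototroph counts found by
exact enumeration so the hierarchical equal-per-species average
reproduces every printed cell. The family-level row becomes a family
of single-genome genera. Taxonomy above the mapped rank is synthetic
placeholder naming (`fam_<Genus>`), constructed so each row's
neighborhood contains exactly its printed genome count; profile
identities (99/96/92) place each phylotype at its printed rank. The
regression test reproduces all 320 printed index cells after 2-decimal
rounding.

Because the pipeline computes with exact genome fractions (e.g.
181/224 = 0.808) while the printed indices are 2-decimal roundings,
aggregate community percentages can differ from a hand summation over
printed cells by at most $100 \times 0.005 = 0.5$ percentage points;
the test suite checks the pipeline's B12 auxotrophy of the
twenty-species community against the printed-cell hand sum within that
bound, and against an independent naive double-sum oracle to 1e-9.

# Numerical choices and degenerate inputs

* Abundances are converted to fractions on load and renormalized to
  column sum 1 (tolerance 1e-9 in the validity check); reports emit
  percentages, avoiding silent 100-fold errors.
* Weight sums are validated to 1e-12; phenotype indices are clipped of
  float round-off at the $[0,1]$ endpoints, so an all-prototroph
  neighborhood gives auxotrophy exactly 0.
* Indices carry full precision internally; only display output rounds
  (4 decimals in TSVs, 2 in the printed-table convention).
* An empty reference file (header only) loads as an empty collection
  with a warning; duplicate genome ids, non-binary cells and
  inconsistent taxonomy (one species under two genera) are errors
  naming the offending record.
* A profile whose only phylotype is unmapped has mapped fraction 0 and
  an undefined phenotype index (an error, not a silent 0).
* The pipeline is deterministic: identical configurations reproduce
  output files byte-for-byte; randomness exists only in the study
  generator, which requires a seed.

# Validation design and problem sizes

The test suite validates each stage against independent oracles:
brute-force weight enumeration, a scalar double-sum CPI oracle
(agreement to 1e-12), round trips, and the printed-table regression.
Property checks run on 1000 random community instances (conservation,
weight normalization, renormalization validity). Estimator calibration
uses designed auxotrophy fractions {0.1, 0.3, 0.5, 0.75} recovered
within 2 percentage points at depth $10^5$ with 6 replicates, and a
null study (1000 repetitions, 10 species, 15 samples per side) whose
empirical false-positive rate at $p<0.05$ must lie within binomial
error of the nominal level. The power property injects a 2-fold shift
into a species near 3% abundance — detectable but non-dominant, since
shifting a dominant species separates every other species through
compositional closure and creates exact-test ties — and requires it to
rank first by p-value in at least 19 of 20 seeds. These sizes are the
package's validation choices; larger designs only tighten the same
checks.

# Known limitations

* Phenotype precision is bounded by the reference collection: genus-
  and family-level mappings average over heterogeneous neighborhoods,
  and the downgrade fallback trades precision for coverage.
* Exact duplicate strains in a merged reference catalog are not
  detected beyond the genome-id key.
* Compositional effects are not modeled in group comparison (no
  log-ratio transform); a strong shift in one species induces
  anti-correlated shifts in all others.
* Copy-number renormalization inherits the incompleteness of
  copy-number catalogs; it is validated by properties, not against any
  published renormalized table.
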