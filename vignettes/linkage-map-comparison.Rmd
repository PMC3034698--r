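---
title: "Methods: linkage-map construction and cross-species comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage-map construction and cross-species comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkmapr)
```

This vignette is the package's own account of its methods: the statistical
model behind each stage, the conventions and tunable parameters, the design
choices made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## The mapping design

Everything in the mapping stage assumes a **haploid, phase-known design**:
the progeny are haploid males of a single heterozygous queen, so each
individual carries one (possibly recombinant) maternal haplotype and each
biallelic marker call is directly a haplotype state, coded 0/1 with `NA` for
missing. There is no dominance, no second parent, and recombinant counting
is direct. Diploid or outbred designs are out of scope.

### Segregation distortion

Each marker's allele counts are tested against the Mendelian 1:1 expectation
with a 1-df chi-square statistic, *without* continuity correction — on a
(60, 40) split this gives exactly chi2 = (60−50)²/50 + (40−50)²/50 = 4.00.
The star annotation uses the conventional seven thresholds 0.1, 0.05, 0.01,
0.005, 0.001, 0.0005, 0.0001. Distorted markers are annotated but never
excluded from mapping: the independence statistic used for linkage (below)
conditions on both margins of the haplotype table, so marginal distortion
does not masquerade as linkage.

### Two-point linkage

For a marker pair the complete-case individuals form a 2×2 haplotype table.
Mapping is **phase-unknown**: the relative phase is chosen to minimise the
recombinant count, so with cross-class count `c` and same-class count `s`,
R = min(c, s) and θ = R/n ≤ 0.5. The linkage support is the likelihood-ratio
independence statistic G² = 2 Σ O·ln(O/E) (zero cells contribute nothing)
expressed on the LOD scale as G²/(2 ln 10). A pair monomorphic within its
informative subset carries no information and is flagged with LOD 0 and
θ = 0.5. A light consistency pass multiplies the pairwise phase signs along
adjacent ordered triples and counts conflicts; on clean data the count is 0.

### Grouping and ordering

Linkage groups are the connected components of the marker graph with edges
at independence LOD ≥ 5 (components delegated to igraph). Group labels are
deterministic: decreasing size, then smallest marker id.

Ordering re-implements the *described skeleton* of regression mapping as
used by the standard commercial tool for this design — incremental
insertion, a weighted least-squares criterion, and a three-point ripple —
without promising numerical identity with that tool (its internals are not
public). Concretely:

1. Only **usable linkages** (θ < `max_theta` = 0.40 and LOD > `min_lod` =
   1.0) inform the fit; a group that falls apart under this filter is an
   error listing the fragments.
2. The seed is the strongest usable pair; remaining markers are inserted in
   decreasing informativeness (number of usable linkages, then summed LOD,
   then id — the id tie-break keeps runs reproducible).
3. An order is scored by Σ w·(d(θᵢⱼ) − |xᵢ − xⱼ|)² over usable pairs, where
   d is the Kosambi distance, x the cumulative adjacent-Kosambi coordinates
   of the candidate order, and w the pairwise LOD. Each insertion takes the
   gap minimising this criterion over the whole current order.
4. After every insertion a **ripple** slides a window of `ripple_window` = 3
   consecutive markers along the order, tries all 3! permutations of each
   window, scores them on the window plus up to `ripple_neighbors` = 10
   flanking markers on each side, and keeps any strict improvement
   (> 1e−9, so floating-point ties never flip an order).
5. Markers with no usable link to the placed set are deferred and retried;
   `rounds` = 3 passes are made before the leftovers are reported.

Output positions are cumulative Kosambi distances between adjacent markers,
d = 25·ln((1+2θ)/(1−2θ)) cM, with the inverse θ = tanh(d/50)/2 (the round
trip is exact to well below 1e−10). Orientation is normalised so the
lexicographically smaller terminal marker sits at 0 cM. Co-segregating
markers (θ = 0) would produce tied positions; a `tie_jitter` of 1e−6 cM
keeps positions strictly increasing without visibly inflating lengths.

θ values at or above 0.5 have no finite Kosambi distance; wherever an
unusable pair still needs a numeric distance for scoring, θ is capped at
0.4999 (≈ 115 cM), which acts as a large soft penalty rather than an
infinity.

## Map statistics

Three conventions are fixed by validating against the published per-LG
table shipped with the package (all 18 rows reproduce at the printed
precision under exactly these and no simpler alternative):

- **average marker distance = LG length / marker count** (not interval
  count);
- **corrected length = length·(1 + 2/n)**: each chromosome end beyond the
  terminal markers is credited one average spacing, since no flanking
  markers can exist there;
- the **genome-wide average spacing is the unweighted mean of the per-LG
  averages** (sample SD over LGs), and it is the *unrounded* mean that
  feeds the saturation function — feeding the rounded 2-decimal value in
  changes the printed percentage by 0.02.

Genome coverage is 100·observed/corrected. The saturation model
c = 1 − e^(−2md/L) gives the expected proportion of a genome of genetic
length L within d cM of one of m randomly placed markers; its closed-form
inverse is d = −L·ln(1−c)/(2m). The LG-length/marker-count association is
the ordinary Pearson correlation with a two-sided t-test (n−2 df), via
`stats::cor.test`.

A single-marker LG has zero observed length, hence zero average spacing and
zero corrected length; it is kept in the table with a warning rather than
dropped, since dropping it would silently change the totals.

## Genome size and recombination rate

The **anchor estimator** converts one clone's physical-to-genetic scale
into a genome size: Mb = (kb / cM) × total map cM / 1000. With several
anchors, per-anchor estimates and their mean are reported. The
**cytometry estimator** is the product of a bias-corrected DNA-content
ratio and the reference genome's size. Because intercalating stains are
biased towards the AT fraction, the measured ratio needs correcting when
query and reference AT contents differ; no single published arithmetic for
that correction is canonical, and for the validation data none of the
simple models tried (ratio of AT contents, ratio of complements, additive
offsets) reproduces the published corrected ratio from the published AT
contents. The package therefore never invents the arithmetic silently: the
`"proportional"` model (× at_ref/at_query) is offered for exploration, and
the `"fixed"` model applies an externally supplied factor, which is the
honest way to use a corrected ratio taken from the literature. The
recombination rate is the plain quotient cM/Mb, and
`genome_size_consensus()` is the mean of independent estimates.

## The comparative stage

Input is a table of unique best homology hits, one per query marker, with
target LG (or `"Un"` for unassigned sequences), target cM position and
alignment-quality fields.

- **Filtering**: keep a hit iff alignment length > 30 bp AND (score > 45 OR
  identity > 67%), all strict. The published filtering sentence chains the
  three thresholds with an ambiguous conjunction; this reading is the one
  that keeps all three thresholds meaningful (a pure-OR mode is provided
  for sensitivity analysis).
- **Contingency and matching**: mapped filtered hits are cross-tabulated
  query LG × target LG (`"Un"` kept as a column but never counted towards
  assignments). A target LG is an assigned *segment* of a query LG when it
  has ≥ `min_markers` = 3 supporting homologs — the unique small threshold
  that exactly reproduces the published assignment pattern on all 18 rows,
  including the five composites and the three too-small LGs. Composites
  with more than two segments are legal but flagged.
- **Reduction**: both genomes are restricted to the markers with kept,
  assigned hits; query positions are kept un-normalised so spans match the
  full map; the target pseudo-map orders the same markers by target
  position within each target LG.
- **Insertions**: a maximal run of ≤ `max_run` = 2 consecutive markers
  whose target is not among the LG's segments, flanked on *both* sides by
  segment markers, is one insertion event. Terminal (unflanked) and longer
  foreign runs are retained unclassified. The flanked-only rule is adopted
  deliberately: counting terminal runs would over-report insertions
  wherever a translocated block abuts a chromosome end.
- **Synteny**: classified insertion markers are pruned first, so a lone
  foreign marker does not break an otherwise conserved neighbourhood. A
  pair adjacent on the pruned query LG whose hits lie on one common
  assigned target LG is *syntenic* iff the two markers are also adjacent
  among that target LG's shared markers. Per-pair adjacency is
  **orientation-insensitive**, so a fully inverted block contributes
  syntenic pairs; orientation consistency is required only when chaining
  pairs into runs. Same-LG non-adjacent pairs are *rearranged* (the
  signature of within-chromosome inversions and shuffles). Pairs bridging
  two different segments of a composite are `insertion_flank` when the
  interval spans a pruned insertion, otherwise `unclassified`, as are pairs
  touching unclassified foreign markers.
- **Summary**: per LG, syntenic spans on both maps and their ratio, the
  rearranged spans (including `insertion_flank` intervals — their markers
  are on matched chromosomes but not in conserved order), insertion counts
  and the percentages. Percentage denominators are the **corrected** LG
  lengths (validated: 24.692/127.38 = 19.38% on the worked row). A
  rearranged *block* is a maximal run of consecutive rearranged intervals.
  Genome-wide spans are totals over all LGs; genome-wide percentages are
  unweighted means over the LGs with at least one classified homolog pair,
  matching the published table's convention; the genome-wide span ratio is
  the ratio of summed spans.

### Known inconsistencies in the reference tables

`check_reference_tables()` recomputes every derivable cell of the packaged
published tables from the primitive ones and verifies agreement at printed
rounding (±0.01 on cM values and percentages, ±0.005 on ratios, 1e−4 on the
correlation). Four printed figures are not reproducible from the printed
cells and are reported as known inconsistencies rather than failures: the
three span column totals (the printed totals differ from the column sums by
0.09–13 cM; for the rearranged column the running text's total *is* the
true cell sum) and the span-ratio mean (the printed 0.45 is neither the
mean of the per-LG ratios, 0.73, nor the ratio of the summed spans, 0.44).
Similarly, the published map-length increase over the predecessor map
(271.21 cM) differs from the printed subtraction by 0.1 cM and is not
reproduced. One corrected-length cell follows the rounded-average
convention where the other seventeen follow the unrounded one; it still
agrees within the 0.01 tolerance.

## The synthetic-data generator

The generator produces every input the analysis consumes, with a replayable
truth log. Its **defaults are the study conditions** of the system the
package was validated on: 18 LGs of 29 uniformly spaced markers over 106 cM
(≈ 516 markers, ≈ 1900 cM), 384 genotyped haploid males, 47% of markers
with a homology hit of which 6% hit unassigned target sequences, and a
rearrangement dose of 5 reciprocal translocations and 21 short
transpositions (the observed composite and insertion counts) plus 12
inversions (the within-chromosome shuffling is abundant in the real
comparison but its event count is unobservable; a dozen inversions
reproduces a comparable rearranged fraction). Genotyping error defaults to
0.5% and missingness to 10%, typical for semi-automated SSR scoring.

Crossovers follow either a **Poisson** process (rate 1 per 100 cM, no
interference — Haldane-consistent and analytically checkable: two markers
10 cM apart recombine with probability (1−e^(−0.2))/2 ≈ 0.0906) or a
**stationary gamma renewal** process (shape `gamma_nu`, mean spacing 100
cM, burnt in from outside the chromosome) for positive interference, which
is the norm in these genomes. Transmission distortion is applied by
one-sided flips towards the configured probability, which preserves the
linkage structure rather than redrawing calls. All randomness flows from
the single mandatory seed (the genome, progeny and anchor stages use
`seed`, `seed+1`, `seed+2` so the draws are separate but jointly
deterministic).

What the generator does **not** emulate — and hence what passing recovery
tests do and do not show: marker ascertainment bias and heterogeneous
informativeness, non-uniform marker spacing, position-dependent genotyping
error, segmental duplications producing multi-hit homology (hits are unique
by construction), and map-function mismatch beyond the built-in one
(estimation uses Kosambi while the Poisson model is Haldane-consistent;
the resulting few-percent length bias is tolerated by the ±5-percentage
point bands of the recovery tests). Recovery results on synthetic data
bound algorithmic correctness, not field performance.

## Validation strategy and problem sizes

The marker-level data behind the published comparison are not
machine-readable, so the suite validates in two layers: (i) every derivable
cell of the published summary tables is recomputed from primitives, and
(ii) property-based tests on seeded synthetic data check the algorithms
where no published oracle exists — an exhaustive-enumeration ordering
oracle (groups of 7, all 5040 orders, 50 replicates, ≥ 90% agreement up to
reversal), an adjacency-enumeration synteny oracle (100 random ≤ 8-marker
groups, exact agreement), noiseless order recovery (10-marker groups,
n = 500, 50 seeds, |Kendall τ| = 1 in ≥ 95%), and end-to-end
planted-rearrangement recovery (6-LG genomes of 12 markers, n = 384, 0.5%
error, 20 seeds: exact LG-partition recovery, exact insertion-count
recovery on transposition-only genomes, genome synteny fraction within 5
percentage points of the truth-derived value). These sizes keep the whole
suite under half a minute while leaving each property's sampling error far
below its assertion margin; the generator's *defaults* remain the
study-scale conditions above.

## Limitations

- Ordering is heuristic (greedy insertion + ripple); for pathological LOD
  surfaces the exhaustive oracle shows occasional metastable orders even on
  clean data, which is why the agreement bound is 90%, not 100%.
- No multipoint maximum-likelihood mapping, no interference estimation from
  data, no confidence intervals on map length.
- The comparative stage classifies marker *adjacencies*; it cannot place
  rearrangement breakpoints between markers, and spans are bounded by the
  outermost homologous markers.
- The AT-bias correction is a model choice, not a measurement; results
  based on the `"fixed"` model are only as good as the supplied factor.
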