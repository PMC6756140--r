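---
title: "Methods: pseudo-testcross mapping, scaffold anchoring and genome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-testcross mapping, scaffold anchoring and genome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draftmap)
```

# Overview

`draftmap` implements the computational core of a linkage-assisted draft
genome project for an obligately outcrossing plant: building a genetic map
from a single open-pollinated maternal plant and its full-sib families,
anchoring assembly scaffolds to the resulting linkage groups, comparing
those groups against the pseudochromosomes of a better-assembled relative,
selecting SNP capture probes from assembler bubbles, and profiling genome
size and heterozygosity from k-mer spectra.  Every analysis can be driven
end to end by the built-in simulator, which generates pedigrees with the
statistical structure the methods assume.

This vignette records the models, the parameters that matter, the numeric
choices, and the places where the design was genuinely open.

# The pseudo-testcross design

In an outbred, highly heterozygous species neither parent is inbred, so
classical mapping populations are unavailable.  The pseudo-testcross
exploits loci where exactly one parent is heterozygous (Aa x aa): offspring
segregate 1:1 heterozygote : homozygote, so each such marker behaves like a
backcross marker for the informative parent, and the two parents can be
mapped separately.  Two marker sets are used:

* **Maternal testcross set** (whole cohort): loci where the genotyped
  mother is heterozygous and every (unsampled) pollen donor is homozygous
  for the same allele.  Because the fathers were never genotyped, the
  paternal condition is verified from the offspring themselves: the
  non-missing offspring calls must fall into exactly the two classes of an
  Aa x aa cross -- any third class rejects the locus.  Thresholds: minor
  genotype class at least 24 across the cohort, at most 30% missing, and a
  Phred confidence mask at 15.
* **Sibling set** (one full-sib family of 22): loci where exactly one
  parent is heterozygous.  A heterozygous mother with testcross-segregating
  sibs gives a maternal marker; a homozygous mother whose sibs segregate
  into her class plus heterozygotes implies a heterozygous father
  (paternal marker).  Loci with three classes (both parents heterozygous)
  are dropped.  Thresholds: minor class at least 5, at most 4 missing,
  Phred mask at 20.

The Phred confidence mask retains a call only when both non-called
genotypes in the normalised likelihood triplet are at or above the
threshold, i.e. one genotype is clearly most probable and both alternatives
clearly are not.  Masked calls become missing; call values are never
changed.

# Two-point linkage and clustering

For two same-parent testcross markers scored in `n` shared offspring with
`k` phase-discordant pairs under coupling, the phase minimising the
recombinant count `k*` is chosen and

* `rf = k*/n`
* `LOD = k* log10(rf) + (n - k*) log10(1 - rf) + n log10 2` (with
  `0 log 0 = 0`),

the base-10 log likelihood ratio of linkage at the maximum-likelihood `rf`
against free recombination.  Markers of different parental classes are
mutually uninformative (`rf = 0.5`, `LOD = 0`): maternal and paternal maps
are built separately by construction.

Linkage groups are single-linkage components: transitive closure over
pairs with LOD at or above the threshold (8.4 for the core map; 6.1, 6.0,
5.5 for the sibling ladder).  Two guards shape the graph:

* Pairs sharing fewer than `min_informative` (default 10) scored offspring
  have their LOD forced to 0, preventing chains through sparsely covered
  pairs.  This floor subsumes the "safe marker" notion of conventional
  two-point pipelines and is configurable.
* No recombination-fraction ceiling is applied; the LOD threshold is the
  sole criterion.

With 22 offspring the maximum attainable LOD is `22 log10 2 = 6.62`, and a
single recombinant already caps a pair below 6.0; at the sibling thresholds
the linkage graph therefore consists exactly of zero-recombinant pairs with
at least 20 shared calls.  The implementation detects this regime and
switches from the blocked dense scan to an exact hash join over
missing-pattern supersets, which makes desk-scale sibling analyses (tens of
thousands of markers) tractable.  The two strategies are verified against
each other in the test suite.

Map distances use the Kosambi function `d = 25 ln((1 + 2r)/(1 - 2r))` cM,
which admits partial crossover interference.  Marker order within a group
is a heuristic: nearest-neighbour chaining seeded from the tightest pair,
then 2-opt reversals until no swap reduces the sum of adjacent `rf`.  Exact
optimality is only guaranteed where 2-opt reaches the optimum (small
groups); orientation is canonicalised by the lexicographic order of the
terminal marker ids.

# Perfect-linkage consolidation and scaffold anchoring

Markers with identical segregation vectors on the same scaffold are merged
first ("identical" includes the missing pattern; no imputation is
performed).  Across scaffolds, only complete vectors merge, and both
identical and complementary vectors qualify -- complementary complete
vectors are the two phases of one segregation pattern.  Each bin carries
the union of its scaffolds.

Anchoring then combines three inputs: core linkage-group labels of
scaffolds (from the whole-cohort map), the bins, and sibling clusterings at
the LOD ladder 6.1, 6.0, 5.5.  For each ladder step, two vote-ratio rules
are applied repeatedly until no new scaffold is assigned:

* **Bin rule** (ratio 3): within a bin, if the most common core label is at
  least three times as common as the runner-up, unassigned member
  scaffolds adopt it.
* **Group rule** (ratio 10): the same over the scaffolds of each sibling
  cluster.

A missing runner-up counts as zero votes, so unanimous evidence always
passes -- a strict reading of the ratio would forbid every unanimous
assignment, which cannot be intended.  Exact ratio equality passes (the
rule is read as "at least"); top-count ties assign nothing and are logged
as conflicts.  Assignments accumulate across steps, core labels are never
overwritten, and nothing is ever revoked.  Within a sweep the bin rule runs
before the group rule; the fixpoint does not depend on this order (tested),
only the conflict log may differ.  Whether the original procedure iterated
to a fixpoint within each ladder step or made one pass is not documented
anywhere we could follow; fixpoint iteration was chosen because it makes
the result order-invariant and idempotent, both of which are tested.

# Macrosynteny comparison

Scaffolds anchored to linkage groups are compared against a reference
relative through a best-hit table (one pseudochromosome position per
scaffold; the sequence alignment producing it is outside this package).
The count matrix tallies scaffolds per (linkage group, pseudochromosome)
cell.  A group and a pseudochromosome are declared a one-to-one pair when
each is the unique argmax of the other and the shared cell exceeds half the
group's hits.  The dominance fraction operationalises "most of the
scaffolds map there"; it is explicit and configurable because the
underlying notion is qualitative.

For each pair, one marker is selected per 1-Mbp window of the
pseudochromosome (most complete first, then leftmost), the group is ordered
on the genetic map, and the dot series (physical bp, cumulative Kosambi cM)
is decomposed into maximal strictly monotone runs.  Monotone runs --
increasing or decreasing, since the map orientation is arbitrary -- are the
signature of conserved marker order; run boundaries mark rearrangement
breakpoints at the map's resolution.

# Probe selection from assembler bubbles

De Bruijn assemblers emit "bubbles" where a heterozygous site splits the
graph; each bubble is a candidate hybridization probe tagged by its SNP.
The pipeline:

1. **Dedupe**: single-linkage clusters at >= 90% global pairwise identity
   (exact Needleman-Wunsch; identity is matches over alignment columns) are
   removed wholesale.  Near-identical bubbles usually reflect repeats, not
   single heterozygous loci, so no representative is kept; this reading of
   the original clustering step is ambiguous and the behaviour is
   configurable through the identity threshold.
2. **Tiered selection** under a per-scaffold quota (1 for scaffolds under
   10 kbp, 2 otherwise) and a global cap of 20,000: tier 1 takes bubbles
   mapping uniquely at >= 90% identity; tier 2 those mapping to at most 4
   locations at >= 90%; tier 3 those mapping to at most 3 locations at
   >= 95%.  Tiers fill in order under deterministic within-tier ordering
   (scaffold id, SNP offset, id), so the output is independent of input
   order.
3. **Trimming** to 80 bp centred on the SNP (SNP at window index
   `floor(80/2)`), shifting the window to stay inside the sequence near the
   ends; shorter sequences are returned whole and flagged.  The off-by-one
   side of "centred" is not determined by the original description; the
   floor convention is fixed here.

# K-mer genome profiling

A diploid read set yields a bimodal k-mer depth histogram: homozygous
regions contribute one species at full depth, heterozygous regions two
species at half depth, and sequencing errors pile up at depth ~1.  With
per-base heterozygosity `h` and k-mer length `k`, the fraction of k-mer
loci overlapping a heterozygous site is `q = 1 - (1 - h)^k`.

Peak finding smooths the counts (centred moving average, window 5; the raw
series has jitter that fakes minima), takes the first local minimum after
depth 1 as the error valley, the global maximum of depth x smoothed count
beyond the valley as the homozygous peak (depth-weighting stops the taller
half-depth peak from capturing the argmax), and the local maximum nearest
half the homozygous depth -- searched within 25% of that half-depth and
above 5% of the main peak's height -- as the heterozygous peak.  Without a
qualifying heterozygous peak, heterozygosity is reported as 0.

The estimator is a transparent two-component assignment: genome size is the
k-mer instance mass beyond the valley divided by the homozygous depth;
species between the valley and the midpoint of the two peaks are assigned
to the heterozygous component, giving the species fraction
`f = 2q / (1 + q)`, inverted to `q = f / (2 - f)` and
`h = 1 - (1 - q)^(1/k)`.  This is deliberately simpler than full
mixture-model profilers; published headline figures from such tools are
model-dependent and are not reproduction targets here.  The test surface is
recovery on simulated spectra (size within 10%, heterozygosity within 25%,
heterozygous peak at half the homozygous depth within 20%).

# The simulator and the study conditions

`simulate_pedigree()` emulates the motivating study design: one heterozygous
maternal plant, open-pollinated; each fruit is sired by a single pollen
donor, so offspring form full-sib families (defaults: 96 offspring in six
families, the largest of 22, up to six fathers).  The karyotype default is
11 chromosomes (the gametic number of the species group at hand, shared
with its reference relative).

Choices a user should know about, with defaults and why:

* **Crossover model**: Haldane (Poisson crossover count with mean map
  length in Morgans, uniform placement, no interference).  Distances are
  *reported* with Kosambi throughout the mapping code; the simulation
  model is chosen for independence of disjoint intervals, which the
  calibration tests rely on.  At the short distances that drive clustering
  the two functions differ negligibly.
* **Genetic length**: 60 cM per chromosome -- a plant-typical value above
  the one-obligate-crossover floor of 50 cM.
* **Physical scale**: 5 Mbp per chromosome with 20-100 kbp scaffolds tiled
  without gaps.  Physical size only affects scaffold bookkeeping, so it is
  scaled down from a real genome while marker counts are kept realistic.
  Real assemblies also carry unplaced sequence, which is irrelevant to the
  algorithms under test.
* **Genotype observation model**: calls are flipped to a uniformly chosen
  other genotype with probability 0.02 and masked missing with probability
  0.10 (the enriched-library regime the filters were designed for).
  Phred-scaled triplets come from a Poisson(20) read-depth, binomial
  allele-read model with 1% base error, normalised so the emitted call has
  PL 0.  Reads are generated conditional on the emitted call, so likelihood
  triplets are consistent with their genotype and the confidence mask does
  not silently remove the simulated errors.  Per-offspring depth of the
  original enriched libraries is not documented; `mean_depth` is a free
  parameter.
* **Marker density** is per-analysis, not a generator default.  The core
  map uses a density retaining roughly 700 maternal-testcross markers after
  filtering (the motivating study retained thousands; 700 keeps adjacent
  markers ~1 cM apart, far inside the ~20 cM chaining radius of LOD 8.4 at
  n = 90).  The sibling analysis uses a much higher density (1,300 markers
  per Mbp before filtering).  This is deliberate: with 22 offspring a
  chromosome is cut into ~14 segments per parent by the family's
  crossovers, adjacent segments can only chain through markers whose
  missing calls cover the recombinant individual, and the original
  sibling set was an order of magnitude denser still.  The density was set
  so that the expected number of unchained segment boundaries is well
  below one per study, which is the regime the published design operated
  in.

What the simulator does **not** model: read-level sequencing of the
pedigree, mapping or reference bias, segregation distortion, correlated
missingness (bad samples/loci), and crossover interference.  Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every artefact of real data.

## What the seeded design-recovery runs show

Clustering the filtered maternal-testcross set at LOD 8.4 yields exactly
the configured 11 chromosome groups across seeds.  The single-family
sibling analysis at LOD 6.0 yields close to 22 substantial groups (two per
chromosome: one maternal, one paternal), but the count is genuinely
stochastic at n = 22: a chance near-collision of two segregation patterns
(Hamming distance <= 2 across 22 sibs) bridged by missing calls merges two
groups, and an uncovered recombination boundary splits one.  Both events
have expectation of order one per simulated study.  The acceptance script
therefore reports the median of five independent replicates for this
count, which is the package's own measurement protocol for a noisy
integer-valued design property.

Problem sizes used by the bundled checks: 11 chromosomes x 5 Mbp; 90
offspring and ~3,500 raw markers for the core map; 22 offspring and ~70,000
raw markers (~43,000 consolidated bins) per sibling replicate; 10,000
probe candidates; 1 Mbp genomes at 84x for k-mer recovery.

# Known limitations

* Marker ordering is locally optimal only; long groups may retain 2-opt
  artefacts.
* The anchoring vote rules trust core labels entirely; a wrong core label
  propagates (mitigated by the ratio thresholds and the conflict log).
* The probe dedupe step is quadratic in candidate count and intended for
  desk-scale inputs; production-scale deduplication belongs to dedicated
  clustering tools.
* K-mer counting holds all k-mers in memory; it is exact but sized for
  test genomes, not sequencing runs.
* Intercross (both-parents-heterozygous) loci, multipoint likelihoods and
  sex-averaged maps are out of scope.
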