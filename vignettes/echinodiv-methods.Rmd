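---
title: "Methods: multi-marker diversity analysis for barnyard grass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-marker diversity analysis for barnyard grass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echinodiv)
```

`echinodiv` quantifies diversity of *Echinochloa* (barnyard grass)
populations across four evidence streams — quantitative traits, DNA
barcodes, dominant SCoT bands, herbicide resistance — and measures how the
streams agree. This vignette is the package's account of the statistics it
implements, the choices made where the methodology was genuinely open, and
what the synthetic study generator does and does not emulate.

## Trait diversity and clustering

Inputs are per-population means of nine quantitative traits, M1–M9 (leaf
length, leaf width, panicle length, raceme length, awn length, spikelet
length, first-glume/spikelet ratio, stem diameter, plant height;
centimetres except the dimensionless ratio M7). For each trait the package
reports range, max, min, mean, the *sample* standard deviation *s*
(*n* − 1 denominator, matching the defaults of the desktop statistics
packages this workflow descends from) and CV = 100·*s*/*x̄*.

Diversity uses the Shannon–Wiener index in nats, H′ = −ΣPᵢ ln Pᵢ, over ten
trait levels centred on the mean: level 1 collects values below
*x̄* − 2*s*, level 10 values at or above *x̄* + 2*s*, and eight half-open
intervals of width 0.5·*s* fill the middle. All bin edges belong to the
upper bin (`[lo, hi)`), consistent with the "≥" convention of the top
level. A trait with zero spread has no meaningful bins; `assign_levels()`
errors rather than inventing them, and `diversity_table()` can drop such a
trait with a warning (`drop_degenerate = TRUE`). H′ is maximal at ln 10 ≈
2.303 for a uniform level distribution and zero when one level holds all
populations.

Traits are z-scored per column (`standardize_traits()`, which is idempotent
and therefore does not enforce the raw-scale validity checks of the
readers) and clustered with Ward's minimum-variance method. Heights follow
the Lance–Williams recurrence on squared Euclidean distances; the optional
`rescale = TRUE` maps them affinely onto the 0–25 axis familiar from SPSS
dendrograms (h → 25·h/max h), because published cut values such as 15.0 are
expressed on that axis. `cut_dendrogram()` groups leaves connected by
merges *strictly below* the threshold, so a cut at 0 isolates every sample
even when exact duplicates merge at height 0, and cluster counts are
monotone non-increasing in the threshold. Cluster labels are consecutive
integers numbered by first appearance in input row order — deterministic
and insensitive to how the clustering library happens to order merges.

## Herbicide multi-resistance

Resistance is called from whole-plant fresh-weight inhibition,
100·(1 − treated/control), clamped at 0 when treated plants outgrow
controls; a biotype is resistant to a herbicide when inhibition is
*strictly below* 78%. Multi-resistance is the number of distinct herbicide
sites of action (SOAs) with at least one resistant call, so duplicating a
herbicide within a mechanism class never inflates it; the count of
resistant herbicides is also reported and can be selected instead
(`measure = "herbicide"`). The default map assigns the six assay herbicides
HRAC/WSSA-style classes — ACCase (metamifop, cyhalofop-butyl), ALS
(penoxsulam, pyribenzoxim), PSII (propanil), synthetic auxin (quinclorac) —
and is a config input, since mechanism grouping is a scientific choice, not
a property of the data.

Trait–resistance association uses Pearson correlation with a two-sided
p-value from the t distribution on *n* − 2 df. A zero-variance vector
yields a missing r rather than an error, so one flat trait cannot abort a
screen.

## DNA barcodes

A site of an aligned locus is *variable* when at least two distinct
unambiguous bases (A/C/G/T) occur among the samples; gaps, N and IUPAC
ambiguity codes are ignored at that site. When a reference accession
accompanies the alignment, positions are also reported in the reference's
ungapped 1-based coordinates (the convention of GenBank-anchored SNP
figures). The *haplotype* of a sample is its full vector of states at the
variable sites; haplotype classes, numbered by first appearance, are the
barcode cluster assignment. Concatenating loci (identical sample sets
required) can only refine this partition — a property the tests assert.

K2P distances, d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q) with transition and
transversion proportions P and Q, are computed with *pairwise* deletion:
each pair is compared over the sites where both carry unambiguous bases.
Pairwise deletion preserves information in short barcodes compared with
complete deletion; either is defensible and the choice is declared, not
inferred. When a log argument is non-positive the pair is *saturated*: the
distance is reported as `NA` and flagged, never clamped to an arbitrary
large value, and tree building refuses matrices containing such pairs.

Neighbor joining follows Saitou–Nei with the Studier–Keppler Q criterion.
Among tied minimal pairs the lexicographically smallest pair of current
node indices is chosen, so even an all-equal matrix yields a deterministic
tree. Negative branch estimates (possible on non-additive input) are
clamped to zero with the deficit moved to the sibling edge, preserving the
path length between the joined nodes; on additive matrices the algorithm
is exact, which the tests verify against every 4- and 5-taxon topology and
against an independent NJ implementation. Bootstrap supports resample
alignment columns with replacement; replicate *r* draws from a
deterministic substream derived from `(seed, r)`, so supports are
reproducible and do not depend on sample order. Supports annotate the
bipartitions of the *original* topology (no consensus tree is built), as
integer percentages of replicates.

## SCoT dominant markers

A band locus is polymorphic when both presence and absence occur among the
samples. PIC treats a dominant 0/1 locus as two observable allele classes,
presence at frequency *p* and absence at 1 − *p*:
PIC = 1 − *p*² − (1 − *p*)², symmetric in *p* and maximal (0.5) at
*p* = 0.5. No Hardy–Weinberg back-estimation of the recessive allele
frequency is attempted — it is the simplest reading of the standard formula
for dominant data, and the choice is isolated in `pic_locus()`. Per-primer
PIC averages over *polymorphic* loci by default, since monomorphic loci
contribute exactly 0 and would dilute the informativeness measure;
`pic_include_monomorphic = TRUE` switches to averaging over all loci.
Published per-primer PIC values cannot be reconstructed from printed
average allele frequencies at all (the formula applied to the printed
frequency gives a different number), so only column aggregates of printed
PIC values are ever checked.

Simple-matching similarity counts agreement at *all* scored loci, shared
absences included — monomorphic loci contribute, because the coefficient
compares whole binary profiles. 1 − SM is a scaled Hamming distance (hence
a metric), and UPGMA on it yields an ultrametric dendrogram cut at a
dissimilarity threshold with the same strict-below, first-appearance
labelling as the trait dendrogram.

## Cross-marker concordance

Each method's clusters are encoded as integers in a fixed shared sample
order and correlated pairwise (Pearson, two-sided t on *n* − 2 df).
Pearson-on-labels is *not* invariant to how cluster ids are numbered; the
first-appearance convention makes the raw value reproducible, and an
exhaustive relabeling-maximized r (over at most 6! label permutations of
one member of each pair) is reported as a diagnostic upper bound. Raw r
remains the primary output. Adjusted-Rand-style statistics are deliberately
out of scope as primary outputs.

One calibration subtlety: under a *permutation* null (one labeling fixed,
the other permuted), the p-value support is a small finite set — at
*n* = 50 with five groups roughly forty distinct values — because r depends
only on the contingency table. The distribution is close to uniform
decile-by-decile, but a plain Kolmogorov–Smirnov test is anticonservative
on such ties. The calibration tests therefore simulate the null by drawing
two *independent* random labelings per replicate, which mixes the discrete
supports into an effectively continuous one.

## The synthetic study generator

`paper_like_config()` is the single place where the emulated study
conditions live: 46 populations in five groups of 12/13/9/3/9 (an
unbalanced field collection); loci ITS (588 bp), *psbA* (337 bp), *matK*
(1312 bp) and *trnL-F* (954 bp) with 5/2/2/1 planted haplotypes and
5/2/1/0 variable sites; 72 band loci over six primers (12/13/9/15/12/11
bands, 62 polymorphic); and six herbicides over four SOA classes.

* **Traits** are drawn from group-specific normal archetypes, truncated to
  valid ranges. Archetype means are anchored on the published cluster
  descriptions (group 1: 89.13 cm mean height, 39.0 cm leaves; group 2:
  26.6 cm leaves; group 3: 0.66 cm stems; group 4: 0.81 cm awns; group 5:
  43.35 cm height, 0.29 cm stems). Within-group SDs are set so that the
  *pooled* per-trait dispersion matches the published trait table while
  the non-awn marginals remain unimodal enough to pass normality checks,
  as the field data did; that deliberately places only part of the
  variance of the minor traits between groups, so trait clustering on the
  default config is imperfect — just as the field study's morphological
  clusters only weakly matched its genetic groups. Awnless groups are
  truncated at zero, reproducing the zero-inflated, non-normal awn-length
  distribution the field data show. `trait_sd_scale` shrinks or inflates
  all within-group SDs; at 0.35 the archetypes are separated by far more
  than 3 pooled SDs and Ward clustering recovers the groups, which is how
  the conditional recovery property is tested.
* **Barcodes** are a seeded random reference per locus with planted
  group-specific transitions; within-group sequences are identical, making
  groups exact haplotype classes. Nuclear ITS follows the five main
  groups; the chloroplast loci follow a two-level *plastid* grouping that
  deliberately crosses the nuclear one (plastid type 2 occurs only inside
  nuclear groups 4 and 5), so the ITS × psbA combination realises exactly
  seven combined haplotypes while remaining a refinement of both
  single-locus partitions.
* **Bands** are group profiles XOR symmetric Bernoulli(0.02) flip noise.
  Noise applies only to the planted-polymorphic loci: scoring error arises
  at faint variable bands, and leaving the ten invariant strong bands
  noise-free keeps the observed polymorphism rate at the emulated 62/72
  condition. Random group profiles put between-group SM dissimilarity
  around 0.4 and within-group around 0.04, so the synthetic SCoT cut of
  0.30 sits cleanly between the two scales; the published-data threshold
  0.62 reflects that survey's stronger profile divergence and remains the
  documented replication setting for real data.
* **Resistance** draws each population's SOA count from a binomial whose
  logit is linear in the z-scored coupled traits (leaf length M1 and
  spikelet length M6, coupling 1.5 by default — strong enough for a clear
  positive correlation at n = 46; coupling 0 gives the null), then
  translates resistant/susceptible classes into fresh weights with
  inhibition uniform on 20–70% or 85–100%.

Each component draws from its own substream derived from the master seed,
so identical configs and seeds give byte-identical files and adding a
generator never perturbs the draws of an earlier one.

What the generator does **not** emulate: within-group sequence variation
(available via stress-test mutation only through custom configs), linkage
among bands, coalescent realism, measurement replicates, environmental
covariates, or any geography. Passing tests on synthetic data therefore
demonstrate the *pipeline's* correctness under known truth, not the
biological fidelity of any particular field survey.

## Problem sizes and numerical conventions

The test suite runs the full synthetic study across 20 seeds, checks NJ
exactness on all 4- and 5-taxon topologies, compares Ward/UPGMA with a
naive Lance–Williams recomputation at n ≤ 8, verifies K2P against
brute-force substitution counting on 200-bp pairs, and calibrates p-values
with 500-replicate simulated nulls at n = 50 — sizes chosen to exercise
every code path with comfortable statistical resolution. Numerical
conventions throughout: coordinates are 1-based inclusive; CSV is
comma-separated UTF-8 with '.' decimals and mandatory headers; FASTA input
must be pre-aligned (the package never aligns); Newick output quotes leaf
names containing metacharacters and writes bootstrap supports as integer
internal-node labels; branch lengths round-trip to 1e-6; equality
tolerances in invariants are 1e-9 unless a formula is exact.

## Known limitations

Pearson-on-labels concordance inherits the label-numbering sensitivity
discussed above; the diagnostic bounds it but cannot recover how any
particular published analysis numbered its clusters, so published
cross-marker correlation values are not reproducible targets. Dominant
markers cannot distinguish heterozygotes, so PIC here is an
informativeness index, not an estimate of expected heterozygosity under
Hardy–Weinberg. Saturated K2P pairs stop tree building by design; highly
diverged inputs need a different substitution model, which is out of
scope. The SPSS-style 0–25 rescaling is an affine convenience for applying
published cut heights, not a calibrated genetic distance.
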