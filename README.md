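# echinodiv

Multi-marker diversity analysis for barnyard grass (*Echinochloa* spp.)
populations.

Barnyard grass is the dominant weed of paddy rice and a frequent carrier of
herbicide resistance. Field surveys typically characterise its populations
with several complementary marker systems at once — quantitative
morphological traits, DNA barcodes (nuclear ITS and the chloroplast loci
*psbA*, *matK*, *trnL-F*) and dominant SCoT (start codon targeted) band
markers — and then ask how well the systems agree and whether morphology
tracks herbicide multi-resistance. `echinodiv` implements that entire
workflow as composable, tested R functions for weed scientists and
population geneticists, together with a synthetic-study generator so every
stage can be exercised against known ground truth.

## The statistics at the core

* **Trait diversity.** For each quantitative trait the usual Range / Max /
  Min / Mean / *s* / CV table, with CV = 100·*s*/*x̄* (sample SD, *n*−1),
  plus the Shannon–Wiener index H′ = −Σ*P*ᵢ ln *P*ᵢ over ten trait levels:
  level 1 below *x̄* − 2*s*, level 10 at or above *x̄* + 2*s*, and eight
  half-open 0.5 *s* steps between. Standardized traits are clustered with
  Ward's minimum-variance method on Euclidean distances; heights can be
  rescaled to the 0–25 axis on which published cut values (e.g. 15.0) are
  expressed.
* **DNA barcodes.** Variable sites (unambiguous bases only, with optional
  reference-accession coordinates), haplotype groups as equivalence classes
  of variable-site vectors, Kimura 2-parameter distances
  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q) with pairwise deletion and explicit
  saturation flags, Saitou–Nei neighbor-joining with deterministic
  tie-breaking, column-bootstrap supports, and multi-locus concatenation
  (which can only refine haplotype groups).
* **SCoT bands.** Polymorphism rates of 0/1 band matrices, polymorphism
  information content PIC = 1 − Σ*p*ᵢ² per dominant locus, simple-matching
  similarity SM (shared presences *and* absences), and UPGMA clustering of
  1 − SM cut at a dissimilarity threshold.
* **Resistance.** Fresh-weight inhibition 100·(1 − treated/control), the
  strict `< 78 %` resistance call, multi-resistance as the number of
  distinct herbicide sites of action (SOAs) with a resistant call, and
  Pearson correlation of traits with the multi-resistance count.
* **Concordance.** Each method's clusters are encoded as integers 1..k (by
  first appearance in a shared sample order) and correlated pairwise
  (Pearson, two-sided t-test on *n*−2 df), with a relabeling-maximized r as
  a robustness diagnostic.

## Worked example

```r
library(echinodiv)

study  <- simulate_study(paper_like_config(seed = 42))
report <- run_study(study = study, scot_cut = 0.30)
report$summary
#> # A tibble: 7 × 4
#>   method   n_samples n_groups   cut
#>   <chr>        <int>    <int> <dbl>
#> 1 MT              46        2  15
#> 2 ITS             46        5  NA
#> 3 psbA            46        2  NA
#> 4 matK            46        2  NA
#> 5 trnL-F          46        1  NA
#> 6 ITS+psbA        46        7  NA
#> 7 SCoT            46        5   0.3
```

The simulated 46-population study behaves like the real survey: ITS
resolves the five planted groups, the chloroplast loci see only two
maternal lineages, the invariant *trnL-F* is useless on its own, combining
ITS with *psbA* refines the partition to seven groups, and the SCoT cut
recovers the five groups again.

```r
tidy(report$concordance)
#> # A tibble: 3 × 6
#>   method_a method_b     r       p sig   r_max
#> 1 MT       ITS      0.384 0.00837 **    0.925
#> 2 MT       SCoT     0.384 0.00837 **    0.925
#> 3 ITS      SCoT     1     0       **    1
```

Morphology only partly tracks the genetic groups (r ≈ 0.38 against either
molecular marker here) while the two molecular systems agree — the same
qualitative pattern the field data show. The `r_max` column bounds how much
of the disagreement is mere label numbering.

The published per-trait summary ships with the package, and its printed
aggregates are reproduced by the same code path used for fresh data:

```r
trait_summary_aggregates(published_trait_summary())
#> # A tibble: 1 × 7
#>   n_traits mean_cv min_cv max_cv mean_h min_h max_h
#> 1        9    44.0    11.7   222.   1.69  0.69  2.06
```

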