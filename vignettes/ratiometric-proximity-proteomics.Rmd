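---
title: "Methods: ratiometric proximity proteomics, enrichment testing and contact-site geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric proximity proteomics, enrichment testing and contact-site geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiomap)
```

## The analysis problem

Proximity biotinylation with an engineered peroxidase (APEX2) tags proteins
within a few nanometres of wherever the enzyme is anchored. For *open*
compartments facing the cytosol — the outer mitochondrial membrane (OMM) or
the cytosolic face of the ER membrane (ERM) — the labeling radius alone is
not enough: abundant cytosolic proteins are tagged too. The ratiometric
design solves this with a three-state SILAC experiment. Heavy (H) cells
express the targeted construct, medium (M) cells express a cytosol-targeted
construct, and light (L) cells are an untagged/untreated control. Two
channel ratios then carry complementary information for each protein *g*:

* `log2(H/L)` — the *extent* of specific biotinylation over background;
* `log2(H/M)` — the *spatial specificity*: targeted relative to cytosolic
  labeling.

A protein enters the final spatial proteome only if both quantities clear
data-derived cutoffs in both biological replicates. `ratiomap` implements
that calling procedure, the annotation-based quality metrics around it, a
moderated one-sample t-test for isobaric-tag (iTRAQ) co-IP enrichment, and
a geometric quantifier of mitochondria–ER contacts in traced electron
micrographs, together with seeded generators that produce inputs with known
ground truth for all three.

## Detection filtering and reference normalization

Protein groups flagged as contaminants or reverse-database hits are
removed, and a protein counts as *detected* only with at least two unique
sequenced peptides (`filter_detected()`, boundary 2 inclusive). Raw,
unnormalized SILAC ratios are then anchored on a reference subset of
soluble mitochondrial matrix proteins: for each ratio kind independently,
the median raw ratio over detected reference members is computed, every
protein's ratio is divided by it, and the quotient is log2-transformed
(`normalize_to_reference()`). Two consequences are worth stating
explicitly:

* the median of the reference members' normalized log2 ratios is exactly 0
  (the package's invariant tolerance is 1e-9; the arithmetic is exact up to
  floating point), and
* the transform is scale-equivariant — a global multiplicative offset in
  any channel (mixing error, labeling efficiency) cancels.

The median of an even-sized reference subset is the midpoint of the two
central values, the standard definition. M/L ratios are normalized the same
way and carried through for reporting and QC scatter plots only; no filter
consumes them. Only proteins with both H/L and H/M ratios present in both
replicates enter the cutoff analysis (`join_replicates()`); missing cells
are preserved as missing from parsing onward and are never coerced to zero.

## ROC cutoff selection

Cutoffs are chosen per replicate and per ratio axis from curated classes:

| proteome | axis | true positives | false positives |
|---|---|---|---|
| OMM | H/L | curated OMM list | matrix reference list |
| OMM | H/M | curated OMM list | complement of mitochondrial annotation |
| ERM | H/L | curated ERM list | matrix reference list |
| ERM | H/M | curated ERM list | complement of the curated ERM list |

Every distinct observed score is a candidate threshold; a protein is
"above" a threshold `t` when its score is `>= t` (non-strict, so the
chosen cutoff is itself retained — the convention that makes the reported
cutoff reproduce the reported proteome). TPR and FPR are fractions of
*detected* class members above `t`, and the selected cutoff maximizes
`J = TPR − FPR`. Two decisions here were genuinely open:

* **Tie-break.** When several thresholds attain the maximal `J`, the
  largest (most stringent) wins. This favours specificity; since tied
  thresholds by definition trade no TPR against FPR, the choice only
  affects which boundary proteins are kept, and the monotone-transform
  invariance of the ROC is preserved.
* **ERM H/L false positives.** The H/L axis measures labeling over an
  untagged control, for which the matrix reference list is the natural
  null class for either proteome; the ERM H/L classes therefore reuse the
  matrix list with only the true-positive list swapped.

Reported cutoffs are truncated (toward zero) to two decimals for table
display; filtering uses the exact values by default, with
`use_truncated = TRUE` available to replicate published tables exactly.

## Proteome calls, dual-labeled proteins and intersections

Membership requires all four passes (two axes × two replicates,
`apply_cutoffs()`). Proteins that pass H/L in both replicates but fail H/M
in at least one form the *dual-labeled* set: strongly biotinylated by both
the targeted and the cytosolic construct, hence spatially uninformative and
excluded. The member and dual-labeled sets are disjoint by construction.

`intersect_proteomes()` intersects two calls (e.g. OMM × ERM for
contact-site candidates) and ranks members by a combined enrichment score.
The score is the sum over the two proteomes of the protein's mean
`log2(H/M)` across replicates; no formula is canonical here, so the
alternative (sum of all four values — exactly twice the default, hence the
same ranking) is selectable via `score = "sum_all"`.

## Annotation metrics

`specificity()` reports the fraction of members with prior compartment
annotation against a background universe, plus a sub-compartment breakdown
in which a multiply-annotated protein is assigned once by priority
(`OMM > IMS > IMM > matrix`; `ER > Golgi > PM` for the secretory pathway).
`coverage()` is the recovered fraction of a curated list of established
residents, and `orphan_set()` returns members without prior annotation —
candidate novel residents. Percentages are rounded to whole percent for
presentation; exact fractions are kept in the objects and JSON reports. The
annotation catalog is deliberately an input file, not a bundled database:
the underlying resources are version-dependent, and tests use generated
fixture catalogs instead.

## Moderated t-test for iTRAQ IP-MS enrichment

Detected proteins (≥2 unique quantified peptides and ≥2 ratio observations
in *each* channel pair) have their ratios median-normalized per channel
pair and log2-transformed. Each protein's normalized observations from the
two channel pairs are pooled into a single one-sample test of mean zero.
The pooling was an open design point — the source procedure does not state
whether the two replicate comparisons were tested jointly or separately —
and the pooled one-sample form is the simplest test of the stated null
("not enriched in either replicate") that uses all observations.

The test statistic replaces the per-protein sample variance `s_g^2` (df
`d_g = n_g − 1`) by the posterior variance

```
s̃_g² = (d0·s0² + d_g·s_g²) / (d0 + d_g),    t_g = m̄_g / sqrt(s̃_g²/n_g)
```

with the null distribution `t(d0 + d_g)`. The hyperparameters `(d0, s0²)`
are estimated across all proteins by moment matching on `log s_g²`: under
the scaled inverse chi-square prior, `s_g²/s0²` is F-distributed with
`(d_g, d0)` degrees of freedom, so the mean and excess variance of the log
sample variances identify `s0²` and `d0` through digamma/trigamma
relations; the trigamma inversion uses a Newton iteration, and when the
observed dispersion does not exceed what sampling alone explains, `d0` is
infinite and the prior collapses to the common variance. The limits are
exact and unit-tested: `d0 = 0` reproduces the ordinary one-sample t, and
`d0 = ∞` the z-form `m̄/sqrt(s0²/n)`.

p-values are two-sided; Benjamini–Hochberg adjustment controls the FDR,
and an *enriched* call requires `q < 0.02` (strict) *and* a positive mean
log2 ratio. A two-sided p with a sign constraint was chosen over a
one-sided test because the replicate scatter colors enriched proteins in
the positive quadrant only; at the same `q` threshold the two differ only
by a factor of two in the nominal p, which the FDR step largely absorbs.

## Contact-site geometry

Traced organelle contours arrive as labeled polylines in nanometres.
The mitochondrial perimeter is sampled at evenly spaced arclength steps of
at most 15 nm — the midpoint of the 10–20 nm measurement convention — and
at each sample the minimum Euclidean distance to each ER contour is
evaluated. Maximal runs of consecutive samples closer than 80 nm to the
same ER contour form contact segments; their length is the arclength
between first and last qualifying samples, and the per-sample distances
within the run average to the segment's mean distance. Two points deserve
emphasis:

* **Sampling side.** The mitochondrial contour is sampled, not the ER:
  the metrics are fractions of *mitochondrial* perimeter, so normalization
  and measurement live on the same curve.
* **Terminus spill-over.** Where an ER trace ends, perimeter points up to
  `sqrt(threshold² − gap²)` beyond the overlap are still within the
  threshold of the ER endpoint (≈66 nm per side at a 45 nm gap). This is a
  property of the minimum-distance rule itself, not an artifact; the tests
  assert it quantitatively and the contour generator compensates for it
  (below).

For fraction metrics, runs from distinct ER contours are unioned on the
mitochondrial arc, so overlapping tubules never push a fraction above 1;
the segment list keeps them separate for distance statistics. Closed
contours wrap: a run crossing the trace start is one segment, and a fully
covered closed perimeter reports its exact perimeter as contact length.
Per-mitochondrion fractions and the aggregate fraction (summed contact
length over summed perimeter) satisfy the identity
`aggregate = Σ fraction·perimeter / Σ perimeter` to 1e-9. Mitochondria
touching an ER contour that could not be classified rough or smooth are
excluded from the stratified metrics but retained in the total. Curation
flags (blinding, magnification, section wrinkles) are treated as input row
filters, never computed.

## Synthetic data: what it emulates and what it does not

`simulate_silac()` draws latent per-protein log2 effect pairs from
class-conditional normals: true positives shifted by `(2.0, 1.5)` log2
units on (H/L, H/M) by default, false positives and unrelated proteins at
zero, and the reference class at a configurable anchor (default zero; the
ROC machinery is invariant to the common shift the anchor induces, so its
placement is cosmetic). Replicates share the latent effect such that the
between-replicate correlation is 0.85 at a per-replicate SD of 0.5 —
values chosen to mirror well-correlated replicate scatter (R² around 0.8)
with broad right-shifted true-positive distributions. Raw ratios are
exponentiated and multiplied by channel-level scale factors so that
normalization is genuinely exercised; 5% of ratio cells are missing at
random; decoy rows (single-peptide, contaminant) exercise the detection
filter. `simulate_itraq()` draws per-protein variances from the same
scaled inverse chi-square family the moderated test assumes (`d0 = 4`,
`s0² = 0.1`), with 5% true interactors shifted by 2 log2 units and two
observations per channel pair. `simulate_contour_field()` lays out
near-circular mitochondria and ER arcs at specified gaps covering
specified perimeter fractions, trimming each arc by the terminus
spill-over so the requested contact fraction is exact, and records ground
truth.

What passing tests on these generators shows is that the *procedures* are
correct: cutoffs land where an exhaustive sweep says, recovery and FDR
behave as the model predicts, geometry hits planted fractions within
sampling tolerance. What they do not show: real protein-group tables have
intensity-dependent (not random) missingness, peptide-level aggregation
noise, correlated contamination, imperfect curated lists, and annotation
catalogs with their own error structure; real micrograph traces have
hand-tracing jitter and non-circular organelles. Recovery percentages from
the simulation therefore characterize the method under its own
assumptions, not expected performance on any particular dataset. Recovery
and leakage are measured over proteins that survive detection and pairing
— the population the cutoffs actually see — since upstream missingness is
a property of the data, not of the calling procedure.

## Numerical choices and degenerate inputs

* Median of an even-sized set: midpoint of the central pair.
* Reference-median invariant tolerance: 1e-9.
* Report floats are rendered with `%.17g`: reruns are byte-identical and
  numeric round-trips are exact.
* Truncation (not rounding) to two decimals for displayed cutoffs.
* Trigamma inversion: Newton iteration with asymptotic starts, relative
  tolerance 1e-10.
* Degenerate inputs fail loudly: empty identifier lists, missing reference
  members (named by ratio kind), classes with no detected members, paired
  tables under 3 proteins for R², contours with fewer than 2 points (3 if
  closed) or consecutive duplicate points, p-values outside (0, 1].
* All-equal scores yield that single threshold with `J = 0`; an
  all-covered closed perimeter reports fraction exactly 1.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
the sizes the package treats as its standard study conditions: 3000
proteins (plus 100 reference and ~5% decoys) for the SILAC design, 2000
proteins for the iTRAQ designs, 5000 variance draws for prior-recovery
checks, and fields of 2–6 mitochondria at 180 contour points each. These
sizes keep every check a desk-scale computation while leaving standard
errors small relative to the tolerances tested.

## Known limitations

* Protein identity for set operations defaults to the gene symbol (falling
  back to the first majority accession), uppercased; accession-keyed lists
  are supported but mixing conventions silently shrinks intersections —
  the readers warn only where detectable.
* The moderated test assumes exchangeable variances across proteins; with
  strong mean–variance trends a trended prior would fit better and is not
  implemented.
* Contact metrics are 2-D: fractions of traced perimeter in a section, not
  membrane surface in 3-D.
* The rough/smooth ER distinction is an input label; the package never
  infers it from geometry.
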