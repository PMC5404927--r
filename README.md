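# ratiomap

Analysis pipeline for **ratiometric proximity-biotinylation proteomics** and
the follow-up analyses that usually surround a spatial-proteome study:
isobaric-tag (iTRAQ) IP-MS enrichment testing with a moderated t-test, and
quantification of mitochondria–ER contact sites from traced electron
micrographs.

## Who this is for

Labs mapping **open, cytosol-facing compartments** — the outer
mitochondrial membrane (OMM), the ER membrane (ERM) — with APEX2-style
proximity labeling. In such compartments the labeling radius alone cannot
exclude abundant cytosolic proteins, so the experiment is run as a
three-state SILAC design: heavy (H) = targeted construct, medium (M) =
cytosol-targeted construct, light (L) = untagged control. The pipeline
turns MaxQuant-style protein-group tables into defensible proteome calls.

## The method in brief

For each detected protein (≥2 unique peptides, no contaminant/reverse
flags), two normalized log-ratios are computed by anchoring raw SILAC
ratios on the median of a soluble matrix reference subset:

* `log2(H/L)` — extent of biotinylation over background,
* `log2(H/M)` — spatial specificity over the cytosolic construct.

Per replicate and per axis, a cutoff is selected from curated true/false
positive classes by sweeping every observed score and maximizing the
Youden-style statistic `J = TPR − FPR` (score ≥ threshold counts as above;
ties break toward the most stringent threshold). The final proteome is the
set of proteins above both cutoffs in both replicates; proteins high in
H/L but failing H/M are reported separately as *dual-labeled* exclusions.
Quality is summarized as annotation specificity, curated-list coverage and
orphan counts.

For IP-MS interactor calling, per-protein pooled log2 iTRAQ ratios are
tested against zero with a moderated one-sample t-test: the sample
variance is squeezed toward an empirical-Bayes prior,
`s̃² = (d0·s0² + d·s²)/(d0 + d)`, `t = m̄/sqrt(s̃²/n)` on `d0 + d` degrees
of freedom, with Benjamini–Hochberg FDR control and an enrichment call at
`q < 0.02` with positive mean.

For electron micrographs, traced organelle contours (polylines in nm) are
analyzed with the 80 nm rule: the mitochondrial perimeter is sampled every
≤15 nm, ER segments within 80 nm form contact stretches, and the package
reports per-mitochondrion and aggregate perimeter fractions stratified by
rough/smooth ER, plus membrane-gap statistics.

Every stage has a seeded synthetic-data generator with known ground truth
(`simulate_silac()`, `simulate_itraq()`, `simulate_contour_field()`), so
the whole pipeline is testable without any external download.

## Worked example

```r
library(ratiomap)

sim <- simulate_silac(n_proteins = 3000, seed = 7)
res <- run_silac_analysis(sim$replicate1, sim$replicate2,
                          reference = sim$matrix_set, tp_set = sim$tp_set,
                          proteome_kind = "OMM", catalog = sim$catalog)
#> OMM: detected 3100 / 3255 proteins (replicate 1), 3100 / 3255 (replicate 2)
#> OMM: 2552 proteins with both ratios in both replicates
#> OMM replicate 1: cutoffs log2(H/L) >= 1.15, log2(H/M) >= 0.74
#> OMM replicate 2: cutoffs log2(H/L) >= 1.04, log2(H/M) >= 0.92
#> OMM: final proteome 114 proteins, 24 dual-labeled excluded

res$call
#> OMM proteome call: 2552 paired proteins, 114 members, 24 dual-labeled
round(res$correlations, 3)
#>    hl    hm
#> 0.827 0.802
coverage(res$call$members, sim$tp_set)
#> # A tibble: 1 × 4
#>   n_curated n_recovered coverage percent
#>       <int>       <int>    <dbl>   <dbl>
#> 1       150         113    0.753      75
```

Reading this: of 3255 simulated protein groups per replicate, 3100 pass
the detection filter (≥2 unique peptides, no QC flags) and 2552 carry both
ratios in both replicates. The ROC step picks per-replicate cutoffs on
both axes (printed truncated to two decimals, applied exactly), and the
dual-cutoff intersection calls a 114-member proteome while excluding 24
dual-labeled proteins. Replicate log-ratios correlate at R² ≈ 0.8, and 75%
of the planted true-positive list is recovered.

The same session can run the IP-MS and EM stages:

```r
isim <- simulate_itraq(seed = 7)
mres <- itraq_moderated_test(median_normalize_itraq(filter_itraq(isim$records)))
attr(mres, "prior")
#> empirical-Bayes variance prior over 2000 proteins: d0 = 4.125, s0^2 = 0.103
length(call_enriched(mres))    # q < 0.02, positive mean
#> [1] 85

field <- simulate_contour_field(n_mito = 6, seed = 7)
contact_report(field$contours)
#> contact report: 6 mitochondria, total perimeter 18898 nm
#>   aggregate contact fraction: 24.60% (rough 24.60%, smooth 0.00%)
```

The fitted prior recovers the generator's hyperparameters (`d0 = 4`,
`s0² = 0.1`), and the contact quantifier returns the planted 25% rough-ER
contact fraction within sampling tolerance.

Result objects follow broom conventions (`tidy()`, `glance()`), plot with
`autoplot()` / `plot_ratio_scatter()` / `plot_itraq_replicates()`, and
serialize deterministically with `write_report()`.

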