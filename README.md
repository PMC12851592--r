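# ommaquant

Quantitative phenotyping of the Drosophila compound eye from tabular
measurements: spatial order of the corneal-nipple nanoarray, ommatidial
orientation relative to the eye equator, corneal/bristle morphometrics, and
countercurrent phototaxis scoring. The package is aimed at fly-eye labs
that already segment their SEM/confocal images elsewhere and need the
downstream statistics to be explicit, seeded and testable. A synthetic-data
module generates every input type (point patterns, nested angle tables,
polygon outlines, assay counts), so the entire pipeline runs and is
validated without any microscope data.

## What it computes

**Nipple spatial order.** For centroid patterns in a rectangular window,
the density-normalized pair correlation

g(r) = pair count in [r, r+Δ) / (N ρ π((r+Δ)² − r²)),  ρ = N/|W|,

with translation edge correction, is compared against density-matched
hard-core (random sequential adsorption) null ensembles, via a paired
Wilcoxon signed-rank test and an R² order score (R² < 0.9 flags deviation
from the reference). Empirical curves are then summarized by fitting the
hard-core disk model

g(r) = 0 for r < d;  g(r) = 1 + A·exp(−(r−d)/λ)·cos(2π(r−d)/P) for r ≥ d,

whose parameters — minimum spacing d, contact amplitude A, order-decay
length λ, oscillation period P — are interpretable descriptors of packing.

**Ommatidial orientation.** Circular mean direction μ and mean resultant
length R per group; two-sample Watson's U² (sensitive to location and
dispersion) and the resultant-length difference |R₁ − R₂|, both tested by
a stratified permutation null that shuffles genotype labels only within
each eye (preserving the nested design) with the small-sample correction
p = (k+1)/(n+1).

**Morphometrics.** Shoelace area, perimeter, circularity 4πA/P² (≈ 0.907
for a regular hexagonal cornea), equivalent diameter; fiduciary-microsphere
pixel-to-µm calibration; bristle-class tallies; Kolmogorov–Smirnov
comparison of size distributions.

**Phototaxis.** Final-tube fraction of a three-trial countercurrent assay,
group summaries by genotype/sex, and an independent-trial binomial
simulator whose expected final-tube fraction is p³.

## Worked example

Synthetic two-genotype orientation data at the study's design size
(8 eyes, 5 ommatidia per eye per genotype), equal mean direction but
different concentration:

```r
library(ommaquant)

ctrl <- gen_orientation_dataset(8, 5, mu_deg = 20, kappa = 12,
                                genotype = "control", seed = 101)
mut  <- gen_orientation_dataset(8, 5, mu_deg = 20, kappa = 1.5,
                                genotype = "mutant", seed = 202)
mut$eye_id <- ctrl$eye_id            # mosaic eyes carry both genotypes
angles <- rbind(ctrl, mut)

stratified_permutation_test(angles, "watson_u2", 10000, seed = 42)
#> stratified permutation test (watson_u2): stat = 0.59734, p = 9.999e-05 (10000 permutations, 8 eyes)
compare_resultant_lengths(angles, 10000, seed = 43)
#> stratified permutation test (resultant_diff): stat = 0.27245, p = 9.999e-05 (10000 permutations, 8 eyes)
```

The control group is tightly aligned (R = 0.966 around 21.3°), the mutant
group broad (R = 0.694), and both tests reject at the permutation floor
1/10001 — the orientation distributions differ, driven by dispersion.

Nipple-order analysis of a pseudo-ordered array (jittered hexagonal
lattice, spacing 2 µm) against its hard-core null:

```r
pp  <- gen_jittered_hex_lattice(2, 0.15, owindow(0, 80, 0, 80), seed = 7)
g   <- estimate_rdf(pp, bin_width = 0.1, r_max = 8)
fit_hardcore(g)
#> hard-core disk model: d = 1.85 um, A = 1.531, lambda = 5.435 um, P = 1.778 um
#>   fit R^2 = 0.7727, converged = TRUE
ens <- simulate_null_rdfs(pp, d_min = 1.2, n_sims = 50,
                          bin_width = 0.1, r_max = 8, seed = 8)
rdf_r_squared(g, ens$mean_curve)$r_squared
#> [1] 0.1406001
```

The fitted minimum spacing (1.85 µm) and period (1.78 µm) sit at the
lattice spacing, and the large contact amplitude plus the R² order score
far below the 0.9 boundary say the array is much more ordered than random
packing at the same density.

End-to-end runners (`run_nipple_analysis()`, `run_orientation_analysis()`,
`run_phototaxis_analysis()`) consume an `analysis_config()` (or a YAML/JSON
file) and write seeded, byte-reproducible JSON/CSV reports. The methods
vignette (`vignettes/ommaquant-methods.Rmd`) documents the models,
numerical choices and limitations.

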