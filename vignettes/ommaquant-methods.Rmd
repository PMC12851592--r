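---
title: "Methods: quantifying compound-eye surface order, orientation and phototaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying compound-eye surface order, orientation and phototaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommaquant)
```

`ommaquant` quantifies three readouts of Drosophila compound-eye
development: the spatial order of the corneal-nipple nanoarray, the
orientation of ommatidia relative to the eye equator, and phototactic
behavior in a countercurrent assay. Upstream image segmentation is out of
scope; the package consumes tabular centroids, angles, outlines and counts,
and ships a synthetic-data module that generates all of these with the
statistical structure the analyses assume, so the full pipeline is testable
without microscope data.

## Spatial order of the nipple array

### The pair-correlation (radial distribution) estimator

For a pattern of $N$ points in a rectangular window of area $|W|$, the
density-normalized pair correlation in the distance bin $[r, r+\Delta)$ is

$$\hat g(r) = \frac{\sum_{i \ne j} \mathbf 1\{d_{ij} \in [r, r+\Delta)\}\, w_{ij}}
                   {N \hat\rho\, \pi\!\left((r+\Delta)^2 - r^2\right)},
  \qquad \hat\rho = N/|W|,$$

so that complete spatial randomness (CSR) gives $g \equiv 1$, an exclusion
zone gives $g = 0$, and preferred spacings appear as peaks. Bins are
half-open with configurable width (default 0.1 µm). By default $w_{ij}$ is
the translation edge correction $|W| / ((a - |dx_{ij}|)(b - |dy_{ij}|))$ for
an $a \times b$ window, which removes the systematic downward bias caused
by annuli leaking outside the window; without it (available as
`edge_correction = "none"`, where $w_{ij} = 1$) the estimator
under-estimates $g$ by roughly $r(a+b)/(\pi a b)$ at distance $r$ —
about 8% averaged over $r \le 25$ µm in a 200 µm field — which already
exceeds the calibration tolerance we hold the estimator to under CSR.
$r_{\max}$ is always clipped to 25% of the smaller window dimension, and
empirical and null curves are estimated identically so any residual bias
cancels in comparisons.

The paper's observation-window sizes are not stated, so fixture windows are
configurable everywhere; tests use 40–200 µm squares, which bracket
realistic high-power SEM fields.

### Density-matched hard-core null

The null model for "no order beyond finite size" is random sequential
adsorption (RSA): points are proposed uniformly and rejected when closer
than $d_{\min}$ to an accepted point, with $d_{\min}$ set to the mean
measured nipple diameter. RSA is the simplest process satisfying "random
placement with a minimum separation". Each null simulation reproduces the
empirical pattern's window and point count exactly (density matching), and
`simulate_null_rdfs()` returns per-bin ensemble means and SDs. Packing
requests whose disks would cover ≥ 50% of the window are rejected up front
(RSA saturates near 54.7% coverage in 2D), and an exhausted proposal budget
raises an error reporting the achieved count rather than returning a
partial pattern silently.

### Comparing curves

Two comparisons are provided, matching how ordered arrays are usually
scored:

* **Paired Wilcoxon signed-rank** on per-bin $g$ differences between an
  empirical curve and its null-ensemble mean, two-sided, zero-difference
  bins dropped (identical curves give $p = 1$ by convention). A caveat this
  package measures and documents: per-bin differences between one pair of
  curves share a pattern-level random offset, so the bins are positively
  correlated and the nominal Wilcoxon null is anticonservative when both
  curves are single unstructured realizations. The test is therefore a
  detection device for the large effects it is used on (an ordered array
  against its hard-core null), not a calibrated test for marginal effects.
* **Coefficient of determination** of the empirical curve against a
  reference curve, $R^2 = 1 - \mathrm{SS}_{\mathrm{res}} /
  \mathrm{SS}_{\mathrm{tot}}$, with $R^2 < 0.9$ flagged as a significant
  deviation. $R^2$ can be negative for gross mismatch; a constant empirical
  curve has undefined $R^2$ and raises an error.

Curves from several ommatidia (each from a different eye) are averaged
bin-wise with `average_rdfs()` before model fitting.

## The hard-core disk model

The parametric model fitted to empirical RDFs is a damped cosine above a
hard core:

$$g(r) = \begin{cases} 0 & r < d \\
 1 + A\, e^{-(r-d)/\lambda} \cos\!\big(2\pi (r-d)/P\big) & r \ge d,
 \end{cases}$$

with minimum spacing $d$ (µm), contact-peak amplitude $A$ (dimensionless;
the contact value is $1+A$), order-decay length $\lambda$ (µm) and
oscillation period $P$ (µm). The phase is fixed at zero at contact, which
is what makes the four parameters identifiable and interpretable: larger
$A$ means tighter packing at contact, larger $\lambda$ means order persists
over more neighbour shells, and $P$ tracks the mean neighbour spacing.
Only contrasts of these parameters between genotypes are interpreted;
absolute values are tied to this functional form.

### Fitting strategy

The $r < d$ discontinuity makes joint gradient optimization ill-posed, so
$d$ is profiled out: it is scanned on a grid of step `bin_width/2` and then
refined continuously within one grid step by golden-section search. At each
candidate $d$, $(\lambda, P)$ are optimized by bounded quasi-Newton on log
scale (cost tolerance $10^{-8}$, at most $10^4$ evaluations per grid
point), with $A \in [0, 10]$ solved in closed form since it enters
linearly. Several numerical choices deserve comment:

* **Sub-$d$ bins stay in the objective**, with the model predicting 0
  there. Dropping them would make the residual sum non-comparable across
  the $d$ grid (larger $d$ trivially discards the high-residual contact
  bins) and, worse, leaves $d$ unidentified: for a noiseless model curve,
  every $d + kP$ fits the $r \ge d$ region perfectly. The sub-$d$ penalty
  is what pins $d$ uniquely.
* **Resolution bounds:** $\lambda \ge \Delta$ and $P \ge 4\Delta$ for bin
  width $\Delta$. A decay shorter than one bin or a period under four bins
  cannot be resolved by binned data and, if allowed, the optimizer uses
  them to fit aliasing artefacts on structureless curves (per-bin
  alternating cosines; sub-bin spikes with arbitrarily large $A$).
  Solutions pinned at these bounds, or at the $A$ ceiling, are reported
  with `converged = FALSE`.
* **Multi-start in $P$** (half and double the initializer's period) guards
  against period-halving local minima.
* The initializer reads curve geometry: $d_0$ is the first $r$ with
  $g > 0.5$, $A_0$ the first-peak height above 1, $P_0$ the spacing of the
  first two local maxima (falling back to $2 d_0$ with a single peak), and
  $\lambda_0 = P_0$. Curves with $\max g \le 1$ have no hard-core structure
  and the initializer refuses them.

Noiseless curves generated by the model itself are recovered to optimizer
tolerance (the test suite requires < 1% on every parameter, and measures
median errors around 2% per parameter at per-bin noise of $\sigma = 0.05$).
The model is a description of liquid-like packing; for patterns without a
sharp exclusion onset (e.g. heavily jittered lattices whose $g$ rises
gradually) it is misspecified, which shows up honestly as low fit $R^2$
and/or bound-pinned, non-converged parameters rather than as a clean fit.

## Ommatidial orientation

Angles are treated as full-circle directional data (period 360°), because
the rhabdomere trapezoid has a defined chirality — 10° and 190° are
different orientations. Ventral-eye angles are mirrored into the dorsal
frame before pooling (the two sides rotate in opposite senses); this is
driven by an optional `side` column and enabled by default in the pipeline,
as is the filter that keeps only ommatidia whose outer photoreceptors are
all of one genotype (optional `pure` column).

`circ_mean_resultant()` returns the circular mean direction $\mu$ and mean
resultant length $R \in [0, 1]$ ($R = 1$ iff all angles coincide; $\mu$ is
flagged undefined at $R = 0$). Group differences are tested with:

* **Watson's $U^2$** two-sample statistic, computed from the combined
  circularly ordered sample as $U^2 = \frac{nm}{N^2} \sum_k t_k (d_k -
  \bar d)^2$ with $d_k$ the ECDF difference at the $k$-th distinct value
  and $t_k$ its multiplicity. The mean-centering makes the statistic
  independent of where the circle is cut, hence invariant to common
  rotations — the implementation is checked against a brute-force oracle
  that scans all $N$ starting rotations. $U^2$ is sensitive to location
  and scale differences alike.
* **Resultant-length difference** $|R_A - R_B|$ on pooled per-group
  angles, targeting concentration (dispersion) differences specifically.

### Stratified permutation inference

Ommatidia are nested in eyes, so exchanging labels across eyes would
overstate the effective sample size. The permutation null therefore
shuffles genotype labels only *within* each eye; every permutation
preserves per-eye group sizes. One permutation re-shuffles every eye
independently, and a single stated permutation count (default $10^4$)
governs the whole test — we read "permutations per eye" as the total count
of such joint permutations, since a per-stratum count has no separate
meaning when each permutation acts on all strata. P-values use the
small-sample correction $p = (k+1)/(n_{\mathrm{perm}}+1)$ with ties counted
as extreme (conservative), so the attainable floor is exactly
$1/(n_{\mathrm{perm}}+1)$. Eyes lacking one of the two labels cannot be
permuted and are excluded with a warning; a single-eye dataset runs with
one stratum and a warning.

At the study's design size — 8 eyes per genotype, 5 ommatidia per eye per
group — the suite measures a type-I error within [0.03, 0.07] at
$\alpha = 0.05$ (500 null datasets, 2000 permutations each) and power
above 0.8 against a pure dispersion difference ($\kappa = 8$ vs $0.5$ at
equal means).

## Morphometrics

Shape descriptors operate on traced polygon outlines, not pixel masks:
area by the shoelace formula, perimeter as the closed vertex-chain length,
circularity $4\pi A/P^2$ and equivalent diameter $2\sqrt{A/\pi}$.
Circularity is scale-invariant, 1 for a circle and $\pi\sqrt3/6 \approx
0.907$ for a regular hexagon — the benchmark value for wild-type corneas.
Self-intersecting or degenerate outlines are rejected. Pixel-mask perimeter
conventions differ slightly from polygon perimeters, so absolute
circularities from other toolchains are comparable only through the
hexagon benchmark.

Length calibration uses fiduciary microspheres of known diameter imaged in
the same frame: scale = nominal/measured (µm per pixel), averaged over
beads when several are present, and applied linearly. Bristle phenotypes
are tallied per eye over a fixed vocabulary (normal, paintbrush,
duplicated, triplicated, quadruplicated); the headline statistic is the
share of multiple bristles that are triplicated or more, reported as `NA`
(absent) when there are no multiple bristles at all — never as 0. Size
distributions are compared with the two-sample Kolmogorov–Smirnov test,
exact for combined $n \le 50$ (the study's per-eye samples are small),
asymptotic otherwise.

## Phototaxis

A countercurrent assay gives each fly three consecutive chances to walk
toward light; tube $k$ holds flies with $k$ successes and the reported
score is the final-tube fraction (three responses out of three). The
simulator draws each fly's successes as Binomial(3, $p$), a fixture model
for testing the scorer, not a behavioral claim: per-trial independence is
almost certainly wrong for real flies (phototactic ability persists within
a fly), but it fixes the scorer's expectation at exactly $p^3$, which is
what the consistency tests need. With $p = 0.794$, 35-fly assays average
$\approx 50\%$ in the final tube, matching the magnitude reported for
control genotypes. Group summaries (mean, SD, n of scored fractions by
genotype and/or sex) are the inputs to downstream tests; no
multiple-comparison adjustment is applied at this layer and reports record
that fact.

## Synthetic data: what it does and does not emulate

The generators reproduce the statistical structure the analyses assume:
CSR for randomness baselines; RSA for minimum-separation nulls; a
Gaussian-jittered hexagonal lattice for wild-type-like pseudo-order (the
paper gives no generative model for "pseudo-organized", so the jittered
lattice is this package's fixture choice — its first RDF peak sits at the
lattice spacing and its order decays with jitter); nested von Mises angles
for orientation; noisy hexagons for outlines; and independent-trial
binomial counts for behavior. Jittered points leaving the window are
discarded, as in a cropped SEM field, not wrapped.

They do *not* emulate segmentation error, nipple-diameter variation across
an eye, dorsoventral gradients, inter-eye heterogeneity beyond the eye
stratum, or non-independent fly behavior. Passing tests therefore
demonstrate that the estimators and tests are correct and calibrated under
the stated models at the study's design sizes — not that real corneas obey
those models.

Every generator takes an explicit seed and is bitwise reproducible; there
is no hidden global RNG state (the caller's stream is saved and restored).
Reports embed the seed and settings used, and identical configuration
yields byte-identical reports.

## Problem sizes used by the test suite

Simulation-based checks run at deliberately moderate sizes chosen to hold
Monte-Carlo error well inside the asserted bands: RDF calibration at
$n = 2000$ points × 20 seeds; exclusion checks at $n = 500$ × 10 seeds;
noisy-fit recovery over 50 seeds; permutation size at 500 null datasets ×
2000 permutations; power at 100 datasets × 999 permutations; phototaxis
consistency over 1000 assays. `scripts/acceptance.R` re-runs the same
computations from scratch with a caller-supplied seed.
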