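---
title: "Estimating body weight from biometric measurements with metaheuristic polynomial fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body weight from biometric measurements with metaheuristic polynomial fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwestim)
```

## The problem

Weighing sheep on a scale is slow, stressful for the animal and impractical
at pasture.  An alternative is to estimate body weight (BW, kg) from body
measurements — heights, lengths and girths — which can themselves be read
off depth images taken from the side of the animal.  `bwestim` implements
that whole chain for seven biometric variables: height at withers (HWK),
rump height (RHK), body length (BLK), diagonal body length (BDLK), total
body length (BTLK), girth semi-circumference (GSCK) and abdomen
semi-circumference (ASCK), all in cm, with the K suffix marking
depth-sensor provenance.

## The model

The estimator is an adjustable-degree polynomial with one power term per
variable,

$$\widehat{BW} = \sum_{i=1}^{7} a_i\,\tilde x_i^{\,e_i},
  \qquad a_i \in [0,1],\; e_i \in \{0,\dots,5\},$$

where both the coefficient $a_i$ and the integer exponent $e_i$ of every
term are free parameters (14 in total), so the fit chooses the polynomial
degree per variable instead of fixing it in advance.  The convention
$0^0 = 1$ makes an exponent-0 term a pure constant, which keeps the family
closed under a constant offset up to the coefficient bound.

### Normalization

The $\tilde x_i$ are *normalized* variables.  Raw centimetre inputs raised
to the fifth power with coefficients bounded by 1 cannot produce
kilogram-scale outputs, so each variable is divided by a per-cohort
reference scale (by default its cohort maximum, giving training values in
(0, 1]) and the observed weight by a reference weight.  The scales live in
a `norm_context` stored inside every fitted model, which makes models
portable across cohorts.  Scale-by-maximum is a design choice: it is the
simplest normalization consistent with the coefficient bounds and with
reporting errors as percentages; any fixed positive scales would work, and
the percentage metrics are invariant to the choice.

### Fitness and metrics

The single objective both optimizers minimize is the RMSE between
normalized predictions and normalized observed weights (`fitness()`).  For
reporting, `weight_metrics()` computes RMSE% (RMSE over mean observed
weight), the coefficient of determination R² (unclipped, NA for
zero-variance observations), MBE% (mean bias over mean observed weight) and
MAPE%.  The percentage metrics are scale-free, so they are identical on the
kg and normalized scales.

## The optimizers

Both optimizers act on one mixed encoding: a 14-gene vector, genes 1–7
continuous in [0, 1], genes 8–14 on an integer grid in {0, …, 5}.  Bounds
are described per gene with an optional grid step (`gene_bounds()`), which
both generalizes the integer exponents and allows fully discretized search
spaces small enough for exhaustive enumeration to certify the optimum — the
test suite uses exactly that oracle.

**Genetic algorithm** (`ga_fit()`): 200 individuals; linear rank selection
restricted to the best 85% ("biological pressure"); single-point crossover
at a uniform cut; per-individual mutation with probability 0.30 resampling
one uniformly chosen gene; 10% elitism with cached fitness (elites are
never re-evaluated).  These defaults follow the study protocol this package
implements.  Per-individual mutation of a single gene is the literal
reading of "probability that an individual will mutate"; per-gene mutation
is a documented alternative we did not adopt.

**Cuckoo search** (`csa_fit()`): 200 nests, abandonment probability
Pa = 0.25.  Each iteration proposes one cuckoo from a uniformly chosen nest
by a Lévy-flight step (Mantegna construction, $\beta = 1.5$, step scale 1%
of each gene's range — the conventional defaults, since the protocol fixes
only Pa and the nest count), snapped to the gene grid and clipped; it
replaces a uniformly chosen nest if strictly fitter.  Then the worst
$\lceil 0.25 \cdot 200\rceil$ nests are rebuilt by Lévy steps from
surviving nests.  Real-valued arithmetic on integer genes is rounded half
away from zero, keeping one unified encoding.

### The evaluation budget

Both optimizers stop on a shared budget of fitness evaluations (default
40,000), the basis of a fair comparison between them.  The budget is spent
*exactly*: the final offspring batch (GA) or abandonment batch (CSA) is
truncated to the remaining evaluations, so `run_comparison()` always gives
both algorithms identical evaluation counts by construction rather than by
numeric coincidence of generation sizes.  Ties in fitness always retain the
incumbent, and each fit draws from a single seeded generator, so identical
inputs give bit-identical results.

## The synthetic cohort generator

The real measurement campaign this method family targets (56 ewes,
BW 30.31 ± 7.83 kg, sensor-vs-manual correlations 0.83–0.93 averaging
0.90) is not publicly deposited, so `generate_cohort()` builds cohorts with
the same statistical structure:

* a latent size factor $s \sim N(1, 0.08^2)$ drives all variables
  allometrically, $x_j = b_j\, s^{\gamma_j} (1+\varepsilon)$, with
  $\varepsilon \sim N(0, 0.03^2)$ idiosyncratic noise.  Baselines $b_j$
  (62, 64, 60, 68, 95, 38, 42 cm) and exponents $\gamma_j$ (0.9–1.3,
  girth-type measures most size-sensitive) are plausible implementer-chosen
  values for ~30 kg hair sheep — synthetic, not published data;
* the true weight comes from a fixed member of the polynomial family
  itself (`default_truth_model()`), affinely matched to the target moments
  (30.31, 7.83 kg), plus residual weight noise with CV 0.05 — a plausible
  irreducible error for biometric weight prediction, deliberately below
  total reported model errors, which also contain misfit.  With the default
  rescale the cohort SD is $\sqrt{7.83^2 + (30.31 \cdot 0.05)^2} \approx
  7.98$ kg;
* `rescale_bw = FALSE` scales (never shifts) the weights instead, keeping
  the stored ground-truth model *exactly* generative — the affine shift
  adds a constant the 7-term family cannot represent exactly.  Recovery
  experiments use this mode, and they recover the model in its own
  normalization context, where "recovery" is well defined;
* the sensor channel multiplies each true value by $(1+\delta)$,
  $\delta \sim N(0, 0.043^2)$.  The sensor CV was calibrated analytically
  (from the closed-form correlation of a multiplicative-noise channel) so
  the average true-vs-sensor Pearson correlation is 0.90, the design
  target; the per-variable values span ~0.88–0.93;
* `inject_outliers()` adds rare gross errors: with probability 2/56 per
  animal, one variable of the sensor channel is put off by ±50%, emulating
  sudden animal movement during acquisition.

What the generator does *not* emulate: real allometry is not exactly
log-linear, sensor errors are not independent across variables (posture
affects several lengths at once), and manual-tape errors are absent.
Passing recovery and moment tests therefore validates the estimation
machinery, not field performance on real animals.

## The depth pipeline

`render_phantom()` replaces the sensor with an exact forward model: an
axis-aligned ellipsoid at 1.5 m rendered by per-pixel ray intersection
under a pinhole camera (default focal 292.5 px at 320 × 240 — half the
commonly used 640 × 480 sensor focal; the original hardware calibration is
deliberately not reproduced, the intrinsics are configurable constants).
The measurement chain then mirrors field processing: `segment_depth()`
keeps depths within 1.2–1.8 m (zeros are always dropped; segmentation is
idempotent), `backproject_and_flatten()` bins the back-projected points
into a 1 cm/pixel planar histogram, and `measure_distance()` reads
Euclidean landmark distances in cm.  `measure_phantom()` runs the chain
end-to-end: landmark positions are found by casting rays from the
silhouette centroid (programmatic placement replaces interactive
point-picking, for testability), and errors are reported against the
phantom's closed-form truth.  Two systematic error sources bound the
accuracy: 1 cm binning (±1–2 cm on a measurement) and apparent-contour
shrinkage (a tangent-ray effect of order $(c/z_0)^2/2$, under 1% here);
noise-free landmarks come out within ~3%, comfortably inside the 5%
acceptance band, and 2 cm depth noise stays within 8%.

Semi-circumferences cannot be observed from one side view;
`semi_circumference()` reconstructs them as half-ellipse perimeters
(Ramanujan approximation) from the silhouette height, with the transverse
depth an explicit assumption.  This is a documented stand-in for an
underdetermined step, not a measurement.

## Numerical and design choices

* Percentage normalizations (RMSE%, MBE% by mean observed weight) are the
  only choice that makes unit-free error tables well defined; MAPE is
  undefined at zero observed weight (error), R² at zero variance (NA with
  warning — kept non-fatal so the other metrics of a degenerate example
  remain usable).
* Generation accounting: a GA generation costs `population − elite`
  evaluations because elite fitness is cached; this maximizes search per
  budget.
* `rank_select()` uses the simplest linear rank weights
  $w = N_{el} - \mathrm{rank} + 1$; ties break by insertion order
  (stable sort), so results are deterministic.
* Exponent 0 is reachable by the search; it degrades a term to a constant,
  which is continuous with the rest of the grid and occasionally useful to
  absorb offsets.
* Test and example problem sizes (e.g. recovery at n = 56 with the full
  40,000-evaluation budget, grid oracles with ~10³ points, phantom suites
  of 5 × 5 landmark pairs) were chosen so the whole suite runs in about a
  minute on one core while still exercising every stage at protocol-scale
  budgets.

## Limitations

* The optimizers are stochastic; at the default budget the GA's recovery
  error on noise-free cohorts is near the 10⁻² acceptance level and varies
  by a factor of ~2 across seeds.  Cuckoo search refines more precisely at
  the same budget, consistent with its small-step Lévy local search.
* The model family is additive in single-variable powers: interactions
  (e.g. length × girth products, as in classical tape formulas) are not
  representable.
* Coefficients are bounded to [0, 1] on the normalized scale; a cohort
  whose weight scale is far from its measurement scales could saturate the
  bound.
* The classical baseline formulas (`schaeffer_weight()`,
  `agarwal_weight()`, growth curves) are kept in their native source units
  (inches, months) with no conversion, for comparison in their own terms.
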