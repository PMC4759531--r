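---
title: "Contact-point detection and thin-sample modulus extraction: models, parameters and design choices"
author: "afmcp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-point detection and thin-sample modulus extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmcp)
```

## The problem

An AFM force-displacement record contains only two signals: the piezo
displacement `Z` and the cantilever deflection `d`. Everything a
mechanics analysis needs — the force `F = k d`, the indentation
`delta = (Z - Z_CP) - (d - d_CP)`, and the local sample thickness
`h = |Z_CP - Z_glass|` — is referenced to the contact point (CP), the
sample at which the tip first touches the surface. On stiff substrates
the CP is a sharp kink; on a 1–10 kPa gel or a living cell the
deflection grows from the noise floor quadratically, and a CP
misplaced by tens of nanometres propagates into order-of-magnitude
errors in the fitted Young's modulus. The package automates CP
detection by *sequential search*: every candidate sample on the
approach segment is treated as a trial CP, scored by one or more test
parameters designed to peak near the true contact, and the highest
(combined) score wins.

## Contact models and units

Canonical units everywhere: nm for `Z`, `d`, `delta`, `h`; nN for
force; kPa for moduli; N/m for the spring constant (1 N/m × 1 nm =
1 nN, and 1 kPa = 1e-6 nN/nm², which is where the `1e-6` prefactor in
the model code comes from).

For a rigid cone of half-opening angle θ on an elastic half-space
(Sneddon):

$$F = \frac{2}{\pi}\,\frac{E}{1-\nu^2}\,\tan\theta\,\delta^2 .$$

For a soft layer of thickness `h` bonded to a rigid substrate the
half-space assumption fails and the substrate stiffens the response.
The bottom-effect cone correction multiplies the Sneddon force by a
polynomial in the dimensionless ratio $w = \delta\tan\theta/h$:

$$F_{\mathrm{BECC}} = F_{\mathrm{Sneddon}}\,(1 + b_1 w + b_2 w^2),
  \qquad b_1 = \frac{2 \times 1.7795}{\pi^2},\quad
  b_2 = 16 \times 1.7795^2 ,$$

where 1.7795 is the bonded-layer image constant in the incompressible
limit. The coefficients live in one constant table
(`beccCoefficients()`) so the transcription is isolated; a unit test
pins `B(0) = 1` (the thick-sample Sneddon limit). Reproductions of
this correction in the literature differ in the normalisation of the
second-order term; every self-consistency result in this package
(generation, fitting, detection) holds for any monotone `B` with
`B(0) = 1`, so the choice affects absolute force values but not the
logic of any analysis stage.

Both models are *linear* in `E`. `fitModulus()` therefore computes the
least-squares modulus in closed form, $\hat E = \sum F g / \sum g^2$
with `g` the model force at `E = 1`, instead of running an iterative
optimiser — the exact minimiser of the same objective, at a fraction of
the cost, which matters because the goodness-of-fit search performs one
fit per candidate. Estimates are constrained to (1e-3, 1e4] kPa;
values clamped at a bound are flagged as non-converged. Points with
`delta < 0` are excluded (the models describe contact only), as are
points with `delta >= h` in BECC fits (outside the correction's
validity). `r²` is computed on the fitted range only. The power-law
fit `F = A δ^x` (`fitPowerLaw()`) is initialised from the log–log
regression and refined by a damped Gauss–Newton iteration written out
in the package; an established Levenberg–Marquardt implementation
serves as the independent cross-check in the test suite.

## The four test parameters

* **Goodness of fit** (`gof_whole`, `gof_low`): re-reference the curve
  at the trial point (`delta = 0`, `F = 0` there), fit the contact
  model to the contact part, score by `r²`. `gof_low` fits only the
  first third (`gofLowFraction = 1/3`) of the contact points — the
  low-indentation region most sensitive to the CP. When the curve has
  a glass reference, the thickness entering the BECC fit is recomputed
  per candidate (`h_i = Z_glass - Z_i`), keeping the trial model
  self-consistent.
* **Ratio of variances** (`rov`): deflection variance in a 50-nm
  window just ahead of the trial point divided by that just behind it
  (`rovWindow = 50`; the trial point belongs to neither window). Off
  contact both windows see only noise and the ratio hovers near 1 — for
  `w` samples per window its null expectation is the F-ratio mean
  `(w-1)/(w-3)`, 19/17 ≈ 1.12 at the default sampling. Near the CP the
  ahead-window picks up the contact rise first and the trace peaks.
  The only numerical hazard is a noiseless flat denominator; it is
  floored at (1e-3 nm)² and such entries are flagged.
* **Log-modulus derivative** (`delta_e`): the modulus series `E(i)`
  from a sequential fit scan changes roughly exponentially in the
  trial index for thin-film analyses; the trace is
  `-d(ln E)/di`, computed with the 6th-order central stencil
  (−1, 9, −45, 0, 45, −9, 1)/60, so that an inflection of `ln E(i)`
  near the CP becomes a local maximum. The three candidates at each
  edge are invalid by construction. When combined with a
  goodness-of-fit component the scan is shared, so the combination
  still costs one fit per candidate.
* **Power-law exponent** (`ple`): fit `F = A δ^x` to a 250-nm region
  of travel ahead of the trial point (`pleVicinity = 250`); score
  `-|x - 2|`, maximal where the response is purely quadratic, as it is
  at the true CP of a conical contact. The vicinity restriction keeps
  the thin-film higher-order terms (which push `x` above 2) from
  dominating; any strictly decreasing function of `|x - 2|` selects
  the same argmax.

Each trace is min–max normalised onto [0, 1] (`normalizeTrace()`)
before multiplication. Min–max rather than divide-by-max because the
raw ΔE and PLE scores are negative, and a multiplicative combination
needs non-negative factors; the argmax is unchanged either way.
Combined traces are frequently multimodal; the CP is the candidate
with the highest combined value, ties resolved towards the earlier
index (the conservative choice: a too-early CP under-reports
indentation rather than inventing it). Every candidate in range is
evaluated — bracketing optimisers such as golden-section search assume
a unimodal objective and are deliberately not offered.

## The search range

A design point where this package departs from a plain full-range
sweep: by default (`searchRange = "auto"`) the candidate range is
restricted to a vicinity of a coarse contact estimate before the
sequential search runs. The estimate is the first sustained crossing
of the deflection above its baseline (median of the first 25% of the
approach) by 5 noise standard deviations (MAD-based, floored at
0.05 nm so the rule is defined on noiseless data); the window extends
750 nm back and 250 nm forward of the crossing. The back margin is
sized from the physics: deflection grows as the square of the travel
past contact, so on the softest default samples the crossing lags the
true CP by up to ~300 nm, and 750 nm is a comfortable multiple of
that.

The restriction is not an optimisation shortcut; it is what makes the
statistical test parameters well-posed. On a 2048-sample curve whose
baseline occupies three quarters of the ramp, the RoV trace under the
null is an F(19,19) ratio at ~1500 candidates: its upper tail alone
reaches the height of the genuine contact peak, and an unrestricted
argmax lands on baseline noise thousands of nm from contact.
`searchRange = "full"` and explicit index windows remain available,
and `candidateRange()` always intersects the range with each
component's structural margins (full RoV windows, stencil edges, PLE
vicinity, ≥10 points ahead for fits).

## The synthetic generator

`generateCurve()` emulates the benchmark measurement regime for soft
thin gels: 5-µm triangular ramps at 2048 samples per direction, a
0.03 N/m cantilever with a 35° conical tip, an incompressible sample
of constant true modulus (10 kPa by default) whose thickness is drawn
uniformly from 2–8 µm per curve, iid Gaussian deflection noise
(1 nm), and a glass reference set exactly at `Z_cp + h`. On the
contact side the noiseless deflection solves the *implicit* force
balance `k d = F_BECC((Z - Z_cp) - (d - d_cp))` by vectorised
bisection (60 halvings of a bracket that always contains the unique
root, since the corrected force is strictly increasing in
indentation); a small-deflection approximation `delta ≈ Z - Z_cp`
would bias the ground truth, because at 10 kPa and 0.03 N/m the
deflection is a non-negligible fraction of the travel. The residual
`|k d - F_BECC(δ)|` is below 1e-6 nN at every sample, which a test
asserts. The true CP is snapped onto the sampling grid so the
ground-truth index is exact.

The contact point falls in the last quarter of the ramp
(`cpPositionRange = c(0.75, 0.9)`). That choice sets the force scale:
0.5–1.25 µm of contact travel produces peak forces of roughly 3–15 nN
and deflections of 100–500 nm — the regime of gentle indentation
mapping on gels and cells. Placing the CP early in the ramp instead
drives the solver to ~70 nN and 2.4 µm of deflection on a 10 kPa film,
forces no soft-sample experiment reaches. Generation refuses
parameters that push the indentation beyond `0.8 h`, the validity
envelope of the thin-film correction.

What the generator deliberately omits: baseline drift and 1/f noise
(a linear drift term exists but is off by default), hydrodynamic drag,
adhesion (snap-in/snap-off), viscoelastic hysteresis (an optional
withdraw-stiffening factor exists for testing the approach/withdraw
comparison), and any non-Hertzian surface layer. These omissions are
load-bearing for how test results should be read, as the next section
explains.

## What passing (and failing) on synthetic data does and does not show

Synthetic curves generated *from* the fitted model with iid Gaussian
noise are the cleanest possible test of self-consistency, and the
suite uses them that way: noiseless inverse problems recover the
generating modulus to optimiser precision, the goodness-of-fit
strategies localise the true CP to the sample, and the implicit-solver
residuals vanish. But the same property makes these curves a
best-case scenario for the *classical* whole-curve strategy: when the
data really are model + iid noise, re-fitting the model over the whole
curve at every trial point is essentially maximum-likelihood CP
estimation, and `gof_whole` localises to ±1 sample and recovers the
modulus to ~1% — with none of the overestimation, thickness-correlated
bias or skew that motivates combined strategies on real instrument
data. Published benchmarks on real gel curves show `gof_whole`
overestimating several-fold; that pathology is driven by the
real-data structure (drift, adhesion, surface layers) the generator
omits, not by Gaussian noise.

Two further regime differences are worth knowing before comparing
traces against real-data figures:

* On model-consistent curves the log-slope of `E(i)` has a local
  *maximum* at the CP, not the dip that real thin-sample curves show,
  so the ΔE trace anti-peaks at the CP and its global maximum sits at
  the search-window edge. ΔE's value on real data comes from a
  feature synthetic data does not reproduce.
* RoV's localisation is limited by its window geometry: the
  ahead-window senses the deflection slope half a window past the
  trial point, so with finite noise the trace peaks systematically
  ~5–20 samples inside contact. It is a robust coarse locator, not a
  sample-exact one.

Consequently, on synthetic batches the combined product inherits
RoV/ΔE's window-scale errors (~100–200 nm median) while `gof_whole`
is near-perfect — the *opposite* ranking of the real-data benchmark.
The acceptance suite measures and reports both results as they come
out; the module tests assert only the properties the data regime
actually supports.

## Assessment metrics

For a collection of curves from a nominally homogeneous sample,
`assessStrategy()` reports the mean and variance of `E`, the success
rate (fraction inside an acceptance range, bounds inclusive, with
failed detections kept in the denominator), the sample covariance
between `E` and thickness (the thin-film tell-tale: residual positive
covariance means under-correction, negative covariance
over-correction), and the Fisher–Pearson skewness `g1` (CP noise
produces log-normal-like positive skew). The global metric

$$M = \frac{\sigma^2(E)\,\lvert\sigma(E,h)\rvert\,\lvert s(E)\rvert}{SR}$$

(kPa³ nm; lower is better) takes absolute values of the signed
components so that over- and under-correction both count against a
strategy. Sample (n−1) covariance and moment skewness are used; the
distinction from other estimator conventions is below the precision of
any published table. `strategyBenchmark()` ships the component metrics
of a published >1000-curve benchmark on ~10 kPa thin gels as reference
input; recomputing `M` from those components reproduces seven of the
eight printed values within 1%, while the printed value for the
best-performing combination differs from its own components by ~11% —
an internal inconsistency of the printed table (no rounding of the
components can bridge it), flagged here so nobody chases it as a bug.

## Problem sizes and runtime

The default study sizes keep the full suite inexpensive: the ranking
experiment uses 200 curves at 2048 samples (about 12 s end to end),
the localisation study 20 curves per strategy, the RoV null study 100
curves; module tests use 512-sample curves. A full-range
goodness-of-fit scan on a 2048-sample curve costs ~1.5 s in pure R;
the default vicinity restriction reduces it by roughly five-fold,
which is also why no compiled code is needed.

## Known limitations

* Conical tip geometry only; pyramidal, spherical and flat-punch
  indenters, and adhesive (JKR/DMT) or explicitly viscoelastic contact
  are out of scope.
* The BECC coefficient transcription ambiguity noted above affects
  absolute corrected forces on thick-ish samples at large `delta/h`.
* Deflection must already be calibrated to length units; photodiode
  sensitivity and spring-constant calibration are upstream of this
  package, as are vendor binary file formats.
* The depth-resolved pair (`fitLow`/`fitHigh`) splits the contact
  points at N/2 by index, which weights travel, not indentation depth.

## A worked example

```{r example, eval = FALSE}
library(afmcp)
ds <- generateDataset(sampleProfile(), nCurves = 20, seed = 1)
res <- analyzeBatch(ds$curves, strategySpec(c("gof_low", "rov", "delta_e")),
                    srRange = c(0.3, 60))
attr(res, "summary")
cp <- findContactPoint(ds$curves[[1]], strategySpec())
writeTraces(cp, "traces.tsv")   # candidate grid + raw/normalised traces
```
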