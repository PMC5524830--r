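---
title: "Methods: point-source tracer kinetics of the brain extracellular space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-source tracer kinetics of the brain extracellular space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecstrace)
```

## The forward model and its assumptions

A microlitre-scale bolus of an inert extracellular tracer (Gd-DTPA)
injected into a brain nucleus spreads through the extracellular space
(ECS) and is simultaneously removed by bulk clearance routes (perivascular
drainage, cellular uptake). `ecstrace` models the experiment as an
instantaneous point source in an infinite, homogeneous, isotropic medium
with first-order clearance:

$$\frac{\partial C}{\partial t} = D^* \nabla^2 C - k' C, \qquad
C(r,t) = \frac{Q}{\alpha}\,(4\pi D^* t)^{-3/2}
\exp\!\left\{-\frac{r^2}{4 D^* t} - k' t\right\}.$$

This is the canonical quantification model of tracer-based ECS MRI, and it
is what gives the estimated parameters their meaning: $D^*$ is the
*effective* diffusion coefficient (free diffusivity reduced by ECS
tortuosity) and $k'$ lumps all first-order removal routes into a single
rate. The assumptions to keep in mind:

* **Instantaneous release.** The actual infusion takes about two minutes;
  the first image follows at ten minutes and observation spans hours, so
  the delta-function source is a good approximation at the times that are
  actually fitted.
* **Homogeneity and isotropy.** White-matter anisotropy, regional
  heterogeneity, and tissue boundaries are ignored. The model is local to
  the injected nucleus.
* **Single clearance compartment.** Everything that removes tracer is one
  exponential. A consequence worth stating explicitly: within this model,
  raising $k'$ with everything else fixed *shortens* the half-life and
  *shrinks* the peak distribution volume (a property the test suite checks
  on a parameter sweep). A data set in which one group shows both the
  highest $k'$ and the longest $t_{1/2}$ cannot be reproduced jointly by
  any single-compartment model; the package therefore treats the four
  observables as separately measured quantities and never forces the
  mechanistic model to reproduce a full cross-group pattern.

## Parameters, units and defaults

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `d_eff` ($D^*$) | mm²/s | — (per animal) | group means span 2.0–2.7 × 10⁻⁴ |
| `k_clear` ($k'$) | 1/s | — (per animal) | see the unit note below |
| `dose` ($Q$) | mol | 2 × 10⁻⁸ | 2 µl of 10 mmol/L Gd-DTPA |
| `alpha` ($\alpha$) | — | 0.2 | classical rodent-brain ECS volume fraction |
| `center` | mm | (−4.8, 1.9, −7.8) | substantia nigra stereotactic site |
| `theta` ($\theta$) | mol/mm³ | 3 × noise SD | detection threshold for Vd |

**The $k'$ unit note.** Published group tables in this literature print
$k'$ on the same 10⁻⁴ scale — and sometimes with the same mm²/s unit
string — as $D^*$. A clearance rate coefficient must carry 1/time, so the
package carries $k'$ in s⁻¹ internally and interprets printed magnitudes
as multiples of 10⁻⁴ s⁻¹. The pipeline manifest repeats this convention in
its warnings so no downstream reader can miss it.

$\alpha$ scales the concentration amplitude only: it cancels exactly out
of the $D^*$, $k'$ and half-life estimates (a test asserts this), and is
absorbed into the fitted effective dose.

**Half-life definition.** $t_{1/2}$ is defined on the distribution-volume
curve: the time elapsed after the peak of $V_d(t)$ until the curve first
falls to half the peak, located by linear interpolation between bracketing
samples. When the sampled span ends above half-maximum the value is
flagged undefined rather than extrapolated. Two clearly named alternatives
— `content_half_life()` ($\ln 2/k'$, the total-content half-life) and
`local_half_life()` (decay of $C(r,t)$ at a fixed site) — are provided for
comparison but are never used by the pipeline.

**Vd conventions.** Neither the detection threshold nor the denominator of
"Vd-max%" is standardised in the literature this package serves. Both are
explicit: $\theta$ defaults to three times the image noise SD expressed in
concentration units (for noise-free analytic work it must be supplied),
and the percentage denominator is the volume of the brain mask — by
default an ellipsoid inscribed in the rendered grid, i.e. a
one-hemisphere-scale reference region, recorded in every result object.
Absolute Vd-max% values therefore depend on these conventions and are
comparable only within a convention, which is why the acceptance
experiment targets $(D^*, k')$ recovery rather than Vd levels.

## What the synthetic generator emulates — and what it does not

`draw_cohort()` draws per-animal $(D^*, k')$ (mechanistic mode) or all
four observables (empirical mode) from normal distributions truncated at
zero, using the published group means/SDs as defaults. `render_image_series()`
renders the analytic field on a 64³ grid of 0.2 mm voxels centred on the
injection site and adds i.i.d. Gaussian noise.

Chosen study conditions, fixed once:

* **n = 9 animals per group.** Published F statistics pin down the
  attrition-adjusted sample size; `audit_group_n()` shows n = 9 is the
  unique equal-n value in 5–10 consistent with all four printed F values.
  (The printed Pearson p-values, by contrast, are consistent with n = 10 —
  an internal inconsistency of the source material that the package notes
  but does not attempt to resolve; the correlation checks use n = 10.)
* **Acquisition schedule: 12 volumes, 15 min apart, first at 10 min.**
  The source protocol does not state its schedule; this one spans both the
  rise and the decay of $V_d(t)$ for group-mean parameters (half-lives of
  roughly 67–98 min) within a 2.9 h session, which is what a practitioner
  would design.
* **Noise: additive Gaussian at 2% of peak enhancement.** Post-enhancement
  SNR is high enough that the Rician floor is negligible, and no noise
  characterisation is published; 2% of peak is a realistic figure for the
  regime and is also the level at which the recovery contract is stated.
* **Enhancement model: linear,** `signal = baseline + beta × concentration`,
  with β = 10⁹ signal units per mol/mm³ and baseline 100 so that peak
  enhancement is a few tens of signal units. Relaxivity nonlinearity and
  sequence physics are out of scope.

What the generator does **not** emulate: motion and misregistration,
spatially correlated noise, partial-volume and susceptibility artefacts,
anisotropic or heterogeneous diffusion, and any real anatomy beyond an
ellipsoidal brain mask. Passing the recovery tests therefore demonstrates
that the estimation machinery is correct and well-conditioned under the
stated model — not that real-scanner series of a real nucleus would be
recovered with the same accuracy.

## Estimation: numerical choices

**Masking.** Fitting uses voxels whose *locally smoothed* (3³ boxcar)
concentration exceeds 5% of the smoothed series peak. With 2% noise a raw
5%-of-peak threshold sits at only 2.5 noise SDs, so a raw mask admits tens
of thousands of pure-noise voxels scattered through the volume; smoothing
cuts the noise SD about five-fold and makes false inclusions negligible,
while the tracer field — smooth at the voxel scale — is essentially
unchanged. The fitted values themselves are always the raw, unsmoothed
concentrations.

**Loss.** The objective is bounded nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`) on *linear* concentration
residuals, which is the maximum-likelihood fit under the additive Gaussian
noise the renderer produces. A log-space least-squares variant
(`loss = "log"`) is retained because the log model is exactly linear in
useful coordinates, but it is not the default: the expectation of
$\log(C + \varepsilon)$ is biased low where $C$ is within a few noise SDs
of zero, and at 2% noise that bias propagates into multi-percent errors in
$k'$. Initialisation, however, exploits the log-linear structure:
regressing $\log C + \tfrac{3}{2}\log t$ on $r^2/t$ and $t$ gives
$-1/(4D^*)$ and $-k'$ as slopes, and the intercept recovers the log
amplitude.

**Bounds, tolerances, tie-breaks.** $D^*$ is constrained to
[10⁻⁵, 10⁻²] mm²/s and $k'$ to [0, 10⁻²] s⁻¹ — a generous physical
envelope; the objective tolerance is 10⁻¹⁰ with at most 200 iterations;
ties in the arg-max of $V_d$ resolve to the earliest time.
Non-convergence is recorded in the result's diagnostics, never thrown.
Degenerate inputs (empty masks, fewer than 20 suprathreshold observations,
fewer than 3 time points) raise classed validation errors that the
pipeline converts into flagged per-animal records.

## Oracles

Two independent numerical routes validate the closed form. A radial
quadrature of $\alpha\int C\,dV$ must equal $Q e^{-k't}$ (mass balance
under clearance) to within 0.1%. A finite-difference solver — 7-point
Laplacian, absorbing boundaries, explicit Euler for diffusion under the
stability bound $D^*\Delta t/\Delta x^2 \le 1/6$, with the clearance term
applied exactly each step as $e^{-k'\Delta t}$ — is initialised from the
analytic field and must track it within 1% of local magnitude on
suprathreshold voxels. The validation configuration starts the comparison
at 900 s so the initial Gaussian is resolved over several 0.1 mm voxels,
and ends it before the far tail reaches the absorbing boundary at
appreciable amplitude; both choices are about making the *discretised*
problem faithful to the continuum one being checked.

## Group statistics

`anova_from_summary()` implements the textbook reconstruction of one-way
ANOVA from per-group (n, mean, SD); `anova_oneway()` computes the same
quantities from raw values by a genuinely separate code path, and the test
suite asserts their algebraic identity to 10⁻¹⁰ as well as agreement with
base R's `oneway.test()`. LSD comparisons use the pooled error term with
no multiplicity adjustment, and all p-values are two-sided (sidedness is
rarely stated in the target literature; two-sided is the conservative
default). Pearson inference uses the exact-null $t$ transform, so printed
$(r, n)$ pairs can be audited without raw data. Type-I error calibration
of the ANOVA p-values is checked by simulation (10⁴ null cohorts of
4 × 9 observations).

The summary-statistics route is also what powers `audit_group_n()`:
with equal groups, $F$ at fixed means/SDs is proportional to n, so adjacent
candidate sizes differ by ~11% while rounding of printed summaries
contributes well under 1% — the consistent n is unambiguous.

## Problem sizes

The defaults used throughout the package and its checks are the study-scale
ones: 64³ voxels at 0.2 mm, 12 time points, 36-animal cohorts, 20-replicate
recovery experiments, 10⁴-draw calibration simulations. Unit tests exercise
the same code paths on reduced grids (24³–48³) where the property under
test does not require full resolution.

## Known limitations

* The mechanistic model cannot, by construction, reproduce a group pattern
  in which clearance rate and half-life rise together; such patterns must
  be treated as empirical observables (empirical mode exists for exactly
  this).
* Vd-max% levels are convention-dependent (threshold, reference volume);
  only within-convention comparisons are meaningful.
* The renderer's noise is spatially white; correlated acquisition noise
  would slow the √n averaging that the fit enjoys here.
* The FD oracle is explicit-Euler and intended for validation at desk
  scale, not as a general PDE solver.
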