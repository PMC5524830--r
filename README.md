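# ecstrace

Quantification of diffusion and clearance in brain extracellular space
(ECS) from dynamic contrast-enhanced imaging of a locally injected tracer.

## The problem

When a small extracellular tracer such as Gd-DTPA is injected as a bolus
into a brain nucleus (here the substantia nigra of a rat), its subsequent
spread and disappearance on serial T1-weighted MRI carries quantitative
information about the tissue: how fast the tracer diffuses through the
tortuous extracellular space, and how fast it is cleared from it. Four
parameters summarise an experiment:

* **D\*** — effective diffusion coefficient of the tracer in tissue
  (mm²/s),
* **k′** — first-order clearance rate coefficient (1/s),
* **Vd-max%** — the maximum of the tracer distribution volume over time,
  as a percentage of a reference brain volume,
* **t₁/₂** — the half-life of the distribution volume's decline from its
  peak.

`ecstrace` implements the full analysis chain as a tested, reproducible
pipeline. Because no image data are deposited with studies of this design,
the package ships a first-class synthetic-cohort generator that emulates
the four-group study layout (PD model, Madopar-treated, sham, control)
with published group means/SDs as ground truth, so every downstream stage
is exercisable end to end.

## The model

The forward model is the instantaneous point-source solution of the
diffusion equation with first-order clearance,

    ∂C/∂t = D* ∇²C − k′ C,
    C(r, t) = (Q/α) (4π D* t)^{−3/2} exp{ −r²/(4 D* t) − k′ t },

for a dose Q released at t = 0 into ECS volume fraction α. The
distribution volume at a detection threshold θ is Vd(t) = (4/3)π r*(t)³
with

    r*² = 4 D* t [ ln( Q / (α (4π D* t)^{3/2} θ) ) − k′ t ].

Estimation inverts the rendered signal (linear enhancement model) and fits
(D\*, k′, amplitude) by bounded nonlinear least squares over all
suprathreshold voxel observations, initialised from the log-linear
structure of the model. Vd-max% and t₁/₂ are measured from the
voxel-count distribution-volume curve. A finite-difference PDE solver and
a radial-quadrature mass-balance check serve as independent oracles for
the closed form.

Group statistics reproduce the field's standard workflow from formulas:
one-way ANOVA (from raw values or from published mean ± SD summaries),
Fisher's LSD post-hoc comparisons, and Pearson correlation inference —
including a sample-size auditor that finds the per-group n consistent with
a published F statistic when a paper omits it.

## Worked example

Re-analysing a published group table (D\* on the 10⁻⁴ mm²/s scale,
mean ± SD, n = 9 per group) without raw data:

```r
library(ecstrace)

specs <- study_groups()   # the four-group design with published summaries
s <- tibble::tibble(group = specs$label, n = 9,
                    mean = specs$d_eff_mean * 1e4,
                    sd   = specs$d_eff_sd   * 1e4)
a <- anova_from_summary(s)
a
#> One-way ANOVA: F(3, 32) = 5.779, p = 0.002826

lsd_posthoc(s, a$ms_within, a$df_within)
#> # A tibble: 6 × 5
#>   group1  group2  mean_diff t_stat  p_value
#> 1 PD      Madopar    0.404   2.09  0.0449
#> 2 PD      sham       0.666   3.44  0.00163
#> 3 PD      control    0.721   3.73  0.000753
#> 4 Madopar sham       0.262   1.35  0.185
#> 5 Madopar control    0.317   1.64  0.111
#> 6 sham    control    0.0550  0.284 0.778
```

The omnibus F of 5.78 on (3, 32) df says the four group means differ
beyond chance; the LSD rows show the PD group driving the effect, with the
Madopar–sham and Madopar–control contrasts non-significant.

One synthetic animal end to end — render a noisy series at the PD-group
mean parameters, then recover them:

```r
p <- tracer_params(d_eff = 2.744e-4, k_clear = 2.153e-4)
series <- render_image_series(p, seed = 101)   # 64³ voxels, 12 time points
analyze_animal(series, animal_id = "PD_demo", group = "PD")
#>   est_d_eff est_k_clear vd_max_pct t_half_s converged
#>    0.000274    0.000213       1.52    625.5      TRUE
```

The fit returns D\* = 2.74 × 10⁻⁴ mm²/s and k′ = 2.13 × 10⁻⁴ s⁻¹, within
about 1% of the generating values despite 2% image noise; `vd_max_pct`
and `t_half_s` are measured from the voxel-count Vd curve of this
synthetic acquisition (their absolute values depend on the detection
threshold and reference volume conventions, which are explicit arguments).

The sample-size auditor, given the published means/SDs and F values of all
four parameters:

```r
audit_group_n()
#>       n f_d_eff f_k_clear f_vd_max_pct f_t_half max_rel_dev consistent
#> 1     5    3.21      11.1         7.12     13.0    0.444    FALSE
#> ...
#> 5     9    5.78      20.0        12.8      23.4    0.000802 TRUE
#> 6    10    6.42      22.2        14.2      25.9    0.112    FALSE
```

Only n = 9 reproduces all four published F statistics simultaneously.

A full cohort run (simulate → estimate → group statistics → report
bundle) is one call, or the CLI dispatcher in `inst/scripts/ecstrace.R`:

```r
run_pipeline(default_run_config(seed = 1), out_dir = "run1")
```

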