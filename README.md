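# dtialps

Diffusion-MRI analysis **along the perivascular space** (the ALPS index), a
non-invasive proxy for glymphatic/interstitial fluid dynamics, together with
a synthetic corona-radiata phantom for studying how the index behaves when
the acquisition changes.

At the level of the lateral ventricle body, projection fibers run
inferior–superior (z), association fibers anterior–posterior (y), and the
perivascular spaces of the medullary veins right–left (x) — perpendicular to
both fiber systems. With `Dxx`, `Dyy`, `Dzz` the diffusion-tensor diagonal
in the scanner frame, measured in ROIs in the projection and association
areas:

```
ALPS index = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

computed per hemisphere (ALPS-R, ALPS-L) and bilaterally (their mean). The
index is 1 when nothing moves preferentially along the perivascular axis;
healthy adult values are around 1.5.

The package is aimed at researchers who use the ALPS index and need to
understand or demonstrate its reproducibility: it provides the ROI
machinery and index computation for real NIfTI + bval/bvec data, the
reliability statistics used to judge it (ICC(2,1) with confidence intervals
and Landis–Koch labels, paired t/Pearson comparisons, repeated-measures
ANOVA), and a fully seeded simulation harness that replays a
multi-condition acquisition experiment — test–retest, plane tilt, chin-up
head position, averaging, 3/12/30 gradient axes, three diffusion times, two
scanner noise profiles — on a known ground truth.

## Worked example

Simulate one standard acquisition (12-axis MPG, b = 1000 s/mm², 2 averages,
TE 85 ms, SNR 40), fit the tensor, and compute the index:

```r
library(dtialps)

spec   <- phantom_spec()                       # ground-truth anatomy
field  <- build_phantom(spec)
scheme <- make_scheme(12, averages = 2, te_ms = 85)
acq    <- simulate_dwi(field, scheme, snr_b0 = 40, seed = 42)

fit <- fit_dti(acq)
fit
#> Log-linear diffusion tensor fit: 12-axis b=1000 avg=2 TE=85
#>   64 x 48 x 24 voxels, 13 volumes; 73728 voxels in fit mask (100.0%)
#>   median RMS log-signal residual (in mask): 0.0281

res <- alps_index(diffusivity_maps(fit), default_rois(spec, "large_sphere"))
res
#> ALPS index (tensor)
#>   right 1.5840  left 1.5673  bilateral 1.5757
#>   right: Dxx(proj) 0.0007492  Dxx(assoc) 0.0007466  Dyy(proj) 0.0004737  Dzz(assoc) 0.0004707
#>   left: Dxx(proj) 0.0007447  Dxx(assoc) 0.0007485  Dyy(proj) 0.0004788  Dzz(assoc) 0.000474

alps_truth(spec)      # the analytic ground truth of this phantom
#> [1] 1.578947
```

The noisy pipeline lands within ~0.2% of the closed-form value; with
`snr_b0 = Inf` it agrees to machine precision. A test–retest block over a
simulated cohort (7 subjects, 4 sessions of the standard sequence) and its
reliability:

```r
design  <- study_design(n_subjects = 7, conditions = study_conditions()[1:4, ], seed = 7)
results <- run_study(design)
sub <- results[results$pattern == "large_sphere" & results$side == "Bil", ]
m <- sapply(c("1a", "1b", "1c", "1d"), function(cl)
  sub$alps[sub$condition == cl][order(sub$subject[sub$condition == cl])])
icc21(m)
#> ICC(2,1), absolute agreement (7 subjects x 4 sessions)
#>   ICC = 0.998  95% CI [0.995, 1.000]  (almost perfect)
```

Each row of `m` is one simulated subject: between-subject spread (~1.47 to
1.77 here) comes from per-subject diffusivity jitter, within-subject spread
(third decimal) from acquisition noise only — hence the near-ceiling ICC.
`run_study(study_design(seed = ...))` runs the full 12-condition design and
`check_findings()` scores the qualitative expectations (reliability under
matched conditions, degradation under rotation, diffusion-time trend, ...).
See the methods vignette (`vignettes/alps-simulation.Rmd`) for the model,
its parameters and its limits.

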