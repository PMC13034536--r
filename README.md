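# mdslope

Quantifies the **marginal diffusion slope (MDS)**, an imaging biomarker of
tumour-margin infiltration in glioma. Diffusion-weighted MRI measures the
apparent diffusion coefficient (ADC, mm²/s), which falls with cellularity;
how steeply ADC rises across the enhancing-tumour boundary distinguishes
circumscribed margins (steep rise) from diffusely infiltrated ones
(shallow rise), and steeper marginal slopes accompany longer survival.

For each voxel of the refined enhancing-tumour boundary the package
estimates a unit outward normal by eigen-decomposition of the local
boundary scatter (5×5(×5) kernel; tangential directions carry the large
eigenvalues, the normal the smallest), samples the ADC map centrifugally
from −2 mm to +6 mm around the boundary at 2 samples/mm, keeps profiles
that stay within the combined tumour/FLAIR abnormality for a contiguous
span of more than 4 mm through the boundary, and fits ordinary
least-squares slopes

&nbsp;&nbsp;&nbsp;&nbsp;MDS_profile = slope of ADC vs distance, per-index slope × 2 points/mm → (mm²/s)/mm

The patient-level MDS is the mean of the valid per-profile slopes. The
package also ships the validation apparatus: a radial-gradient sphere
phantom, a Gaussian-cellularity diffusion simulator built on Graham's
relation D ∝ 1/√ρ (normalized to plateau at 8×10⁻⁴ mm²/s), preclinical
ADC-versus-cell-density band analyses with the TCD/ADC infiltration
index, cohort statistics (Pearson MDS–OS, Cox hazard ratio per SD of MDS
with Schoenfeld checks, Kaplan–Meier summaries), MRI repeatability
statistics (RMCoV, ICC(2,1), Bland–Altman), and synthetic generators
with known ground truth for all of it.

## Worked example

A synthetic patient with a known marginal ramp (9 mm transition, slope
(8−6)×10⁻⁴ / 9 ≈ 2.22×10⁻⁵ (mm²/s)/mm) and mild noise:

```r
library(mdslope)
fx  <- makeSyntheticPatient(transition_width_mm = 9, flair_margin_mm = 4.5,
                            noise_sd = 1e-5, seed = 42)
res <- computeMDS(fx$adc, fx$seg)
res
#> MDSResult: mean MDS = 2.20865e-05 (632/632 profiles valid)
fx$true_slope
#> [1] 2.222222e-05
head(perProfile(res), 3)
#>   vector_id        slope    intercept r_squared n_samples_used
#> 1         1 2.170481e-05 0.0006551446 0.9884932             14
#> 2         2 2.089320e-05 0.0006587058 0.9895070             14
#> 3         3 2.054250e-05 0.0006609892 0.9845040             14
```

All 632 boundary normals yield valid profiles and the recovered mean,
2.21×10⁻⁵ (mm²/s)/mm, sits within 1% of the imposed truth. The simulator
shows the biomarker's mechanism — wider Gaussian cellularity fronts
(more infiltrative margins) give strictly lower MDS:

```r
runInfiltrationSweep(c(1, 2, 4, 8))
#>   sigma_mm     mean_mds n_valid n_total
#> 1        1 7.371113e-05      12      12
#> 2        2 7.794831e-06      24      24
#> 3        4 7.822643e-07      52      52
#> 4        8 2.409399e-07     104     104
```

Real data enter as co-registered NIfTI volumes
(`readScalarVolume`, `readSegmentation`, six-class label scheme with
enhancing tumour = 1, FLAIR abnormality = 3), or through the bundled CLI
(`inst/cli/mds.R`) with subcommands `compute`, `simulate`, `phantom`,
`preclinical`, `cohort` and `fixtures`, each writing a JSON run manifest.

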