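# dtialps

Simulation and recovery of the **DTI-ALPS index**, a diffusion-MRI proxy
for glymphatic (perivascular waste-clearance) function, with the cohort
statistics used to compare it between children with absence epilepsy (CAE)
and healthy controls (HC).

At the level of the lateral ventricle body, perivascular spaces run along
the image x-axis, perpendicular to the projection fibers (z) and
association fibers (y). With 5 mm disk ROIs in the two tracts, the index is

    ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)

where the Dij are means of raw diagonal diffusion-tensor components
(mm²/s) over each ROI. ALPS = 1 in an isotropic medium; lower values
indicate reduced perivascular diffusivity.

Because the clinical raw data are not publicly deposited, the package is
built around *parameter recovery*: a three-tract digital phantom encodes
any desired ALPS value exactly, a Stejskal–Tanner simulator produces the
30-direction b = 1000 s/mm² acquisition with Rician noise, and the full
fit → ROI → index → statistics chain is validated by recovering the known
truth. A Gaussian-copula cohort generator reproduces the study's group
distributions (ALPS 1.45 ± 0.36 in 42 CAE vs 1.66 ± 0.30 in 50 HC) and
covariate correlations (ALPS–age r = 0.766 CAE / 0.651 HC, ALPS–duration
r = −0.48).

## Worked example

```r
library(dtialps)

spec <- phantom_spec()                         # 48 x 48 x 24, 1.72 x 1.72 x 3 mm
gtab <- build_gradient_table(30, 1000, 1)      # 30 directions + 1 b0

# encode a ground truth, image it at SNR 30, measure it back
field <- make_phantom(spec, alps_true = 1.45)
dwi   <- simulate_dwi(field, gtab, s0 = 1000, snr = 30, seed = 1)
run_subject_pipeline(dwi, phantom_spec = spec)
#> ALPS measurement
#>   projection ROI  ( 9 vox): Dxx = 0.0005852, Dyy = 0.0004057 mm^2/s
#>   association ROI ( 9 vox): Dxx = 0.0005759, Dzz = 0.0004083 mm^2/s
#>   ALPS index = 1.4265
```

The measured 1.4265 sits within the per-subject noise SD (~0.04) of the
encoded 1.45; with `snr = NULL` the recovery is exact to 1e-6. Cohort-level
statistics reproduce published p-values from summary statistics alone:

```r
t_test_summary(1.45, 0.36, 42, 1.66, 0.30, 50)
#> two-sample t-test (pooled): 1.450 +/- 0.360 (n=42) vs 1.660 +/- 0.300 (n=50)
#>   t = 3.052, df = 90, p = 0.002984
```

i.e. the headline group difference (p < 0.01), and
`t_test_summary(8.31, 2.12, 42, 8.44, 1.94, 50)` gives p = 0.76 (groups
age-matched).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write tables to `results/`:

1. `01_phantom_validation.R` — noiseless exactness of the simulate→fit→ALPS
   chain; tract color conventions; example NIfTI outputs.
2. `02_group_recovery.R` — 92 subjects imaged at SNR 30; recovered group
   means vs the generating 1.45 / 1.66 and the pooled t-test.
3. `03_correlation_recovery.R` — copula cohorts pushed through the imaging
   pipeline; recovered ALPS–covariate correlations at clinical n plus an
   n = 2000 generator-level check.
4. `04_cohort_statistics.R` — the statistical battery from printed summary
   statistics and from a fully simulated, pipeline-measured cohort.

Run each with `Rscript analysis/01_phantom_validation.R` etc. from the
repository root. The methods vignette
(`vignettes/dti-alps-methods.Rmd`) documents the model, parameter
choices, numerical conventions, and what passing recovery tests does and
does not establish about real data.

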