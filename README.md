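# adctexture

Haralick texture features computed from apparent diffusion coefficient
(ADC) maps are popular quantitative-imaging biomarkers, but their values
depend strongly on choices that are rarely reported: image resolution and
noise, the b-values used to fit the ADC map, the gray-level quantization
method, and the number of gray levels in the co-occurrence matrix.
`adctexture` is an R package for quantifying that dependence. It targets
imaging scientists who want to know, before pooling multi-center or
multi-protocol data, which texture features survive which workflow changes.

The package provides an end-to-end, fully synthetic test bench:

1. **Phantom simulation** — spatially correlated ADC fields (Gaussian
   random field texture) inside ellipsoidal ROIs, optionally bordered by a
   fluid-like high-ADC structure (ADC ≈ 3000 ×10⁻⁶ mm²/s, CSF- or
   urine-like), converted to diffusion-weighted signal by mono-exponential
   decay *S(b) = S₀ exp(−b·ADC)* with additive Gaussian noise. Two built-in
   protocols: a glioma-like one (b = 0…1000 s/mm² in steps of 200, voxel
   1.2 mm, σ = 17) and a prostate-like one (b = 0, 800 s/mm², voxel
   1.625 mm, σ = 2.5).
2. **Pre-processing** — in-plane downsampling (block averaging), noise
   injection with variance additivity (total σ scaled by a factor *f* by
   adding σ√(f²−1)), and voxel-wise ADC fitting by ordinary least squares
   of ln *S* against *b*.
3. **Quantization** — AutoROI (ROI min/max), AutoSlice (per-slice min/max)
   or Manual (fixed limits, clipping) mapping of ADC to gray levels 1…*N*.
4. **GLCM and features** — per-slice symmetric 8-direction co-occurrence
   matrices, summed over slices and normalized to the joint probability
   *p(i,j)*, from which the 19 Haralick features (contrast, correlation,
   energy, entropy, homogeneity, the information measures of correlation,
   the sum/difference statistics, …) are evaluated.
5. **Sensitivity analysis** — a one-at-a-time design varies each parameter
   (resolution ×{1, 1.5, 3}; noise ×{1, 2, 4}; four b-value subsets; gray
   levels {8, 16, 32, 64, 128}; three quantization methods) while the rest
   stay at reference (1.0×, 1.0×, reference b-subset, *N* = 32, AutoROI).
   Every pair of settings is compared per feature with a two-sample
   Kolmogorov–Smirnov test; a parameter significantly affects a feature if
   any pair falls below the Bonferroni-corrected threshold α/m (α = 0.01;
   m = 475 tests for the glioma design, 361 for the prostate design, 836
   jointly).

## Worked example

A 72-phantom glioma-protocol cohort, the full one-at-a-time design, and
the pairwise KS analysis (about 10 s on one CPU):

```r
library(adctexture)
prot  <- make_protocol("glioma")
batch <- make_phantom_batch(72, prot, seed = 2024)
des   <- experiment_design(prot)
tab   <- run_design(batch, des, seed = 2024)
res   <- all_pairs_tests(tab, des)
print(res)
#> Sensitivity analysis: 475 pairwise KS tests, alpha = 0.01 Bonferroni-corrected for 475 tests (threshold 2.11e-05)
#> Significant (parameter, feature) results: 60 of 95
```

Which features each parameter affects (Bonferroni-significant at
α = 0.01):

```r
agg <- res$aggregated
split(agg$feature[agg$significant], agg$parameter[agg$significant])
#> resolution   -> contrast, correlation, difference_entropy, difference_variance,
#>                 dissimilarity, entropy, homogeneity, inverse_difference, sum_of_squares
#> noise        -> 16 of 19 features
#> b_values     -> (none)
#> gray_levels  -> 18 of 19 features (all but correlation)
#> quantization -> 17 of 19 features
```

The b-value combination used to construct the ADC map changes nothing —
mono-exponential decay makes all log-linear fits estimate the same slope —
while the number of gray levels changes almost everything. The mechanism is
direct: features are functions of the *N*×*N* matrix *p(i,j)* and of the
indices *(i, j)*, so growing *N* rescales them by orders of magnitude. For
one phantom:

```r
tab[tab$roi == 1 & tab$parameter == "gray_levels",
    c("setting", "contrast", "energy", "entropy", "homogeneity")]
#>  setting contrast   energy entropy homogeneity
#>        8    0.558 0.094209    2.63       0.758
#>       16    1.767 0.028253    3.84       0.576
#>       32    6.582 0.007528    5.14       0.376
#>       64   25.877 0.002122    6.39       0.218
#>      128  103.457 0.000683    7.50       0.119
```

Delineation robustness — how much each feature moves when the ROI is
expanded by one voxel next to a fluid structure, under AutoROI versus fixed
Manual limits:

```r
ph  <- make_phantom_batch(1, prot, seed = 11)[[1]]
adc <- fit_adc(ph$dwi)
roi_perturbation(adc, ph$roi, manual_limits = c(500, 1500))
```

For most features the Manual percentage change is far smaller than the
AutoROI one, because fixed limits absorb the fluid voxels that the dilated
ROI captures.

## Command line

A thin wrapper over the `cli_*` functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/adctexture.R", package="adctexture"))')" \
  simulate --config cfg.yaml --out phantoms/
```

with verbs `simulate`, `features`, `sensitivity` and `perturb`; see
`?cli_simulate` and friends.
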